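#' Generate the full "ocfate" synthetic study
#'
#' One call produces every input of the nomination analysis with a planted
#' ground truth: a 50 Mb single-chromosome annotation (400 genes, 70%
#' active), an H3K27Ac landscape with 20 planted super-enhancer loci among
#' 400 typical enhancers at a 20:1 per-bp signal ratio, ARID1A-style
#' occupancy peaks at 60 designated genes (8 of them SE-associated),
#' BRD4-style reference/alternative peak sets with 40 planted losses,
#' negative-binomial counts for a 1200-cell two-cluster design with planted
#' markers and condition DEGs (including one SE-associated, occupied,
#' downregulated target gene — the nominated "master regulator" analog),
#' and anchored 3C-qPCR quantities with a 3-fold planted condition effect
#' at the E2-like fragment.
#'
#' @param out_dir Directory to write all standard-format files plus
#'   `manifest.json`, or `NULL` to keep everything in memory.
#' @param seed Master integer seed; stage seeds are derived as small
#'   offsets and recorded in the manifest.
#' @return A list with components `annotation`, `landscape`, `arid1a`,
#'   `brd4` (ref/alt/lost), `sc` (counts/cells/truth), `three_c`, and
#'   `manifest`.
#' @export
simulate_ocfate <- function(out_dir = NULL, seed = 1) {
  genome_length <- 5e7
  anno <- simulate_annotation(n_genes = 400, genome_length = genome_length,
                              active_fraction = 0.7, seed = seed)
  land <- simulate_enhancer_landscape(anno, n_se = 20, n_typical = 400,
                                      signal_ratio = 20,
                                      genome_length = genome_length,
                                      seed = seed + 1)
  se_genes_true <- vapply(land$truth$planted_se_loci, `[[`, "", "gene_id")
  ids <- S4Vectors::mcols(anno$genes)$gene_id
  picks <- with_seed(seed + 2, {
    occ_se <- sample(se_genes_true, 8)
    occ_other <- sample(setdiff(ids, se_genes_true), 52)
    target <- sample(occ_se, 1)
    non_se_occ <- setdiff(ids, union(se_genes_true, c(occ_se, occ_other)))
    list(occupied = c(occ_se, occ_other), target = target,
         deg_down_other = sample(non_se_occ, 24),
         deg_up = sample(setdiff(non_se_occ, character(0)), 25),
         markers = sample(ids, 20))
  })
  arid1a <- simulate_occupancy_peaks(anno, picks$occupied, n_extra = 0,
                                     genome_length = genome_length,
                                     seed = seed + 3)
  brd4 <- simulate_dependent_peaks(n_peaks = 200, n_lost = 40,
                                   genome_length = genome_length,
                                   seed = seed + 4)
  sc <- simulate_counts(ids, n_cells_target = 400, n_cells_rest = 800,
                        marker_genes = picks$markers, marker_fold = 4,
                        deg_up = picks$deg_up,
                        deg_down = c(picks$target, picks$deg_down_other),
                        deg_fold = 3, seed = seed + 5)
  frags <- data.frame(
    fragment_id = c("short", "F1", "E2", "E3", "F4", "F5"),
    distance_kb = c(2, -15, 10, 21, 35, 50)
  )
  true_if <- list(
    ctrl = c(short = 100, F1 = 15, E2 = 60, E3 = 45, F4 = 10, F5 = 5),
    ko = c(short = 100, F1 = 15, E2 = 20, E3 = 15, F4 = 10, F5 = 5)
  )
  tc <- simulate_3c(frags, true_if, control_fragment = "short", cv = 0.1,
                    n_replicates = 4, seed = seed + 6)
  manifest <- list(
    seed = seed,
    stage_seeds = list(annotation = seed, landscape = seed + 1,
                       selection = seed + 2, occupancy = seed + 3,
                       dependent = seed + 4, counts = seed + 5,
                       three_c = seed + 6),
    genome_length = genome_length,
    planted_se_loci = land$truth$planted_se_loci,
    planted_typical_enhancers = land$truth$planted_typical_enhancers,
    chip_total_mapped_reads = land$truth$chip_lib,
    input_total_mapped_reads = land$truth$input_lib,
    planted_occupied_genes = picks$occupied,
    planted_dependent_peaks = brd4$lost,
    planted_markers = lapply(picks$markers, function(g)
      list(gene_id = g, fold = 4, cluster = "c4")),
    planted_condition_degs = c(
      lapply(c(picks$target, picks$deg_down_other), function(g)
        list(gene_id = g, direction = "down")),
      lapply(picks$deg_up, function(g)
        list(gene_id = g, direction = "up"))),
    planted_target = picks$target,
    three_c_true_if = true_if
  )
  res <- list(annotation = anno, landscape = land, arid1a = arid1a,
              brd4 = brd4, sc = sc, three_c = tc, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_annotation(anno$genes, file.path(out_dir, "annotation.gff3"),
                          body = anno$bodies)
    write_narrowpeak(land$peaks, file.path(out_dir, "h3k27ac.narrowPeak"))
    write_bedgraph(land$chip, file.path(out_dir, "h3k27ac_treat.bedGraph"))
    write_bedgraph(land$input, file.path(out_dir, "h3k27ac_input.bedGraph"))
    write_narrowpeak(arid1a, file.path(out_dir, "arid1a.narrowPeak"))
    write_narrowpeak(brd4$ref, file.path(out_dir, "brd4_wt.narrowPeak"))
    write_narrowpeak(brd4$alt, file.path(out_dir, "brd4_ko.narrowPeak"))
    write_count_matrix(sc$counts, sc$cells, file.path(out_dir, "counts"))
    utils::write.table(tc$measurements, file.path(out_dir, "three_c.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

check_report_consistency <- function(nom) {
  k <- nom$cardinalities
  ok <- k["n_triple"] <= min(k["n_se_occ"], k["n_se_deg"], k["n_occ_deg"]) &&
    all(nom$se_occ %in% nom$se_genes) &&
    all(nom$se_occ %in% nom$occupied_genes) &&
    all(nom$triple %in% nom$se_occ) &&
    all(nom$triple %in% nom$deg_genes)
  if (!ok) stop("internal error: set-algebra consistency check failed")
  invisible(TRUE)
}

stage_msg <- function(name, t0, verbose) {
  if (verbose) {
    message(sprintf("[secanalyze] %-16s done in %.2fs", name,
                    as.numeric(Sys.time()) - t0))
  }
}

#' Run the full nomination analysis end-to-end
#'
#' Orchestrates the complete chain on the synthetic "ocfate" study:
#' simulate, write and re-read all inputs through the package's own format
#' readers, call super-enhancers, annotate factor occupancy, compute
#' dependent peaks, compute condition DEGs in the target cluster, nominate
#' targets by triple intersection, and normalize/compare the 3C profile.
#' Writes `report.json` (all cardinalities and the nominated gene list,
#' deterministic given the seed), `config.resolved.yaml` and per-stage
#' subdirectories under `out_dir`. Set-algebra consistency of the reported
#' cardinalities is checked after every run.
#'
#' @param out_dir Output directory.
#' @param seed Master integer seed.
#' @param se_cfg An [se_config()].
#' @param criterion A [marker_criterion()].
#' @param occupancy_window Occupancy TSS window in bp.
#' @param min_overlap Minimum overlap (bp) counting a peak as retained.
#' @param direction DEG direction used for nomination.
#' @param verbose Log stage timings to stderr.
#' @return The report, invisibly (a named list mirroring `report.json`).
#' @export
run_nomination_pipeline <- function(out_dir, seed = 1,
                                    se_cfg = se_config(),
                                    criterion = marker_criterion(),
                                    occupancy_window = 50000,
                                    min_overlap = 1L,
                                    direction = "down",
                                    verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  sim_dir <- file.path(out_dir, "sim")
  sim <- simulate_ocfate(sim_dir, seed = seed)
  stage_msg("simulate", t0, verbose)

  t0 <- as.numeric(Sys.time())
  peaks <- read_intervals(file.path(sim_dir, "h3k27ac.narrowPeak"),
                          "narrowPeak")
  genes <- read_gene_annotation(file.path(sim_dir, "annotation.gff3"))
  chip <- read_bedgraph(file.path(sim_dir, "h3k27ac_treat.bedGraph"),
                        sim$manifest$chip_total_mapped_reads)
  input <- read_bedgraph(file.path(sim_dir, "h3k27ac_input.bedGraph"),
                         sim$manifest$input_total_mapped_reads)
  se <- run_se_pipeline(peaks, genes, chip, input, config = se_cfg,
                        out_dir = file.path(out_dir, "se"))
  stage_msg("call-se", t0, verbose)

  t0 <- as.numeric(Sys.time())
  arid1a <- read_intervals(file.path(sim_dir, "arid1a.narrowPeak"),
                           "narrowPeak")
  occupied <- annotate_peaks_to_genes(arid1a, genes, occupancy_window)
  utils::write.table(data.frame(gene_id = occupied),
                     file.path(out_dir, "occupied_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_msg("occupancy", t0, verbose)

  t0 <- as.numeric(Sys.time())
  wt <- read_intervals(file.path(sim_dir, "brd4_wt.narrowPeak"), "narrowPeak")
  ko <- read_intervals(file.path(sim_dir, "brd4_ko.narrowPeak"), "narrowPeak")
  dep <- dependent_peaks(wt, ko, min_overlap)
  write_bed(dep, file.path(out_dir, "dependent_peaks.bed"))
  stage_msg("dependent-peaks", t0, verbose)

  t0 <- as.numeric(Sys.time())
  sc <- read_count_matrix(file.path(sim_dir, "counts"))
  deg <- condition_deg(sc$counts, sc$cells$cluster, sc$cells$condition,
                       cluster = sim$sc$truth$target_cluster,
                       condition_pair = sim$sc$truth$conditions,
                       criterion = criterion)
  utils::write.table(deg$all, file.path(out_dir, "deg_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg("deg", t0, verbose)

  t0 <- as.numeric(Sys.time())
  nom <- nominate_targets(se$assignment$genes, occupied, deg$all, direction)
  check_report_consistency(nom)
  write_nomination_json(nom, file.path(out_dir, "nomination.json"))
  stage_msg("nominate", t0, verbose)

  t0 <- as.numeric(Sys.time())
  tc <- read_three_c(file.path(sim_dir, "three_c.tsv"))
  prof <- normalize_interaction(tc, "short")
  cmp <- compare_conditions(prof, condition_pair = c("ko", "ctrl"))
  utils::write.table(prof$profile, file.path(out_dir, "three_c_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg("three-c", t0, verbose)

  report <- list(
    seed = seed,
    n_enhancers = se$se_call$n_enhancers,
    n_super = se$se_call$n_super,
    cutoff_rank = se$se_call$cutoff_rank,
    n_se_genes = length(se$assignment$genes),
    n_occupied = length(occupied),
    n_dependent_peaks = length(dep),
    n_deg_up = nrow(deg$up),
    n_deg_down = nrow(deg$down),
    cardinalities = as.list(nom$cardinalities),
    nominated = nom$nominated,
    three_c_e2_ratio = cmp$ratio[cmp$fragment_id == "E2"]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cfg <- list(seed = seed,
              promoter_flank = se_cfg$promoter_flank,
              stitch_gap = se_cfg$stitch_gap,
              assign_window = se_cfg$assign_window,
              occupancy_window = occupancy_window,
              min_overlap = as.integer(min_overlap),
              min_fold = criterion$min_fold, min_pct = criterion$min_pct,
              max_p = criterion$max_p, direction = direction)
  yaml::write_yaml(cfg, file.path(out_dir, "config.resolved.yaml"))
  invisible(report)
}
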