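test_that("generators are bit-reproducible given a seed", {
  a1 <- simulate_annotation(n_genes = 100, genome_length = 1e7, seed = 1)
  a2 <- simulate_annotation(n_genes = 100, genome_length = 1e7, seed = 1)
  expect_identical(as_bed_frame(a1$genes), as_bed_frame(a2$genes))
  a3 <- simulate_annotation(n_genes = 100, genome_length = 1e7, seed = 2)
  expect_false(identical(as_bed_frame(a1$genes)$start,
                         as_bed_frame(a3$genes)$start))
  d1 <- tempfile(); d2 <- tempfile()
  simulate_ocfate(d1, seed = 5)
  simulate_ocfate(d2, seed = 5)
  for (f in c("annotation.gff3", "h3k27ac.narrowPeak",
              "h3k27ac_treat.bedGraph", "counts/matrix.mtx",
              "three_c.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("generator RNG is self-contained and leaves the session RNG alone", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_annotation(seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("active flags follow the requested Bernoulli fraction", {
  # wide genome so the spacing precondition holds at n = 10000
  a <- simulate_annotation(n_genes = 10000, genome_length = 2.6e8,
                           active_fraction = 0.5, seed = 4)
  n_active <- sum(S4Vectors::mcols(a$genes)$active)
  # binomial 99% interval around 5000
  expect_gt(n_active, 5000 - 2.58 * sqrt(10000 * 0.25))
  expect_lt(n_active, 5000 + 2.58 * sqrt(10000 * 0.25))
  b <- simulate_annotation(n_genes = 50, genome_length = 5e6,
                           active_fraction = 1, seed = 1)
  expect_true(all(S4Vectors::mcols(b$genes)$active))
  expect_error(simulate_annotation(n_genes = 1000, genome_length = 1e6),
               "too small")
})

test_that("planted SE constituents stitch into exactly one region each", {
  anno <- simulate_annotation(seed = 2)
  land <- simulate_enhancer_landscape(anno, seed = 2)
  stitched <- merge_within(
    exclude_promoter_regions(land$peaks, anno$genes, 2500), 12500)
  for (locus in land$truth$planted_se_loci) {
    reg <- genomic_intervals(locus$chrom, locus$start, locus$end)
    hits <- GenomicRanges::findOverlaps(reg, stitched)
    expect_length(hits, 1L)
    # the stitched region contains all constituents of the locus
    idx <- S4Vectors::subjectHits(hits)
    expect_equal(S4Vectors::mcols(stitched)$constituent_count[idx],
                 locus$n_constituents)
  }
})

test_that("a landscape without signal contrast flags the degenerate curve downstream", {
  # forty identical enhancers under constant coverage: every stitched
  # region carries the same total signal, so the rank curve has no
  # inflection and no super-enhancer is called
  genes <- gene_annotation("g1", "chrS", 5000)
  starts <- seq(100000, by = 50000, length.out = 40)
  peaks <- genomic_intervals("chrS", starts, starts + 1000)
  cov <- genomic_intervals("chrS", starts, starts + 1000)
  S4Vectors::mcols(cov)$score <- 2
  chip <- coverage_track(cov, 1e6)
  res <- run_se_pipeline(peaks, genes, chip)
  expect_true(res$se_call$degenerate)
  expect_equal(res$se_call$n_super, 0L)
})

test_that("emitted files re-parse cleanly and agree with the manifest", {
  d <- tempfile()
  sim <- simulate_ocfate(d, seed = 3)
  expect_no_warning({
    peaks <- read_intervals(file.path(d, "h3k27ac.narrowPeak"), "narrowPeak")
    genes <- read_gene_annotation(file.path(d, "annotation.gff3"))
    chip <- read_bedgraph(file.path(d, "h3k27ac_treat.bedGraph"))
    wt <- read_intervals(file.path(d, "brd4_wt.narrowPeak"), "narrowPeak")
    sc <- read_count_matrix(file.path(d, "counts"))
    tc <- read_three_c(file.path(d, "three_c.tsv"))
  })
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 3)
  # every planted entity is locatable in the emitted files
  gene_ids <- S4Vectors::mcols(genes)$gene_id
  expect_true(all(man$planted_se_loci$gene_id %in% gene_ids))
  expect_true(all(man$planted_occupied_genes %in% gene_ids))
  expect_true(all(man$planted_dependent_peaks %in%
                    S4Vectors::mcols(wt)$name))
  expect_true(all(man$planted_condition_degs$gene_id %in%
                    rownames(sc$counts)))
  expect_true(all(man$planted_markers$gene_id %in% rownames(sc$counts)))
  expect_true(all(c("short", "E2", "E3") %in% tc$fragment_id))
  expect_true(grepl("^SEconst_", S4Vectors::mcols(peaks)$name[1]) ||
                any(grepl("^SEconst_", S4Vectors::mcols(peaks)$name)))
})

test_that("3C generator recovers true frequencies in the vanishing-noise limit", {
  frags <- data.frame(fragment_id = c("short", "E2", "E3"),
                      distance_kb = c(2, 10, 21))
  tif <- list(c1 = c(short = 100, E2 = 55, E3 = 40))
  sim <- simulate_3c(frags, tif, cv = 1e-9, n_replicates = 3, seed = 1)
  prof <- normalize_interaction(sim$measurements, "short")$profile
  expect_equal(prof$mean_if[match(c("E2", "E3", "short"),
                                  prof$fragment_id)],
               c(55, 40, 100), tolerance = 1e-6)
  expect_error(simulate_3c(frags, tif, cv = 0), "cv")
  tif_bad <- list(c1 = c(short = 90, E2 = 55, E3 = 40))
  expect_error(simulate_3c(frags, tif_bad), "true_if = 100")
})

test_that("count generator rejects invalid dispersion and plants recoverable folds", {
  ids <- sprintf("g%03d", 1:80)
  expect_error(simulate_counts(ids, dispersion = 0), "dispersion")
  sim <- simulate_counts(ids, n_cells_target = 200, n_cells_rest = 800,
                         marker_genes = ids[1:5], marker_fold = 4, seed = 6)
  res <- cluster_markers(sim$counts, sim$cells$cluster, "c4")
  expect_true(all(res$passes[match(ids[1:5], res$gene_id)]))
})
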