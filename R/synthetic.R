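#' @name synthetic
#' @title Synthetic inputs with planted ground truth
#'
#' @description
#' Generators for every input the pipeline consumes — gene annotation,
#' H3K27Ac enhancer landscape with planted super-enhancers, factor
#' occupancy and condition-dependent peaks, negative-binomial single-cell
#' counts with planted markers/DEGs, and anchored 3C-qPCR quantities —
#' together with a ground-truth manifest, so every stage is testable at
#' desk scale without any download. All generators are bit-reproducible
#' given their parameters and seed.
NULL

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a gene annotation
#'
#' Places one TSS per gene, collision-free, by stratifying the chromosome
#' into equal slots and drawing a uniform position within the central 60%
#' of each slot (guaranteeing a minimum TSS spacing of 40% of the slot
#' width). Strands are random; activity flags are Bernoulli draws.
#'
#' @param n_genes Number of genes (>= 10).
#' @param genome_length Chromosome length in bp.
#' @param active_fraction Probability a gene is transcriptionally active.
#' @param seed Integer seed.
#' @param chrom Chromosome name (default `"chrS"`).
#' @return A list with `genes` (TSS annotation `GRanges`), `bodies`
#'   (gene-body `GRanges`) and `seed`.
#' @export
simulate_annotation <- function(n_genes = 400, genome_length = 5e7,
                                active_fraction = 0.7, seed = 1,
                                chrom = "chrS") {
  if (n_genes < 10) stop("need n_genes >= 10")
  slot <- floor(genome_length / n_genes)
  if (slot < 25000) stop("genome too small for collision-free TSS spacing")
  with_seed(seed, {
    tss <- (seq_len(n_genes) - 1) * slot +
      floor(0.2 * slot) + floor(stats::runif(n_genes) * 0.6 * slot)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    active <- stats::runif(n_genes) < active_fraction
    width <- sample(2000:10000, n_genes, replace = TRUE)
    genes <- gene_annotation(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      chrom = chrom, tss = tss, strand = strand, active = active
    )
    body_start <- ifelse(strand == "+", tss, pmax(0, tss - width + 1))
    bodies <- genomic_intervals(chrom, body_start, body_start + width, strand)
    list(genes = genes, bodies = bodies, seed = seed)
  })
}

# place a peak overlapping no promoter and > margin bp from any other peak
place_free <- function(width, promoters, peaks, genome_length, margin,
                       n_try = 200) {
  for (i in seq_len(n_try)) {
    s <- floor(stats::runif(1, margin, genome_length - width - margin))
    raw <- IRanges::IRanges(s, s + width)
    grown <- IRanges::IRanges(s - margin, s + width + margin)
    ok <- (!length(promoters) || !IRanges::countOverlaps(raw, promoters)) &&
      (!length(peaks) || !IRanges::countOverlaps(grown, peaks))
    if (ok) return(s)
  }
  stop("insufficient genome space to place an enhancer; enlarge genome_length")
}

#' Simulate a hockey-stick enhancer landscape with planted super-enhancers
#'
#' Plants `n_se` super-enhancer loci — clusters of 3-8 constituent peaks
#' with intra-cluster gaps drawn well below the stitch gap — each anchored
#' 4-15 kb downstream of a designated active gene's TSS, and `n_typical`
#' isolated single-peak enhancers elsewhere. Peaks avoid promoter windows
#' entirely and distinct entities are separated by more than the stitch gap,
#' so each planted locus stitches into exactly one region. Treatment
#' coverage is Poisson per 50-bp bin with per-bp rate `typical_rate` over
#' typical peaks and `signal_ratio x typical_rate` over SE constituents;
#' the input track is flat Poisson at `input_rate` over the same bins.
#' Library sizes include the (unemitted) genome-wide background at
#' `input_rate`, as a sequencing run would.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param n_se,n_typical Planted super-enhancer loci / typical enhancers.
#' @param signal_ratio SE-to-typical per-bp signal ratio (> 1).
#' @param typical_rate Treatment read rate per bp over typical enhancers.
#' @param input_rate Input (and treatment background) read rate per bp.
#' @param stitch_gap Stitch gap the landscape is built to respect (bp).
#' @param promoter_flank Promoter half-width peaks must avoid (bp).
#' @param genome_length Chromosome length in bp.
#' @param seed Integer seed.
#' @return A list with `peaks` (narrowPeak-style `GRanges`), `chip` and
#'   `input` (`coverage_track`s), and `truth` (planted SE loci with their
#'   designated gene, typical-enhancer intervals, rates, seed).
#' @export
simulate_enhancer_landscape <- function(annotation, n_se = 20,
                                        n_typical = 400, signal_ratio = 20,
                                        typical_rate = 0.5,
                                        input_rate = 0.05,
                                        stitch_gap = 12500,
                                        promoter_flank = 2500,
                                        genome_length = 5e7, seed = 1) {
  if (signal_ratio <= 1 && signal_ratio != 1)
    stop("signal_ratio must be >= 1")
  genes <- annotation$genes
  margin <- stitch_gap + 500
  with_seed(seed, {
    tss0 <- GenomicRanges::start(genes) - 1L
    promoters <- IRanges::IRanges(pmax(0, tss0 - promoter_flank),
                                  tss0 + promoter_flank)
    placed <- IRanges::IRanges()
    active_idx <- which(S4Vectors::mcols(genes)$active)
    if (length(active_idx) < n_se) stop("not enough active genes for SE loci")
    se_gene_idx <- sample(active_idx, n_se)
    peak_chrom <- character(0); peak_s <- integer(0); peak_e <- integer(0)
    peak_rate <- numeric(0); peak_name <- character(0)
    se_truth <- vector("list", n_se)
    chrom <- as.character(GenomicRanges::seqnames(genes)[1])
    for (i in seq_len(n_se)) {
      gi <- se_gene_idx[i]
      done <- FALSE
      for (try in 1:100) {
        k <- sample(3:8, 1)
        widths <- 50L * sample(10:40, k, replace = TRUE)
        gaps <- sample(1000:8000, k, replace = TRUE)[-1]
        offset <- sample(4000:15000, 1)
        s0 <- tss0[gi] + offset
        starts <- s0 + cumsum(c(0L, widths[-k] + gaps))
        ends <- starts + widths
        span <- IRanges::IRanges(starts[1], ends[k])
        grown <- IRanges::IRanges(starts[1] - margin, ends[k] + margin)
        if (ends[k] + margin > genome_length) next
        if (!sum(IRanges::countOverlaps(span, promoters)) &&
            (!length(placed) ||
             !sum(IRanges::countOverlaps(grown, placed)))) {
          placed <- c(placed, span)
          nm <- sprintf("SEconst_%02d_%d", i, seq_len(k))
          peak_chrom <- c(peak_chrom, rep(chrom, k))
          peak_s <- c(peak_s, starts); peak_e <- c(peak_e, ends)
          peak_rate <- c(peak_rate, rep(signal_ratio * typical_rate, k))
          peak_name <- c(peak_name, nm)
          se_truth[[i]] <- list(
            locus_id = sprintf("SE_%02d", i),
            chrom = chrom, start = starts[1], end = ends[k],
            gene_id = S4Vectors::mcols(genes)$gene_id[gi],
            n_constituents = k
          )
          done <- TRUE
          break
        }
      }
      if (!done) stop("insufficient genome space for SE locus ", i)
    }
    typ_truth <- vector("list", n_typical)
    for (i in seq_len(n_typical)) {
      w <- 50L * sample(10:40, 1)
      s <- place_free(w, promoters, placed, genome_length, margin)
      placed <- c(placed, IRanges::IRanges(s, s + w))
      peak_chrom <- c(peak_chrom, chrom)
      peak_s <- c(peak_s, s); peak_e <- c(peak_e, s + w)
      peak_rate <- c(peak_rate, typical_rate)
      peak_name <- c(peak_name, sprintf("typical_%03d", i))
      typ_truth[[i]] <- list(chrom = chrom, start = s, end = s + w)
    }
    peaks <- genomic_intervals(peak_chrom, peak_s, peak_e)
    S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(
      name = peak_name, score = 1000, signalValue = peak_rate,
      pValue = -1, qValue = -1, summit_offset = NA_integer_
    )
    # 50-bp binned Poisson coverage over the peaks
    bin_chrom <- character(0); bin_s <- integer(0); bin_e <- integer(0)
    chip_val <- numeric(0); input_val <- numeric(0)
    for (j in seq_along(peak_s)) {
      bs <- seq(peak_s[j], peak_e[j] - 1L, by = 50L)
      be <- pmin(bs + 50L, peak_e[j])
      bw <- be - bs
      bin_chrom <- c(bin_chrom, rep(peak_chrom[j], length(bs)))
      bin_s <- c(bin_s, bs); bin_e <- c(bin_e, be)
      chip_val <- c(chip_val, stats::rpois(length(bs), peak_rate[j] * bw) / bw)
      input_val <- c(input_val, stats::rpois(length(bs), input_rate * bw) / bw)
    }
    bins <- genomic_intervals(bin_chrom, bin_s, bin_e)
    peak_bp <- sum(bin_e - bin_s)
    bg_bp <- genome_length - peak_bp
    chip_gr <- bins; S4Vectors::mcols(chip_gr)$score <- chip_val
    input_gr <- bins; S4Vectors::mcols(input_gr)$score <- input_val
    chip_lib <- sum(chip_val * (bin_e - bin_s)) +
      stats::rpois(1, input_rate * bg_bp)
    input_lib <- sum(input_val * (bin_e - bin_s)) +
      stats::rpois(1, input_rate * bg_bp)
    list(
      peaks = sort_intervals(peaks),
      chip = coverage_track(chip_gr, chip_lib),
      input = coverage_track(input_gr, input_lib),
      truth = list(planted_se_loci = se_truth,
                   planted_typical_enhancers = typ_truth,
                   signal_ratio = signal_ratio,
                   typical_rate = typical_rate, input_rate = input_rate,
                   chip_lib = chip_lib, input_lib = input_lib,
                   seed = seed)
    )
  })
}

#' Simulate factor-occupancy peaks near designated genes
#'
#' Places one peak within +/- 10 kb of the TSS of each designated gene (so
#' the 50 kb occupancy rule always recovers it) plus optional uniformly
#' placed extra peaks.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param occupied_gene_ids Gene ids the factor occupies.
#' @param n_extra Extra peaks placed uniformly at random.
#' @param width Peak width in bp.
#' @param genome_length Chromosome length in bp.
#' @param seed Integer seed.
#' @return A `GRanges` of peaks (named `occ_<gene>` / `extra_<i>`).
#' @export
simulate_occupancy_peaks <- function(annotation, occupied_gene_ids,
                                     n_extra = 0, width = 600,
                                     genome_length = 5e7, seed = 1) {
  genes <- annotation$genes
  ids <- S4Vectors::mcols(genes)$gene_id
  stopifnot(all(occupied_gene_ids %in% ids))
  with_seed(seed, {
    tss0 <- GenomicRanges::start(genes) - 1L
    idx <- match(occupied_gene_ids, ids)
    off <- sample(-10000:10000, length(idx), replace = TRUE)
    s <- pmax(0, tss0[idx] + off)
    chrom <- as.character(GenomicRanges::seqnames(genes)[idx])
    nm <- paste0("occ_", occupied_gene_ids)
    if (n_extra > 0) {
      es <- floor(stats::runif(n_extra, 0, genome_length - width))
      s <- c(s, es)
      chrom <- c(chrom, rep(chrom[1], n_extra))
      nm <- c(nm, sprintf("extra_%03d", seq_len(n_extra)))
    }
    gr <- genomic_intervals(chrom, s, s + width)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = nm, score = 500)
    sort_intervals(gr)
  })
}

#' Simulate reference/alternative peak sets with planted losses
#'
#' Lays out `n_peaks` well-separated reference peaks; the alternative
#' condition keeps all but `n_lost` of them (jittered within half a peak
#' width, preserving overlap) and drops the lost ones entirely. Spacing
#' (>= 2 kb plus jitter) guarantees a lost reference peak overlaps nothing
#' in the alternative set.
#'
#' @param n_peaks Reference peak count.
#' @param n_lost Peaks lost in the alternative condition.
#' @param genome_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A list with `ref`, `alt` (`GRanges`) and `lost` (names of the
#'   planted dependent peaks).
#' @export
simulate_dependent_peaks <- function(n_peaks = 200, n_lost = 40,
                                     genome_length = 5e7, chrom = "chrS",
                                     seed = 1) {
  stopifnot(n_lost <= n_peaks)
  with_seed(seed, {
    slot <- floor(genome_length / n_peaks)
    if (slot < 4000) stop("genome too small for well-separated peaks")
    w <- sample(300:1500, n_peaks, replace = TRUE)
    s <- (seq_len(n_peaks) - 1) * slot +
      floor(stats::runif(n_peaks) * (slot - max(w) - 2000))
    ref <- genomic_intervals(chrom, s, s + w)
    nm <- sprintf("ref_%03d", seq_len(n_peaks))
    S4Vectors::mcols(ref) <- S4Vectors::DataFrame(name = nm, score = 500)
    lost_idx <- sort(sample(n_peaks, n_lost))
    keep <- setdiff(seq_len(n_peaks), lost_idx)
    jit <- sample(-200:200, length(keep), replace = TRUE)
    jit <- pmin(pmax(jit, -(w[keep] - 50)), w[keep] - 50)
    alt <- genomic_intervals(chrom, pmax(0, s[keep] + jit),
                             pmax(0, s[keep] + jit) + w[keep])
    S4Vectors::mcols(alt) <- S4Vectors::DataFrame(
      name = sprintf("alt_%03d", seq_along(keep)), score = 500)
    list(ref = ref, alt = alt, lost = nm[lost_idx])
  })
}

#' Simulate a single-cell count matrix with planted effects
#'
#' Negative-binomial counts for a two-cluster design (a "rest" cluster and
#' a target cluster, both carrying the two conditions): baseline per-gene
#' means are lognormal around `base_mean`; `marker_genes` are
#' `marker_fold`-fold up in the target cluster (both conditions);
#' `deg_up`/`deg_down` genes are `deg_fold`-fold up/down in the treatment
#' condition within the target cluster only. Planted folds are chosen so
#' the 1.28-fold / 25%-expressing criterion holds in expectation.
#'
#' @param gene_ids Gene identifiers (rownames of the matrix).
#' @param n_cells_target,n_cells_rest Cells per cluster (split evenly
#'   between the two conditions).
#' @param target_cluster,rest_cluster Cluster labels.
#' @param conditions Length-2 labels (reference, treatment).
#' @param base_mean Baseline NB mean per gene per cell.
#' @param dispersion NB size parameter (> 0).
#' @param marker_genes,marker_fold Planted target-cluster markers.
#' @param deg_up,deg_down,deg_fold Planted condition effects in the target
#'   cluster.
#' @param seed Integer seed.
#' @return A list with `counts` (dgCMatrix genes x cells), `cells`
#'   (data.frame cell/cluster/condition) and `truth`.
#' @export
simulate_counts <- function(gene_ids, n_cells_target = 400,
                            n_cells_rest = 800, target_cluster = "c4",
                            rest_cluster = "c0",
                            conditions = c("ctrl", "ko"),
                            base_mean = 2, dispersion = 2,
                            marker_genes = character(0), marker_fold = 4,
                            deg_up = character(0), deg_down = character(0),
                            deg_fold = 2, seed = 1) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  n_genes <- length(gene_ids)
  with_seed(seed, {
    half <- function(n) rep(conditions, c(ceiling(n / 2), floor(n / 2)))
    cells <- data.frame(
      cell = sprintf("cell_%04d", seq_len(n_cells_target + n_cells_rest)),
      cluster = rep(c(target_cluster, rest_cluster),
                    c(n_cells_target, n_cells_rest)),
      condition = c(half(n_cells_target), half(n_cells_rest)),
      stringsAsFactors = FALSE
    )
    lam <- base_mean * stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.5)
    mu <- matrix(lam, n_genes, nrow(cells))
    in_t <- cells$cluster == target_cluster
    in_ko <- in_t & cells$condition == conditions[2]
    mu[gene_ids %in% marker_genes, in_t] <-
      mu[gene_ids %in% marker_genes, in_t] * marker_fold
    mu[gene_ids %in% deg_up, in_ko] <-
      mu[gene_ids %in% deg_up, in_ko] * deg_fold
    mu[gene_ids %in% deg_down, in_ko] <-
      mu[gene_ids %in% deg_down, in_ko] / deg_fold
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                     n_genes, nrow(cells),
                     dimnames = list(gene_ids, cells$cell))
    list(counts = Matrix::Matrix(counts, sparse = TRUE), cells = cells,
         truth = list(markers = marker_genes, marker_fold = marker_fold,
                      deg_up = deg_up, deg_down = deg_down,
                      deg_fold = deg_fold, target_cluster = target_cluster,
                      conditions = conditions, seed = seed))
  })
}

#' Simulate 3C-qPCR quantities around planted interaction frequencies
#'
#' The control (short-range ligation) fragment must carry a true IF of 100
#' in every condition; its quantity anchors each replicate. Other
#' fragments' quantities are lognormal with unit mean around
#' `true_if / 100 x control_quantity`, so [normalize_interaction()]
#' recovers `true_if` in expectation and exactly in the cv -> 0 limit.
#'
#' @param fragments data.frame with `fragment_id`, `distance_kb`.
#' @param true_if Named list: condition -> named numeric vector of true
#'   interaction frequencies per fragment (control = 100).
#' @param control_fragment The short-range control's `fragment_id`.
#' @param cv Coefficient of variation of the lognormal noise (> 0).
#' @param n_replicates Replicates per condition (>= 1).
#' @param base_quantity Mean control-template quantity.
#' @param seed Integer seed.
#' @return A list with `measurements` (3C table data.frame) and `truth`.
#' @export
simulate_3c <- function(fragments, true_if, control_fragment = "short",
                        cv = 0.1, n_replicates = 4, base_quantity = 1000,
                        seed = 1) {
  if (cv <= 0) stop("cv must be > 0")
  for (cond in names(true_if)) {
    if (abs(true_if[[cond]][[control_fragment]] - 100) > 1e-12)
      stop("control fragment must have true_if = 100 in every condition")
  }
  sdlog <- sqrt(log1p(cv^2))
  with_seed(seed, {
    rows <- list()
    for (cond in names(true_if)) {
      tif <- true_if[[cond]]
      for (r in seq_len(n_replicates)) {
        cq <- base_quantity * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
        q <- vapply(fragments$fragment_id, function(f) {
          if (f == control_fragment) cq
          else tif[[f]] / 100 * cq * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          fragment_id = fragments$fragment_id,
          distance_kb = fragments$distance_kb,
          condition = cond, replicate = r, quantity = unname(q),
          stringsAsFactors = FALSE)
      }
    }
    list(measurements = do.call(rbind, rows),
         truth = list(true_if = true_if, cv = cv,
                      control_fragment = control_fragment, seed = seed))
  })
}
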