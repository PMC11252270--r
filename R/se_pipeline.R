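#' Super-enhancer calling configuration
#'
#' Defaults reproduce the standard ROSE-style parameterisation: active
#' enhancers are H3K27Ac regions not contained in +/- 2.5 kb promoter
#' flanks, regions within 12.5 kb of one another are stitched, and active
#' genes are assigned to super-enhancers within a 50 kb window.
#'
#' @param promoter_flank Promoter half-width around each TSS (bp).
#' @param stitch_gap Maximum gap stitched across (bp, inclusive).
#' @param assign_window Gene-assignment window from SE edges (bp).
#' @return A list of class `se_config`.
#' @export
se_config <- function(promoter_flank = 2500, stitch_gap = 12500,
                      assign_window = 50000) {
  stopifnot(promoter_flank > 0, stitch_gap > 0, assign_window > 0)
  structure(list(promoter_flank = promoter_flank, stitch_gap = stitch_gap,
                 assign_window = assign_window), class = "se_config")
}

#' Remove peaks contained in promoter flanks
#'
#' Drops every peak fully contained within `[tss - flank, tss + flank)` of
#' any gene (active or not). Peaks that only partially overlap a promoter
#' window are retained intact — "not contained within" is read literally as
#' full containment. `mode = "any"` drops on any overlap instead.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes Gene annotation (width-1 TSS `GRanges`).
#' @param flank Promoter half-width in bp (> 0).
#' @param mode `"contained"` (default) or `"any"`.
#' @return The retained peaks, original order and metadata preserved.
#' @export
exclude_promoter_regions <- function(peaks, genes, flank = 2500,
                                     mode = c("contained", "any")) {
  mode <- match.arg(mode)
  stopifnot(flank > 0)
  if (!length(genes)) {
    warning("empty gene annotation: no promoter exclusion applied")
    return(peaks)
  }
  promoters <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(genes) - flank),
                     GenomicRanges::start(genes) + flank - 1L)
  )
  type <- if (mode == "contained") "within" else "any"
  drop <- IRanges::overlapsAny(peaks, promoters, type = type,
                                     ignore.strand = TRUE)
  peaks[!drop]
}

#' Call super-enhancers by the geometric inflection of the rank curve
#'
#' Implements the ROSE tangent construction on the hockey-stick curve:
#' enhancers are sorted by increasing background-subtracted signal, ranks
#' and signals are min-max scaled to the unit square, and the cutoff is the
#' point maximising `x - y` — the discrete point where a slope-1 line is
#' tangent to the curve from below. Enhancers strictly above the cutoff rank
#' are super-enhancers. Ties in `x - y` break toward the larger rank (fewer
#' super-enhancers); a curve with no point below the diagonal (all signals
#' identical, or perfectly linear) is degenerate and yields zero calls.
#'
#' @param regions `GRanges` of stitched enhancers (or `NULL` to rank bare
#'   signals).
#' @param signal_rpm Numeric vector of background-subtracted signals
#'   (finite, >= 0), parallel to `regions`; at least 3 values.
#' @return A list of class `se_call` with elements `enhancers` (a data.frame
#'   with `rank` ascending, `signal_rpm`, `is_super` and region columns when
#'   `regions` given), `cutoff_rank`, `cutoff_signal_rpm`, `n_enhancers`,
#'   `n_super`, `degenerate`.
#' @examples
#' call_superenhancers(signal_rpm = c(1, 1, 1, 1, 100))$n_super  # 1
#' @export
call_superenhancers <- function(regions = NULL, signal_rpm) {
  if (length(signal_rpm) < 3) stop("need at least 3 enhancers")
  if (any(!is.finite(signal_rpm)) || any(signal_rpm < 0))
    stop("signals must be finite and >= 0")
  n <- length(signal_rpm)
  ord <- order(signal_rpm)
  s <- signal_rpm[ord]
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- s[n] - s[1]
  degenerate <- FALSE
  if (rng == 0) {
    degenerate <- TRUE
    cutoff_idx <- n
  } else {
    y <- (s - s[1]) / rng
    d <- x - y
    dmax <- max(d)
    eps <- 1e-12   # float-robust tie tolerance on the unit square
    if (dmax <= eps) degenerate <- TRUE
    # ties toward the larger rank: fewer, more conservative SE calls
    cutoff_idx <- max(which(d >= dmax - eps))
  }
  is_super_sorted <- if (degenerate) rep(FALSE, n) else seq_len(n) > cutoff_idx
  enh <- data.frame(rank = seq_len(n),
                    signal_rpm = s,
                    is_super = is_super_sorted)
  if (!is.null(regions)) {
    stopifnot(length(regions) == n)
    enh <- cbind(as_bed_frame(regions)[ord, c("chrom", "start", "end"),
                                       drop = FALSE],
                 enh)
    cc <- S4Vectors::mcols(regions)$constituent_count
    enh$constituent_count <- if (is.null(cc)) NA_integer_ else cc[ord]
    rownames(enh) <- NULL
  }
  structure(list(
    enhancers = enh,
    cutoff_rank = cutoff_idx,
    cutoff_signal_rpm = s[cutoff_idx],
    n_enhancers = n,
    n_super = sum(is_super_sorted),
    degenerate = degenerate
  ), class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("se_call: %d enhancers, %d super-enhancers (cutoff rank %d, %.2f rpm)%s\n",
              x$n_enhancers, x$n_super, x$cutoff_rank, x$cutoff_signal_rpm,
              if (x$degenerate) " [degenerate curve]" else ""))
  invisible(x)
}

#' Assign active genes to super-enhancers by TSS proximity
#'
#' A gene is assigned to a region when it is transcriptionally active and
#' its TSS lies within `[region.start - window, region.end + window)`
#' (window measured from the region edges).
#'
#' @param ses `GRanges` of super-enhancer regions.
#' @param genes Gene annotation (width-1 TSS `GRanges` with `active`).
#' @param window Assignment window in bp (> 0).
#' @return A list with `per_se` (list of sorted gene_id vectors, one per
#'   region) and `genes` (deduplicated, sorted union of all assignments).
#' @export
assign_genes_to_ses <- function(ses, genes, window = 50000) {
  stopifnot(window > 0)
  active <- genes[S4Vectors::mcols(genes)$active]
  per_se <- rep(list(character(0)), length(ses))
  if (length(ses) && length(active)) {
    win <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(ses),
      IRanges::IRanges(pmax(1L, GenomicRanges::start(ses) - window),
                       GenomicRanges::end(ses) + window)
    )
    hits <- GenomicRanges::findOverlaps(win, active, ignore.strand = TRUE)
    ids <- S4Vectors::mcols(active)$gene_id
    if (length(hits)) {
      sp <- split(ids[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
      for (k in names(sp)) per_se[[as.integer(k)]] <- sort(unique(sp[[k]]))
    }
  }
  list(per_se = per_se, genes = sort(unique(unlist(per_se))))
}

#' Run the full super-enhancer identification chain
#'
#' Composition of the pipeline stages: promoter exclusion, stitching,
#' background-subtracted rpm quantification over the stitched regions,
#' geometric inflection cutoff, and gene assignment. Deterministic; given
#' `out_dir`, writes `stitched.bed`, `superenhancers.bed`,
#' `ranked_signal.tsv` (rank, region, rpm, is_super) and `se_genes.tsv`,
#' plus `rank_curve.png` when `plot = TRUE`.
#'
#' @param peaks H3K27Ac peak calls (`GRanges`).
#' @param genes Gene annotation (width-1 TSS `GRanges` with `active`).
#' @param chip,input Treatment and control `coverage_track`s (`input` may be
#'   `NULL`).
#' @param config An [se_config()].
#' @param out_dir Output directory, or `NULL` to skip file output.
#' @param plot Write the hockey-stick rank plot (requires `out_dir`).
#' @return A list with `se_call` (an `se_call`), `stitched` (`GRanges`),
#'   `assignment` (from [assign_genes_to_ses()]), `se_regions` (`GRanges` of
#'   the super-enhancers).
#' @export
run_se_pipeline <- function(peaks, genes, chip, input = NULL,
                            config = se_config(), out_dir = NULL,
                            plot = FALSE) {
  stopifnot(inherits(config, "se_config"))
  if (!length(peaks)) {
    empty <- GenomicRanges::GRanges()
    res <- list(se_call = NULL, stitched = empty,
                assignment = list(per_se = list(), genes = character(0)),
                se_regions = empty)
    if (!is.null(out_dir)) write_se_outputs(res, out_dir)
    return(res)
  }
  kept <- exclude_promoter_regions(peaks, genes, config$promoter_flank)
  stitched <- merge_within(kept, config$stitch_gap)
  sig <- quantify_region_signal(stitched, chip, input)
  call <- call_superenhancers(stitched, sig)
  se_idx <- order(sig)[call$enhancers$is_super]
  se_regions <- sort_intervals(stitched[se_idx])
  assignment <- assign_genes_to_ses(se_regions, genes, config$assign_window)
  res <- list(se_call = call, stitched = stitched,
              assignment = assignment, se_regions = se_regions)
  if (!is.null(out_dir)) write_se_outputs(res, out_dir, plot = plot)
  res
}

write_se_outputs <- function(res, out_dir, plot = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- res$stitched
  if (length(st)) S4Vectors::mcols(st)$name <-
    sprintf("stitched_%05d", seq_along(st))
  write_bed(st, file.path(out_dir, "stitched.bed"))
  se <- res$se_regions
  if (length(se)) S4Vectors::mcols(se)$name <-
    sprintf("SE_%04d", seq_along(se))
  write_bed(se, file.path(out_dir, "superenhancers.bed"))
  rs <- if (is.null(res$se_call)) {
    data.frame(rank = integer(0), chrom = character(0), start = integer(0),
               end = integer(0), signal_rpm = numeric(0), is_super = logical(0))
  } else res$se_call$enhancers
  utils::write.table(rs, file.path(out_dir, "ranked_signal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  se_genes <- data.frame(gene_id = res$assignment$genes)
  utils::write.table(se_genes, file.path(out_dir, "se_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (plot && !is.null(res$se_call)) {
    grDevices::png(file.path(out_dir, "rank_curve.png"), width = 720,
                   height = 560)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_enhancer_ranks(res$se_call)
  }
  invisible(out_dir)
}

#' Hockey-stick plot of ranked enhancer signal
#'
#' @param call An `se_call` from [call_superenhancers()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_enhancer_ranks <- function(call, ...) {
  e <- call$enhancers
  graphics::plot(e$rank, e$signal_rpm, type = "l",
                 xlab = "enhancer rank (increasing H3K27Ac signal)",
                 ylab = "background-subtracted signal (rpm)", ...)
  graphics::points(e$rank[e$is_super], e$signal_rpm[e$is_super],
                   col = "firebrick", pch = 16, cex = 0.6)
  graphics::abline(v = call$cutoff_rank, lty = 2, col = "grey40")
  invisible(call)
}
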