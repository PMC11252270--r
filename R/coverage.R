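#' Construct a coverage track
#'
#' A coverage track pairs piecewise-constant per-bp read depth (bedGraph
#' semantics: each interval carries one depth value) with the library size
#' used for reads-per-million scaling. Uncovered bases have depth 0.
#'
#' @param intervals `GRanges` with a numeric `score` metadata column (read
#'   depth per bp over the interval; values >= 0). Intervals on one
#'   chromosome must not overlap.
#' @param total_mapped_reads Library size in reads (> 0).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(intervals, total_mapped_reads) {
  sc <- S4Vectors::mcols(intervals)$score
  if (is.null(sc)) stop("intervals need a 'score' metadata column")
  if (any(sc < 0)) stop("coverage values must be >= 0")
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0)
    stop("total_mapped_reads must be > 0")
  self <- GenomicRanges::findOverlaps(intervals, drop.self = TRUE,
                                      ignore.strand = TRUE)
  if (length(self)) stop("coverage intervals must not overlap")
  structure(
    list(intervals = sort_intervals(intervals),
         total_mapped_reads = as.numeric(total_mapped_reads)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d intervals on %d chromosome(s), %.0f mapped reads\n",
              length(x$intervals),
              length(unique(as.character(GenomicRanges::seqnames(x$intervals)))),
              x$total_mapped_reads))
  invisible(x)
}

#' Read a bedGraph coverage track
#'
#' Fixed 4-column bedGraph (chrom, start, end, value), 0-based half-open.
#' bedGraph does not encode the library size; supply it via
#' `total_mapped_reads`. When omitted it defaults to the rounded sum of
#' `value x width`, which equals the read count when the track stores per-bp
#' read depth with single-bp reads (the convention of this package's
#' synthetic generator).
#'
#' @param path bedGraph file.
#' @param total_mapped_reads Library size in reads, or `NULL` to infer.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, total_mapped_reads = NULL) {
  tab <- read_tabular(path, 4L, "bedGraph")
  co <- parse_coords(tab$fields, tab$line_no, path)
  val <- suppressWarnings(as.numeric(vapply(tab$fields, `[[`, "", 4L)))
  bad <- which(is.na(val) | val < 0)
  if (length(bad)) {
    stop(sprintf("malformed bedGraph line %d in %s: bad value",
                 tab$line_no[bad[1]], path))
  }
  gr <- genomic_intervals(co$chrom, co$start, co$end)
  S4Vectors::mcols(gr)$score <- val
  if (is.null(total_mapped_reads)) {
    total_mapped_reads <- round(sum(val * GenomicRanges::width(gr)))
  }
  coverage_track(gr, total_mapped_reads)
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- as_bed_frame(track$intervals)
  out <- data.frame(df$chrom, df$start, df$end, df$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

track_rpm_per_region <- function(regions, track) {
  # regions legitimately may sit on chromosomes the track does not cover
  # (they count as zero); silence the seqlevel-mismatch chatter
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(regions, track$intervals,
                                ignore.strand = TRUE))
  if (!length(hits)) return(numeric(length(regions)))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ovw <- pmin(GenomicRanges::end(regions)[q],
              GenomicRanges::end(track$intervals)[s]) -
    pmax(GenomicRanges::start(regions)[q],
         GenomicRanges::start(track$intervals)[s]) + 1
  reads <- S4Vectors::mcols(track$intervals)$score[s] * ovw
  out <- numeric(length(regions))
  agg <- rowsum(reads, q)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out / track$total_mapped_reads * 1e6
}

#' Background-subtracted rpm signal over regions
#'
#' For each region computes the total treatment (ChIP) coverage minus the
#' total input/control coverage, each scaled to reads per million mapped
#' reads, floored at zero: `max(0, sum(chip)/N_chip*1e6 -
#' sum(input)/N_input*1e6)`. Bases outside a track's coverage contribute 0.
#' With `floor = "per_bp"` the subtraction is floored at every base before
#' summation instead of once per region.
#'
#' @param regions `GRanges` of regions to quantify.
#' @param chip Treatment `coverage_track`.
#' @param input Control `coverage_track`, or `NULL` for no background.
#' @param floor `"per_region"` (default) or `"per_bp"`.
#' @return Numeric vector of signals (rpm, >= 0), parallel to `regions`.
#' @export
quantify_region_signal <- function(regions, chip, input = NULL,
                                   floor = c("per_region", "per_bp")) {
  floor <- match.arg(floor)
  stopifnot(inherits(chip, "coverage_track"))
  covered <- unique(as.character(GenomicRanges::seqnames(chip$intervals)))
  if (!is.null(input)) {
    stopifnot(inherits(input, "coverage_track"))
    covered <- union(covered,
                     unique(as.character(GenomicRanges::seqnames(input$intervals))))
  }
  absent <- setdiff(unique(as.character(GenomicRanges::seqnames(regions))),
                    covered)
  if (length(absent)) {
    warning("regions on chromosome(s) absent from coverage: ",
            paste(absent, collapse = ", "), "; their signal is 0")
  }
  if (floor == "per_bp" && !is.null(input)) {
    return(vapply(seq_along(regions), function(i) {
      quantify_per_bp_floor(regions[i], chip, input)
    }, numeric(1)))
  }
  chip_rpm <- track_rpm_per_region(regions, chip)
  input_rpm <- if (is.null(input)) 0 else track_rpm_per_region(regions, input)
  pmax(0, chip_rpm - input_rpm)
}

# per-bp floored subtraction over the disjoint sub-bins of one region
quantify_per_bp_floor <- function(region, chip, input) {
  depth_at <- function(track) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(region, track$intervals,
                                  ignore.strand = TRUE))
    track$intervals[S4Vectors::subjectHits(hits)]
  }
  ci <- depth_at(chip); ii <- depth_at(input)
  cuts <- sort(unique(c(GenomicRanges::start(region), GenomicRanges::end(region) + 1L,
                        GenomicRanges::start(ci), GenomicRanges::end(ci) + 1L,
                        GenomicRanges::start(ii), GenomicRanges::end(ii) + 1L)))
  cuts <- cuts[cuts >= GenomicRanges::start(region) &
                 cuts <= GenomicRanges::end(region) + 1L]
  if (length(cuts) < 2) return(0)
  lo <- cuts[-length(cuts)]; w <- diff(cuts)
  val_in <- function(tr_gr, tr) {
    v <- numeric(length(lo))
    if (length(tr_gr)) {
      idx <- findInterval(lo, GenomicRanges::start(tr_gr))
      ok <- idx >= 1 & lo <= GenomicRanges::end(tr_gr)[pmax(idx, 1)]
      v[ok] <- S4Vectors::mcols(tr_gr)$score[idx[ok]]
    }
    v / tr$total_mapped_reads * 1e6
  }
  sum(pmax(0, val_in(ci, chip) - val_in(ii, input)) * w)
}
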