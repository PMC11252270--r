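#' Construct genomic intervals from 0-based half-open coordinates
#'
#' Builds a [GenomicRanges::GRanges] from BED-style coordinates. The package
#' stores intervals internally as `GRanges` (1-based, closed); this constructor
#' is the single conversion point for 0-based half-open input, matching the
#' coordinate dialect of BED/narrowPeak/bedGraph files.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start positions (>= 0).
#' @param end Integer vector, 0-based exclusive end positions (`end > start`).
#' @param strand Strand, one of `"+"`, `"-"`, `"."` per interval (`.` means
#'   unstranded; merging and overlap ignore strand throughout the package).
#'
#' @return A `GRanges` of the same length.
#' @examples
#' genomic_intervals("chr1", 100, 200)  # the BED interval chr1:100-200
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must be > start (0-based half-open)")
  strand <- ifelse(strand == ".", "*", strand)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}

#' 0-based half-open view of a GRanges
#'
#' Inverse of [genomic_intervals()]: returns a data.frame with BED-style
#' `chrom`, `start` (0-based), `end` (exclusive) columns plus any metadata
#' columns. Used by all writers.
#'
#' @param gr A `GRanges`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`, then
#'   the metadata columns of `gr`.
#' @export
as_bed_frame <- function(gr) {
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = st,
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

sort_intervals <- function(gr) {
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr), GenomicRanges::end(gr))]
}

read_tabular <- function(path, n_min, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(#|track|browser)", lines)
  body_idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < n_min)) {
    bad <- body_idx[which(nf < n_min)[1]]
    stop(sprintf("malformed %s line %d in %s: expected >= %d tab-separated fields",
                 what, bad, path, n_min))
  }
  list(fields = fields, line_no = body_idx)
}

parse_coords <- function(fields, line_no, path) {
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: non-numeric coordinates",
                 line_no[bad[1]], path))
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("invalid interval at line %d in %s: end <= start",
                 line_no[bad[1]], path))
  }
  list(chrom = chrom, start = start, end = end)
}

#' Read peak or region calls from BED, narrowPeak or GFF3
#'
#' Coordinates are normalized to the package's internal representation
#' regardless of dialect (BED and narrowPeak are 0-based half-open; GFF3 is
#' 1-based inclusive) and records are returned sorted by (chrom, start, end).
#'
#' @param path File path.
#' @param format One of `"bed"` (3-6 columns), `"narrowPeak"` (10 columns) or
#'   `"gff3"`.
#' @return A sorted `GRanges` with metadata columns `name`, `score` and, for
#'   narrowPeak, `signalValue`, `pValue`, `qValue` and `summit_offset` (bp
#'   from interval start; `NA` where the caller reported none, i.e. `-1`).
#' @seealso [write_bed()], [write_narrowpeak()], [read_gene_annotation()]
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "gff3")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr)))
      stop("invalid GFF3 interval: end < start in ", path)
    mc <- S4Vectors::mcols(gr)
    nm <- if (!is.null(mc$ID)) as.character(mc$ID) else rep(NA_character_, length(gr))
    sc <- if (!is.null(mc$score)) as.numeric(mc$score) else rep(NA_real_, length(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = nm, score = sc)
    return(sort_intervals(gr))
  }
  n_min <- if (format == "narrowPeak") 10L else 3L
  tab <- read_tabular(path, n_min, format)
  co <- parse_coords(tab$fields, tab$line_no, path)
  fld <- function(i, default) {
    vapply(tab$fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  name <- fld(4L, NA_character_)
  score <- suppressWarnings(as.numeric(fld(5L, NA_character_)))
  strand <- fld(6L, ".")
  strand[!strand %in% c("+", "-")] <- "."
  gr <- genomic_intervals(co$chrom, co$start, co$end, strand)
  if (format == "narrowPeak") {
    summit <- suppressWarnings(as.integer(fld(10L, NA_character_)))
    summit[!is.na(summit) & summit < 0] <- NA_integer_
    bad <- which(!is.na(summit) & summit >= GenomicRanges::width(gr))
    if (length(bad)) {
      stop(sprintf("invalid summit offset at line %d in %s: outside peak",
                   tab$line_no[bad[1]], path))
    }
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = name, score = score,
      signalValue = suppressWarnings(as.numeric(fld(7L, NA_character_))),
      pValue = suppressWarnings(as.numeric(fld(8L, NA_character_))),
      qValue = suppressWarnings(as.numeric(fld(9L, NA_character_))),
      summit_offset = summit
    )
  } else {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = name, score = score)
  }
  sort_intervals(gr)
}

#' Write intervals as BED
#'
#' Emits 0-based half-open coordinates, tab separated, LF line endings, no
#' header. Columns beyond the first three are written only as far as they are
#' available (name, score, strand).
#'
#' @param gr A `GRanges`, optionally with `name` and `score` metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- as_bed_frame(gr)
  if (!nrow(df)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- if (!is.null(df$name)) df$name else paste0("region_", seq_len(nrow(df)))
  sc <- if (!is.null(df$score)) df$score else 0
  out <- data.frame(df$chrom, df$start, df$end, nm,
                    ifelse(is.na(sc), 0, sc), df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write peaks as ENCODE narrowPeak
#'
#' @param gr A `GRanges` with the metadata columns produced by
#'   [read_intervals()] (missing ones are filled with the format's sentinel
#'   values: score 0, signalValue 0, p/qValue -1, summit -1).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(gr, path) {
  df <- as_bed_frame(gr)
  n <- nrow(df)
  if (!n) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  pick <- function(col, default) {
    v <- if (!is.null(df[[col]])) df[[col]] else rep(default, n)
    ifelse(is.na(v), default, v)
  }
  out <- data.frame(
    df$chrom, df$start, df$end,
    pick("name", paste0("peak_", seq_len(n))),
    pick("score", 0), df$strand,
    pick("signalValue", 0), pick("pValue", -1), pick("qValue", -1),
    pick("summit_offset", -1)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Stitch intervals separated by at most a maximum gap
#'
#' ROSE-style stitching: on each chromosome, intervals whose gap
#' (`next.start - prev.end` in 0-based half-open coordinates) is at most
#' `max_gap` are merged transitively into one region. `max_gap = 0` is the
#' classic overlapping/adjacent-interval merge. Strand is ignored.
#'
#' The output regions are pairwise separated by gaps strictly greater than
#' `max_gap`, their union equals the union of the inputs plus the swallowed
#' gaps, and the operation is idempotent and order-independent.
#'
#' @param gr A `GRanges`.
#' @param max_gap Maximum gap in bp allowed inside a stitched region
#'   (inclusive; "within 12.5 kb" means `max_gap = 12500`).
#' @return A sorted, unstranded `GRanges` of stitched regions with a
#'   `constituent_count` metadata column (number of input intervals merged).
#' @examples
#' gr <- genomic_intervals(c("c", "c"), c(0, 150), c(100, 200))
#' merge_within(gr, 50)   # one region [0, 200)
#' merge_within(gr, 49)   # two regions
#' @export
merge_within <- function(gr, max_gap) {
  stopifnot(max_gap >= 0)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                               ignore.strand = TRUE)
  red <- sort_intervals(red)
  S4Vectors::mcols(red)$constituent_count <-
    GenomicRanges::countOverlaps(red, gr, ignore.strand = TRUE)
  red
}

#' Pairwise interval overlap of at least a minimum width
#'
#' Element-wise test: `a[i]` and `b[i]` overlap on the same chromosome by at
#' least `min_bp` bases. Half-open adjacency (e.g. `[0,10)` vs `[10,20)`) is
#' not an overlap. Strand is ignored.
#'
#' @param a,b `GRanges` of equal length (or either of length 1, recycled).
#' @param min_bp Minimum overlap in bp (>= 1).
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  same & ov >= min_bp
}
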