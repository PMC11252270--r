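#' Annotate factor peaks to genes by TSS-window overlap
#'
#' A gene is occupied by a factor when any peak overlaps the window
#' `[tss - window, tss + window)` by at least 1 bp. The rule mirrors the
#' 50 kb proximity convention used for super-enhancer gene assignment;
#' `mode = "nearest"` instead assigns each peak to its single nearest TSS
#' (ChIPseeker-style convention) and keeps genes within the window.
#'
#' @param peaks Factor peak calls (`GRanges`).
#' @param genes Gene annotation (width-1 TSS `GRanges`).
#' @param window Window half-width in bp (> 0).
#' @param mode `"window"` (default) or `"nearest"`.
#' @return Sorted, deduplicated character vector of occupied gene_ids.
#' @export
annotate_peaks_to_genes <- function(peaks, genes, window = 50000,
                                    mode = c("window", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(window > 0)
  if (!length(peaks) || !length(genes)) return(character(0))
  ids <- S4Vectors::mcols(genes)$gene_id
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(genes) - window),
                     GenomicRanges::start(genes) + window - 1L)
  )
  if (mode == "window") {
    hits <- GenomicRanges::findOverlaps(win, peaks, ignore.strand = TRUE)
    return(sort(unique(ids[S4Vectors::queryHits(hits)])))
  }
  near <- GenomicRanges::nearest(peaks, genes, ignore.strand = TRUE)
  ok <- !is.na(near)
  ok[ok] <- IRanges::overlapsAny(peaks[ok], win[near[ok]],
                                       ignore.strand = TRUE)
  sort(unique(ids[near[ok]]))
}

#' Condition-dependent peaks (lost binding sites)
#'
#' Returns the peaks of the reference condition having no overlapping peak
#' (>= `min_overlap` bp) in the alternative condition — e.g. BRD4 binding
#' sites lost after ARID1A depletion. `dependent_peaks(x, x)` is empty and
#' `dependent_peaks(x, empty)` is `x`.
#'
#' @param peaks_ref Peaks in the reference condition (`GRanges`).
#' @param peaks_alt Peaks in the alternative condition (`GRanges`).
#' @param min_overlap Minimum overlap in bp counting as retained (>= 1).
#' @return The dependent subset of `peaks_ref`, metadata preserved.
#' @export
dependent_peaks <- function(peaks_ref, peaks_alt, min_overlap = 1L) {
  stopifnot(min_overlap >= 1)
  if (!length(peaks_alt)) return(peaks_ref)
  retained <- GenomicRanges::countOverlaps(peaks_ref, peaks_alt,
                                           minoverlap = min_overlap,
                                           ignore.strand = TRUE) > 0
  peaks_ref[!retained]
}

#' Nominate targets by set intersection
#'
#' Intersects the super-enhancer-associated gene set, the factor-occupied
#' gene set, and the differentially expressed genes of the requested
#' direction — the Venn-diagram logic nominating a lineage target. All
#' pairwise intersections are reported with cardinalities; the operation is
#' order-independent and idempotent.
#'
#' @param se_genes Character vector of SE-associated gene ids.
#' @param occupied_genes Character vector of factor-occupied gene ids.
#' @param deg A `MarkerResult` data.frame (from [cluster_markers()] or
#'   [condition_deg()]) or a data.frame with `gene_id`, `direction`,
#'   `passes` columns; only passing genes are used.
#' @param direction `"up"`, `"down"` or `"any"`.
#' @return A list of class `nomination` with the three input sets, all
#'   pairwise intersections, the triple intersection, cardinalities, and
#'   `nominated` (the triple intersection).
#' @examples
#' deg <- data.frame(gene_id = c("C", "E"), direction = "down", passes = TRUE)
#' nominate_targets(c("A", "B", "C"), c("B", "C", "D"), deg, "down")$nominated
#' @export
nominate_targets <- function(se_genes, occupied_genes, deg,
                             direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  if (is.data.frame(deg)) {
    keep <- if (is.null(deg$passes)) rep(TRUE, nrow(deg)) else deg$passes
    if (direction != "any") keep <- keep & deg$direction == direction
    deg_genes <- unique(as.character(deg$gene_id[keep]))
  } else {
    deg_genes <- unique(as.character(deg))
  }
  se_genes <- sort(unique(as.character(se_genes)))
  occupied_genes <- sort(unique(as.character(occupied_genes)))
  deg_genes <- sort(deg_genes)
  se_occ <- intersect(se_genes, occupied_genes)
  se_deg <- intersect(se_genes, deg_genes)
  occ_deg <- intersect(occupied_genes, deg_genes)
  triple <- intersect(se_occ, deg_genes)
  if (!length(se_occ) && !length(se_deg) && !length(occ_deg) &&
      length(se_genes) && length(occupied_genes) && length(deg_genes)) {
    warning("gene namespaces do not overlap; empty nomination")
  }
  structure(list(
    se_genes = se_genes, occupied_genes = occupied_genes,
    deg_genes = deg_genes, direction = direction,
    se_occ = se_occ, se_deg = se_deg, occ_deg = occ_deg,
    triple = triple, nominated = triple,
    cardinalities = c(
      n_se = length(se_genes), n_occupied = length(occupied_genes),
      n_deg = length(deg_genes), n_se_occ = length(se_occ),
      n_se_deg = length(se_deg), n_occ_deg = length(occ_deg),
      n_triple = length(triple)
    )
  ), class = "nomination")
}

#' @export
print.nomination <- function(x, ...) {
  k <- x$cardinalities
  cat(sprintf(
    "nomination (direction=%s): |SE|=%d |occupied|=%d |DEG|=%d; |SE∩occ|=%d; triple=%d\n",
    x$direction, k["n_se"], k["n_occupied"], k["n_deg"], k["n_se_occ"],
    k["n_triple"]))
  if (length(x$nominated))
    cat("nominated:", paste(x$nominated, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a nomination as JSON
#'
#' @param x A `nomination`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nomination_json <- function(x, path) {
  jsonlite::write_json(
    list(direction = x$direction,
         cardinalities = as.list(x$cardinalities),
         se_occ = x$se_occ, se_deg = x$se_deg, occ_deg = x$occ_deg,
         nominated = x$nominated),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
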