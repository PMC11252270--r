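#' Marker / differential-expression criterion
#'
#' The cluster-restricted criterion used throughout: a gene passes when it
#' is at least `min_fold`-fold over- (or under-) expressed, expressed in
#' more than `min_pct` of the cells of the overexpressing group, and its
#' rank-sum p-value is below `max_p`. Defaults are 1.28-fold, 25%, p < 0.01
#' on raw (uncorrected) p-values; `adjust = "BH"` switches to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param min_fold Minimum fold change (> 1).
#' @param min_pct Minimum expressing-cell fraction (in (0,1), strict >).
#' @param max_p P-value threshold (in (0,1), strict <).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param pct_group Which group the expressing-fraction filter applies to:
#'   `"higher"` (default; the overexpressing group, which for upregulated
#'   markers is the target group and keeps the criterion antisymmetric
#'   under label swap) or `"target"` (always the target group).
#' @return A list of class `marker_criterion`.
#' @export
marker_criterion <- function(min_fold = 1.28, min_pct = 0.25, max_p = 0.01,
                             adjust = c("none", "BH"),
                             pct_group = c("higher", "target")) {
  stopifnot(min_fold > 1, min_pct > 0, min_pct < 1, max_p > 0, max_p < 1)
  structure(list(min_fold = min_fold, min_pct = min_pct, max_p = max_p,
                 adjust = match.arg(adjust),
                 pct_group = match.arg(pct_group)),
            class = "marker_criterion")
}

#' Library-size normalize and log-transform counts
#'
#' Scales each cell to a common target library size, then applies
#' `log1p`. Deterministic; an all-zero cell gets size factor 1 (with a
#' warning) rather than dividing by zero.
#'
#' @param counts genes x cells matrix (base or `Matrix` sparse),
#'   non-negative counts.
#' @param target_sum Common post-scaling library size (default 1e4).
#' @return A matrix of the same class and dimnames, log1p of the scaled
#'   counts.
#' @export
normalize_counts <- function(counts, target_sum = 1e4) {
  if (nrow(counts) < 1 || ncol(counts) < 1) stop("empty count matrix")
  libs <- Matrix::colSums(counts)
  zero <- libs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s): size factor set to 1")
    libs[zero] <- target_sum
  }
  sf <- libs / target_sum
  if (inherits(counts, "sparseMatrix")) {
    scaled <- counts %*% Matrix::Diagonal(x = 1 / sf)
    dimnames(scaled) <- dimnames(counts)
    out <- scaled
    out@x <- log1p(out@x)
    out
  } else {
    log1p(sweep(counts, 2, sf, "/"))
  }
}

# Vectorised two-sided Wilcoxon rank-sum over matrix rows: normal
# approximation with tie correction and continuity correction, matching
# stats::wilcox.test(exact = FALSE, correct = TRUE).
rank_sum_rows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  sub <- mat[, c(idx1, idx2), drop = FALSE]
  vapply(seq_len(nrow(sub)), function(i) {
    x <- sub[i, ]
    r <- rank(x)
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tab <- table(x)
    tie <- sum(tab^3 - tab)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- W - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
}

marker_table <- function(counts, norm, idx_t, idx_r, criterion) {
  m_t <- Matrix::rowMeans(expm1(norm[, idx_t, drop = FALSE]))
  m_r <- Matrix::rowMeans(expm1(norm[, idx_r, drop = FALSE]))
  fold <- (m_t + 1) / (m_r + 1)
  pct_t <- Matrix::rowMeans(counts[, idx_t, drop = FALSE] > 0)
  pct_r <- Matrix::rowMeans(counts[, idx_r, drop = FALSE] > 0)
  p <- rank_sum_rows(as.matrix(norm), idx_t, idx_r)
  p_use <- if (criterion$adjust == "BH") stats::p.adjust(p, "BH") else p
  pct_use <- if (criterion$pct_group == "target") pct_t else
    ifelse(fold >= 1, pct_t, pct_r)
  direction <- ifelse(fold >= 1, "up", "down")
  fold_ok <- fold >= criterion$min_fold | fold <= 1 / criterion$min_fold
  passes <- fold_ok & pct_use > criterion$min_pct & p_use < criterion$max_p
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("gene_%05d", seq_len(nrow(counts)))
  data.frame(gene_id = ids, fold_change = fold,
             pct_target = pct_t, pct_rest = pct_r,
             p_value = p, p_used = p_use,
             direction = direction, passes = passes,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster marker genes by the fold / percent-expressing / rank-sum rule
#'
#' For every gene, compares the target cluster against all other cells:
#' fold change is the ratio of mean `expm1` log-normalized expression
#' (pseudocount 1 in numerator and denominator), `pct_target`/`pct_rest`
#' are the expressing-cell fractions (count > 0), and the p-value is a
#' two-sided Wilcoxon rank-sum on normalized expression.
#'
#' @param counts genes x cells count matrix, with gene ids as rownames.
#' @param clusters Cluster label per cell (length `ncol(counts)`).
#' @param target_cluster The cluster to profile (>= 3 cells).
#' @param criterion A [marker_criterion()].
#' @param norm Optional pre-computed [normalize_counts()] output.
#' @return A `MarkerResult` data.frame: `gene_id`, `fold_change`,
#'   `pct_target`, `pct_rest`, `p_value`, `p_used`, `direction`, `passes`.
#' @export
cluster_markers <- function(counts, clusters, target_cluster,
                            criterion = marker_criterion(), norm = NULL) {
  stopifnot(length(clusters) == ncol(counts))
  clusters <- as.character(clusters)
  if (!target_cluster %in% clusters) {
    stop("cluster '", target_cluster, "' not found; available: ",
         paste(sort(unique(clusters)), collapse = ", "))
  }
  idx_t <- which(clusters == target_cluster)
  if (length(idx_t) < 3) stop("target cluster has fewer than 3 cells")
  idx_r <- which(clusters != target_cluster)
  if (is.null(norm)) norm <- normalize_counts(counts)
  marker_table(counts, norm, idx_t, idx_r, criterion)
}

#' Condition differential expression within a cluster
#'
#' Restricts to the cells of one cluster and applies the marker machinery
#' with groups given by condition: fold change is
#' `condition_pair[2] / condition_pair[1]` (e.g. knockout over control), so
#' `direction = "up"` means higher in the second condition. Swapping the
#' pair swaps the up and down lists exactly.
#'
#' @param counts genes x cells count matrix.
#' @param clusters Cluster label per cell.
#' @param conditions Condition label per cell.
#' @param cluster Cluster to restrict to.
#' @param condition_pair Length-2 character: (reference, treatment); both
#'   need >= 3 cells within the cluster.
#' @param criterion A [marker_criterion()].
#' @return A list with `all` (the full `MarkerResult` data.frame), `up` and
#'   `down` (the passing subsets by direction).
#' @export
condition_deg <- function(counts, clusters, conditions, cluster,
                          condition_pair, criterion = marker_criterion()) {
  stopifnot(length(clusters) == ncol(counts),
            length(conditions) == ncol(counts),
            length(condition_pair) == 2)
  in_cl <- as.character(clusters) == as.character(cluster)
  if (!any(in_cl)) stop("cluster '", cluster, "' not found")
  cond <- as.character(conditions)
  idx_t <- which(in_cl & cond == condition_pair[2])
  idx_r <- which(in_cl & cond == condition_pair[1])
  if (length(idx_t) < 3 || length(idx_r) < 3) {
    stop("each condition needs >= 3 cells within cluster '", cluster, "'")
  }
  sub <- counts[, c(idx_r, idx_t), drop = FALSE]
  norm <- normalize_counts(sub)
  n_r <- length(idx_r)
  tab <- marker_table(sub, norm, n_r + seq_along(idx_t), seq_len(n_r),
                      criterion)
  list(all = tab,
       up = tab[tab$passes & tab$direction == "up", , drop = FALSE],
       down = tab[tab$passes & tab$direction == "down", , drop = FALSE])
}

#' Read a sparse count matrix with cell metadata sidecars
#'
#' MatrixMarket `matrix.mtx` plus `genes.tsv` (gene_id, one per row) and
#' `cells.tsv` (tab-separated with header: `cell`, `cluster`, `condition`).
#'
#' @param dir Directory containing the three files.
#' @return A list with `counts` (dgCMatrix, gene ids as rownames, cell ids
#'   as colnames) and `cells` (data.frame).
#' @export
read_count_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts))
    stop("sidecar dimensions do not match matrix.mtx")
  rownames(counts) <- genes[[1]]
  colnames(counts) <- cells$cell
  list(counts = counts, cells = cells)
}

#' Write a sparse count matrix with sidecars
#'
#' @param counts genes x cells matrix with dimnames.
#' @param cells data.frame with columns `cell`, `cluster`, `condition`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(counts, cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(counts, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(counts)),
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
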