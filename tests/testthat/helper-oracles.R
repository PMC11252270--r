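# Independent oracles used across the suite. Each recomputes a quantity by a
# route different from the implementation under test.

# Transitive-closure stitching oracle: build the pairwise adjacency graph
# (same chromosome, gap <= max_gap in 0-based half-open coordinates) and take
# its connected components.
brute_merge_oracle <- function(chrom, start0, end0, max_gap) {
  n <- length(start0)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    chrom[i] == chrom[j] &
      pmax(start0[i], start0[j]) - pmin(end0[i], end0[j]) <= max_gap
  })
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  )$membership
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    data.frame(chrom = chrom[idx[1]], start = min(start0[idx]),
               end = max(end0[idx]), n = length(idx))
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Tangent-scan oracle for the rank-curve cutoff: scan every candidate point
# and test the slope-1 tangency condition directly (the line of slope 1
# through the candidate must leave every scaled point on or above it); the
# cutoff is the largest feasible candidate. Degenerate when no point lies
# below the diagonal.
tangent_scan_oracle <- function(signals) {
  n <- length(signals)
  s <- sort(signals)
  x <- (seq_len(n) - 1) / (n - 1)
  if (s[n] == s[1]) return(list(cutoff = n, degenerate = TRUE))
  y <- (s - s[1]) / (s[n] - s[1])
  eps <- 1e-12
  feasible <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in seq_len(n)) {
      if (y[j] - x[j] < (y[i] - x[i]) - eps) { ok <- FALSE; break }
    }
    feasible[i] <- ok
  }
  cutoff <- max(which(feasible))
  degenerate <- all(y - x >= -eps)
  list(cutoff = cutoff, degenerate = degenerate)
}

# Per-base expansion oracle for background-subtracted rpm over one region
# given bedGraph-style data frames (0-based half-open, columns start, end,
# value).
per_base_signal_oracle <- function(region_start0, region_end0,
                                   chip_df, chip_lib, input_df, input_lib) {
  depth_at <- function(df, pos) {
    v <- 0
    for (k in seq_len(nrow(df))) {
      if (pos >= df$start[k] && pos < df$end[k]) v <- df$value[k]
    }
    v
  }
  total <- 0
  for (pos in seq(region_start0, region_end0 - 1)) {
    total <- total + depth_at(chip_df, pos) / chip_lib * 1e6 -
      depth_at(input_df, pos) / input_lib * 1e6
  }
  max(0, total)
}

# random interval landscape on one chromosome (0-based half-open)
random_landscape <- function(n, span = 10000, max_w = 400, chrom = "c") {
  s <- sample.int(span, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = chrom, start = s, end = s + w,
             stringsAsFactors = FALSE)
}
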