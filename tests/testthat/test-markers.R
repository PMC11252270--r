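test_that("normalization scales cells to the target sum then log1p", {
  m <- matrix(c(2, 0, 8), nrow = 3,
              dimnames = list(c("a", "b", "c"), "cell1"))
  norm <- normalize_counts(m, target_sum = 10)
  expect_equal(norm[, 1], log1p(c(a = 2, b = 0, c = 8)))
  # doubling a cell's counts leaves its normalized vector unchanged
  norm2 <- normalize_counts(2 * m, target_sum = 10)
  expect_equal(norm2, norm)
  # column sums pre-log all equal the target
  set.seed(1)
  big <- matrix(rpois(600, 4), nrow = 30)
  expect_equal(colSums(expm1(normalize_counts(big, 1e4))),
               rep(1e4, 20), tolerance = 1e-9)
  # sparse and dense paths agree
  sp <- normalize_counts(Matrix::Matrix(big, sparse = TRUE), 1e4)
  expect_equal(as.matrix(sp), normalize_counts(big, 1e4),
               ignore_attr = TRUE)
  expect_warning(normalize_counts(cbind(big, 0)), "all-zero")
})

test_that("matrix rank-sum p-values match stats::wilcox.test", {
  set.seed(2)
  # include heavy ties (counts) and continuous values
  m <- rbind(matrix(rpois(5 * 60, 1.5), nrow = 5),
             matrix(rnorm(5 * 60), nrow = 5))
  i1 <- 1:25; i2 <- 26:60
  got <- secanalyze:::rank_sum_rows(m, i1, i2)
  want <- apply(m, 1, function(x) {
    stats::wilcox.test(x[i1], x[i2], exact = FALSE, correct = TRUE)$p.value
  })
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("rank-sum p-values are invariant to monotone transformations", {
  set.seed(4)
  m <- matrix(rpois(10 * 80, 3), nrow = 10)
  p1 <- secanalyze:::rank_sum_rows(m, 1:30, 31:80)
  p2 <- secanalyze:::rank_sum_rows(sqrt(m + 1), 1:30, 31:80)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("a gene identical in both groups has fold 1 and fails", {
  # equal library sizes: a constant gene has exactly equal normalized
  # expression in both groups
  counts <- matrix(3, nrow = 5, ncol = 200,
                   dimnames = list(sprintf("g%02d", 1:5), NULL))
  cl <- rep(c("t", "r"), c(50, 150))
  res <- cluster_markers(counts, cl, "t")
  expect_equal(res$fold_change, rep(1, 5), tolerance = 1e-12)
  expect_false(any(res$passes))
  # with unequal libraries the fold stays within sampling noise of 1
  set.seed(5)
  counts2 <- matrix(rpois(40 * 200, 2), nrow = 40,
                    dimnames = list(sprintf("g%02d", 1:40), NULL))
  counts2[1, ] <- 3
  res2 <- cluster_markers(counts2, cl, "t")
  expect_equal(res2$fold_change[1], 1, tolerance = 0.05)
  expect_false(res2$passes[1])
})

test_that("a planted high-fold marker passes the default criterion", {
  set.seed(1)
  n_t <- 200; n_r <- 800
  counts <- matrix(rpois(60 * (n_t + n_r), 1), nrow = 60,
                   dimnames = list(sprintf("g%02d", 1:60), NULL))
  counts[1, 1:n_t] <- rpois(n_t, 8)   # NB-like planted marker, mean 8 vs 1
  cl <- rep(c("target", "rest"), c(n_t, n_r))
  res <- cluster_markers(counts, cl, "target")
  expect_true(res$passes[1])
  expect_equal(res$direction[1], "up")
  expect_gt(res$fold_change[1], 1.28)
  expect_gt(res$pct_target[1], 0.25)
  expect_lt(res$p_value[1], 0.01)
})

test_that("an absent cluster raises an error naming the available ones", {
  counts <- matrix(rpois(20, 2), nrow = 4)
  expect_error(cluster_markers(counts, rep(c("a", "b"), c(2, 3)), "zz"),
               "available.*a, b")
})

test_that("condition DEG is antisymmetric under label swap", {
  sim <- simulate_counts(sprintf("g%03d", 1:150), n_cells_target = 120,
                         n_cells_rest = 100,
                         deg_up = sprintf("g%03d", 1:10),
                         deg_down = sprintf("g%03d", 11:20),
                         deg_fold = 3, seed = 8)
  fwd <- condition_deg(sim$counts, sim$cells$cluster, sim$cells$condition,
                       "c4", c("ctrl", "ko"))
  rev <- condition_deg(sim$counts, sim$cells$cluster, sim$cells$condition,
                       "c4", c("ko", "ctrl"))
  expect_equal(fwd$all$fold_change, 1 / rev$all$fold_change,
               tolerance = 1e-9)
  expect_setequal(fwd$up$gene_id, rev$down$gene_id)
  expect_setequal(fwd$down$gene_id, rev$up$gene_id)
})

test_that("planted symmetric condition effects are recovered with few false positives", {
  ids <- sprintf("g%04d", 1:600)
  up <- ids[1:50]; down <- ids[51:100]
  sim <- simulate_counts(ids, n_cells_target = 600, n_cells_rest = 50,
                         deg_up = up, deg_down = down, deg_fold = 2,
                         seed = 12)
  res <- condition_deg(sim$counts, sim$cells$cluster, sim$cells$condition,
                       "c4", c("ctrl", "ko"))
  expect_gte(mean(up %in% res$up$gene_id), 0.90)
  expect_gte(mean(down %in% res$down$gene_id), 0.90)
  null_ids <- ids[101:600]
  fp <- sum(null_ids %in% c(res$up$gene_id, res$down$gene_id))
  expect_lte(fp / length(null_ids), 0.01)
})

test_that("identical conditions yield (near-)empty DEG lists", {
  sim <- simulate_counts(sprintf("g%03d", 1:300), n_cells_target = 300,
                         n_cells_rest = 20, seed = 30)
  res <- condition_deg(sim$counts, sim$cells$cluster, sim$cells$condition,
                       "c4", c("ctrl", "ko"))
  expect_lte(nrow(res$up) + nrow(res$down), ceiling(0.01 * 300))
})

test_that("a condition with too few cells in the cluster errors", {
  counts <- matrix(rpois(10 * 10, 2), nrow = 10)
  cl <- rep("c4", 10)
  cond <- rep(c("ctrl", "ko"), c(8, 2))
  expect_error(condition_deg(counts, cl, cond, "c4", c("ctrl", "ko")),
               ">= 3 cells")
})

test_that("count matrices round-trip through MTX with sidecars", {
  sim <- simulate_counts(sprintf("g%03d", 1:40), n_cells_target = 12,
                         n_cells_rest = 8, seed = 2)
  d <- tempfile()
  write_count_matrix(sim$counts, sim$cells, d)
  back <- read_count_matrix(d)
  expect_equal(as.matrix(back$counts), as.matrix(sim$counts))
  expect_equal(back$cells$cluster, sim$cells$cluster)
  expect_equal(back$cells$condition, sim$cells$condition)
})
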