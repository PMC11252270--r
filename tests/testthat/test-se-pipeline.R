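make_track <- function(chrom, start0, end0, value, lib) {
  gr <- genomic_intervals(chrom, start0, end0)
  S4Vectors::mcols(gr)$score <- value
  coverage_track(gr, lib)
}

test_that("promoter exclusion drops only fully contained peaks", {
  genes <- gene_annotation("g1", "c", tss = 10200)
  contained <- genomic_intervals("c", 10000, 10400)
  partial <- genomic_intervals("c", 7000, 13000)
  expect_length(exclude_promoter_regions(contained, genes, 2500), 0L)
  expect_length(exclude_promoter_regions(partial, genes, 2500), 1L)
  # any-overlap mode drops the partial one too
  expect_length(exclude_promoter_regions(partial, genes, 2500, mode = "any"),
                0L)
  expect_warning(out <- exclude_promoter_regions(contained,
                                                 genes[0], 2500),
                 "empty gene")
  expect_length(out, 1L)
})

test_that("promoter exclusion equals the all-pairs containment oracle", {
  set.seed(11)
  for (rep in 1:5) {
    pk <- random_landscape(50, span = 60000, max_w = 3000)
    tss <- sample.int(60000, 12) - 1L
    genes <- gene_annotation(sprintf("g%02d", seq_along(tss)), "c", tss)
    flank <- 2500
    keep_oracle <- vapply(seq_len(nrow(pk)), function(i) {
      !any(pk$start[i] >= tss - flank & pk$end[i] <= tss + flank)
    }, logical(1))
    got <- exclude_promoter_regions(
      genomic_intervals(pk$chrom, pk$start, pk$end), genes, flank)
    expect_equal(as_bed_frame(got)$start, pk$start[keep_oracle])
    expect_equal(as_bed_frame(got)$end, pk$end[keep_oracle])
  }
})

test_that("region signal follows the closed form and floors at zero", {
  chip <- make_track("c", 0, 1000, 2, 1e6)
  region <- genomic_intervals("c", 100, 200)
  expect_equal(quantify_region_signal(region, chip), 200)
  # input exceeding chip floors to 0
  input <- make_track("c", 0, 1000, 5, 1e6)
  expect_equal(quantify_region_signal(region, chip, input), 0)
  # chromosome absent from both tracks: zero with warning
  off <- genomic_intervals("other", 0, 100)
  expect_warning(v <- quantify_region_signal(off, chip, input), "absent")
  expect_equal(v, 0)
})

test_that("piecewise-track signal matches the per-base expansion oracle", {
  set.seed(7)
  for (rep in 1:4) {
    # non-overlapping piecewise chip and input segments
    cuts_c <- sort(sample(0:500, 8))
    chip_df <- data.frame(start = cuts_c[seq(1, 7, 2)],
                          end = cuts_c[seq(2, 8, 2)],
                          value = round(stats::runif(4, 0, 5), 2))
    cuts_i <- sort(sample(0:500, 6))
    input_df <- data.frame(start = cuts_i[seq(1, 5, 2)],
                           end = cuts_i[seq(2, 6, 2)],
                           value = round(stats::runif(3, 0, 2), 2))
    chip <- make_track("c", chip_df$start, chip_df$end, chip_df$value, 2e6)
    input <- make_track("c", input_df$start, input_df$end, input_df$value, 1e6)
    region <- genomic_intervals("c", 30, 470)
    want <- per_base_signal_oracle(30, 470, chip_df, 2e6, input_df, 1e6)
    expect_equal(quantify_region_signal(region, chip, input), want,
                 tolerance = 1e-12)
  }
})

test_that("per-bp flooring never yields less than per-region flooring", {
  chip <- make_track("c", c(0, 100), c(100, 200), c(3, 0.5), 1e6)
  input <- make_track("c", c(0, 100), c(100, 200), c(1, 2), 1e6)
  region <- genomic_intervals("c", 0, 200)
  per_region <- quantify_region_signal(region, chip, input)
  per_bp <- quantify_region_signal(region, chip, input, floor = "per_bp")
  expect_equal(per_region, 50)         # (300 + 50) - (100 + 200), floored sum
  expect_equal(per_bp, 200)            # max(0, 2)*100 + max(0, -1.5)*100
  expect_gte(per_bp, per_region)
})

test_that("inflection cutoff isolates an extreme point and flags linear curves", {
  res <- call_superenhancers(signal_rpm = c(1, 1, 1, 1, 100))
  expect_equal(res$n_super, 1L)
  expect_true(res$enhancers$is_super[5])
  expect_false(res$degenerate)

  lin <- call_superenhancers(signal_rpm = c(1, 2, 3, 4, 5))
  expect_equal(lin$n_super, 0L)
  expect_true(lin$degenerate)

  flat <- call_superenhancers(signal_rpm = rep(2, 6))
  expect_equal(flat$n_super, 0L)
  expect_true(flat$degenerate)

  expect_error(call_superenhancers(signal_rpm = c(1, 2)), "at least 3")
  expect_error(call_superenhancers(signal_rpm = c(1, 2, NA)), "finite")
})

test_that("cutoff is invariant to positive scaling of the signals", {
  set.seed(3)
  for (rep in 1:10) {
    s <- c(rexp(40), rexp(5) + 8)
    a <- call_superenhancers(signal_rpm = s)
    b <- call_superenhancers(signal_rpm = s * 137.5)
    expect_equal(a$cutoff_rank, b$cutoff_rank)
    expect_equal(a$enhancers$is_super, b$enhancers$is_super)
  }
})

test_that("adding a below-minimum enhancer rarely removes existing SE calls", {
  set.seed(5)
  violations <- 0L
  for (rep in 1:200) {
    s <- c(rexp(60), rexp(4) + 6)
    before <- call_superenhancers(signal_rpm = s)
    idx_before <- order(s)[before$enhancers$is_super]
    s2 <- c(s, min(s) / 2)
    after <- call_superenhancers(signal_rpm = s2)
    idx_after <- order(s2)[after$enhancers$is_super]
    if (!all(idx_before %in% idx_after)) violations <- violations + 1L
  }
  expect_lte(violations / 200, 0.01)
})

test_that("gene assignment respects the window, measured from region edges", {
  se <- genomic_intervals("c", 100000, 120000)
  g_in <- gene_annotation("gin", "c", 160000, active = TRUE)
  g_out <- gene_annotation("gout", "c", 170001, active = TRUE)
  g_edge <- gene_annotation("gedge", "c", 169999, active = TRUE)
  g_inactive <- gene_annotation("gi", "c", 100500, active = FALSE)
  expect_equal(assign_genes_to_ses(se, g_in, 50000)$genes, "gin")
  expect_equal(assign_genes_to_ses(se, g_out, 50000)$genes, character(0))
  expect_equal(assign_genes_to_ses(se, g_edge, 50000)$genes, "gedge")
  expect_equal(assign_genes_to_ses(se, g_inactive, 50000)$genes, character(0))
})

test_that("the SE pipeline recovers planted loci and is byte-deterministic", {
  anno <- simulate_annotation(seed = 1)
  land <- simulate_enhancer_landscape(anno, seed = 7)
  res <- run_se_pipeline(land$peaks, anno$genes, land$chip, land$input)
  expect_equal(res$se_call$n_enhancers, 420L)
  # every planted locus stitched into exactly one region
  planted <- land$truth$planted_se_loci
  pl_gr <- genomic_intervals(
    vapply(planted, `[[`, "", "chrom"),
    vapply(planted, function(x) x$start, numeric(1)),
    vapply(planted, function(x) x$end, numeric(1)))
  expect_true(all(GenomicRanges::countOverlaps(pl_gr, res$stitched) == 1))
  hit <- GenomicRanges::countOverlaps(pl_gr, res$se_regions) > 0
  expect_gte(sum(hit), 19L)
  # planted SE-associated genes recovered through the 50 kb rule
  genes_true <- vapply(planted, `[[`, "", "gene_id")
  expect_gte(mean(genes_true %in% res$assignment$genes), 0.95)

  d1 <- tempfile(); d2 <- tempfile()
  run_se_pipeline(land$peaks, anno$genes, land$chip, land$input,
                  out_dir = d1)
  run_se_pipeline(land$peaks, anno$genes, land$chip, land$input,
                  out_dir = d2)
  for (f in c("stitched.bed", "superenhancers.bed", "ranked_signal.tsv",
              "se_genes.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("an empty peak set yields an empty result without crashing", {
  anno <- simulate_annotation(seed = 1)
  land <- simulate_enhancer_landscape(anno, seed = 7)
  res <- run_se_pipeline(land$peaks[0], anno$genes, land$chip, land$input,
                         out_dir = tempfile())
  expect_null(res$se_call)
  expect_length(res$se_regions, 0L)
  expect_equal(res$assignment$genes, character(0))
})

test_that("signal is additive over a partition when input is zero", {
  chip <- make_track("c", c(0, 300, 700), c(300, 640, 1000),
                     c(1.5, 0.25, 3), 1e6)
  whole <- genomic_intervals("c", 0, 1000)
  parts <- genomic_intervals("c", c(0, 250, 611), c(250, 611, 1000))
  expect_equal(sum(quantify_region_signal(parts, chip)),
               quantify_region_signal(whole, chip))
})
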