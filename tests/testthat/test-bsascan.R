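test_that("SNP-index is the mutant-allele read fraction with a depth sentinel", {
  expect_equal(snp_index(10, 10), 1.0)
  expect_equal(snp_index(0, 12), 0.0)
  expect_equal(snp_index(6, 12), 0.5)
  expect_true(is.na(snp_index(0, 0)))
  expect_error(snp_index(5, 3), "exceed")
})

test_that("delta-SNP-index is the between-bulk index difference", {
  tab <- snp_table(chrom = "chr1", pos = c(100, 200, 300),
                   ref = "G", alt = "A",
                   parentA_gt = "hom_alt", parentA_dp = 10,
                   parentB_gt = "hom_ref", parentB_dp = 10,
                   mut_bulk_alt = c(12, 6, 3), mut_bulk_dp = c(12, 12, 12),
                   wt_bulk_alt = c(0, 6, 0), wt_bulk_dp = c(12, 12, 0))
  tr <- delta_snp_index(tab)
  expect_equal(tr$delta[1], 1.0)
  expect_equal(tr$delta[2], 0.0)
  expect_true(is.na(tr$delta[3]))      # zero-depth bulk excluded
  expect_equal(tr$abs_delta, abs(tr$delta))
})

test_that("LOESS reproduces constants and straight lines", {
  n <- 120
  pos <- sort(sample.int(1e6, n))
  tr <- data.frame(chrom = "chr1", pos = pos,
                   index_mut = 0.4, index_wt = 0,
                   delta = 0.4, abs_delta = 0.4)
  f <- loess_fit_track(tr)
  expect_equal(f$fitted, rep(0.4, n), tolerance = 1e-8)
  # linear in position, degree 1
  v <- 0.1 + 0.6 * (pos - pos[1]) / (pos[n] - pos[1])
  tr$abs_delta <- v
  f2 <- loess_fit_track(tr, degree = 1, iterations = 0)
  expect_equal(f2$fitted, v, tolerance = 1e-6)
})

test_that("LOESS is equivariant to adding a constant", {
  set.seed(3)
  n <- 150
  pos <- sort(sample.int(1e6, n))
  v <- 0.2 + 0.1 * sin(pos / 5e4) + rnorm(n, 0, 0.02)
  mk <- function(vals) data.frame(chrom = "chr1", pos = pos, index_mut = NA,
                                  index_wt = NA, delta = vals,
                                  abs_delta = vals)
  f0 <- loess_fit_track(mk(v), iterations = 0)$fitted
  f1 <- loess_fit_track(mk(v + 0.3), iterations = 0)$fitted
  expect_equal(f1, f0 + 0.3, tolerance = 1e-8)
})

test_that("smoothing never crosses chromosome boundaries", {
  pos <- seq(1e4, 1e6, length.out = 60)
  tr <- data.frame(chrom = rep(c("chr1", "chr2"), each = 60),
                   pos = rep(pos, 2), index_mut = NA, index_wt = NA,
                   delta = rep(c(0.8, 0.1), each = 60),
                   abs_delta = rep(c(0.8, 0.1), each = 60))
  f <- loess_fit_track(tr, span = 0.3)
  expect_equal(f$fitted[f$chrom == "chr1"], rep(0.8, 60), tolerance = 1e-8)
  expect_equal(f$fitted[f$chrom == "chr2"], rep(0.1, 60), tolerance = 1e-8)
})

test_that("chromosomes with too few informative loci are skipped with a warning", {
  tr <- data.frame(chrom = "chr1", pos = c(1, 2, 3), index_mut = NA,
                   index_wt = NA, delta = c(.1, .2, .3),
                   abs_delta = c(.1, .2, .3))
  expect_warning(f <- loess_fit_track(tr), "too few")
  expect_true(all(is.na(f$fitted)))
})

test_that("candidate regions are disjoint, sorted and above threshold", {
  cfg <- sim_config(seed = 21)
  pop <- simulate_f2_population(cfg)
  b <- build_bulks(pop)
  tr <- loess_fit_track(delta_snp_index(simulate_bulk_readcounts(pop, b)))
  reg <- call_candidate_regions(tr)
  expect_gt(nrow(reg), 0)
  expect_true(all(reg$peak_fitted >= reg$threshold))
  expect_true(all(reg$start <= reg$peak_pos & reg$peak_pos <= reg$end))
  by_chr <- split(reg, reg$chrom)
  for (r in by_chr) {
    if (nrow(r) > 1) expect_true(all(utils::head(r$end, -1) < utils::tail(r$start, -1)))
  }
})

test_that("a single locus above threshold yields a point region", {
  # the empirical 99.9th percentile of 200 values with one spike falls
  # between the spike and the plateau, leaving a single qualifying locus
  tr <- data.frame(chrom = "chr1", pos = seq_len(200) * 1000,
                   index_mut = NA, index_wt = NA, delta = 0,
                   abs_delta = 0, fitted = c(rep(0.1, 100), 0.9, rep(0.1, 99)))
  reg <- call_candidate_regions(tr, quantile = 0.999)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, reg$end)
  expect_equal(reg$peak_pos, 101 * 1000)
})

test_that("an all-tied track degenerates to flagged whole-chromosome regions", {
  tr <- data.frame(chrom = rep(c("chr1", "chr2"), each = 50),
                   pos = rep(seq_len(50) * 1000, 2), index_mut = NA,
                   index_wt = NA, delta = 0.3, abs_delta = 0.3,
                   fitted = 0.3)
  expect_warning(reg <- call_candidate_regions(tr), "degenerate")
  expect_true(all(reg$degenerate))
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(1000, 1000))
  expect_equal(reg$end, c(50000, 50000))
})

test_that("with no causal locus the flagged fraction matches the quantile", {
  cfg <- sim_config(causal_chrom = NA, causal_pos = NA, seed = 31)
  pop <- simulate_f2_population(cfg)
  b <- build_bulks(pop)
  tr <- loess_fit_track(delta_snp_index(simulate_bulk_readcounts(pop, b)))
  reg <- call_candidate_regions(tr, quantile = 0.99)
  inside <- sum(vapply(seq_len(nrow(tr)), function(i) {
    any(reg$chrom == tr$chrom[i] & reg$start <= tr$pos[i] & reg$end >= tr$pos[i])
  }, logical(1)))
  expect_lt(inside / nrow(tr), 0.05)
})

test_that("permutation null maxima sit below the causal-scan peak", {
  cfg <- sim_config(seed = 41)
  pop <- simulate_f2_population(cfg)
  b <- build_bulks(pop)
  tr <- loess_fit_track(delta_snp_index(simulate_bulk_readcounts(pop, b)))
  nulls <- permutation_null_max(pop, n_perm = 5)
  expect_length(nulls, 5)
  expect_true(all(nulls < max(tr$fitted, na.rm = TRUE)))
})
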