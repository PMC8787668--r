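test_that("config validation rejects impossible study designs", {
  expect_error(sim_config(n_f2 = 0), "n_f2")
  expect_error(sim_config(bulk_size = 200, n_f2 = 300), "bulk_size")
  expect_error(sim_config(causal_chrom = "chrX"), "declared chromosome")
  expect_error(sim_config(depth_lambda = 0), "depth_lambda")
  expect_error(sim_config(chromosomes = data.frame(name = "chr1", length = 0)),
               "lengths")
})

test_that("F2 genotypes segregate 1:2:1 and phenotypes 3:1", {
  cfg <- sim_config(n_f2 = 10000, snps_per_chrom = 20, seed = 11)
  pop <- simulate_f2_population(cfg)
  # any locus: AA:Aa:aa within 3 SE of 0.25/0.5/0.25
  for (row in c(1, 10, 25)) {
    fr <- tabulate(pop$geno[row, ] + 1L, 3) / cfg$n_f2
    se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / cfg$n_f2)
    expect_true(all(abs(fr - c(.25, .5, .25)) < 3 * se))
  }
  ct <- table(factor(pop$phenotype, c("speltoid", "normal")))
  expect_gt(chi_square_segregation(ct[[1]], ct[[2]])$p_value, 0.05)
})

test_that("without recombination genotypes are constant along chromosomes", {
  cfg <- sim_config(n_f2 = 50, bulk_size = 10, snps_per_chrom = 30,
                    cm_per_mb = 0, seed = 2)
  pop <- simulate_f2_population(cfg)
  for (chr in unique(pop$snp_map$chrom)) {
    g <- pop$geno[pop$snp_map$chrom == chr, , drop = FALSE]
    expect_true(all(apply(g, 2, function(x) length(unique(x)) == 1)))
  }
})

test_that("population simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_f2 = 100, snps_per_chrom = 50, seed = 7)
  p1 <- simulate_f2_population(cfg)
  p2 <- simulate_f2_population(cfg)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$phenotype, p2$phenotype)
})

test_that("bulks are pure, disjoint, sized exactly and reproducible", {
  cfg <- sim_config(n_f2 = 300, seed = 5)
  pop <- simulate_f2_population(cfg)
  b1 <- build_bulks(pop)
  b2 <- build_bulks(pop)
  expect_identical(b1, b2)
  expect_length(b1$mutant_bulk, 50)
  expect_length(b1$wt_bulk, 50)
  expect_length(intersect(b1$mutant_bulk, b1$wt_bulk), 0)
  expect_true(all(pop$phenotype[b1$mutant_bulk] == "speltoid"))
  expect_true(all(pop$phenotype[b1$wt_bulk] == "normal"))
})

test_that("a phenotype deficit aborts bulk construction with a named count", {
  cfg <- sim_config(n_f2 = 120, bulk_size = 50, seed = 5)
  pop <- simulate_f2_population(cfg)
  # ~30 normals expected out of 120; not enough for a 50-plant bulk
  expect_error(build_bulks(pop), "insufficient normal")
})

test_that("bulk read counts follow the Poisson-binomial depth model", {
  cfg <- sim_config(n_f2 = 400, seed = 9)
  pop <- simulate_f2_population(cfg)
  b <- build_bulks(pop)
  tab <- simulate_bulk_readcounts(pop, b)
  expect_s3_class(tab, "snp_table")
  expect_equal(nrow(tab), nrow(pop$snp_map))
  expect_true(all(tab$mut_bulk_alt <= tab$mut_bulk_dp))
  # wild-type bulk carries no mutant allele at the causal locus
  expect_equal(tab$wt_bulk_alt[pop$snp_map$is_causal], 0)
  # mutant-bulk allele frequency at the causal locus near 2/3
  cz <- pop$snp_map$is_causal
  expect_lt(abs(tab$mut_bulk_alt[cz] / tab$mut_bulk_dp[cz] - 2 / 3), 0.2)
  # determinism
  expect_identical(tab, simulate_bulk_readcounts(pop, b))
})

test_that("unlinked loci have allele frequency 1/2 in both bulks", {
  cfg <- sim_config(n_f2 = 400, seed = 13)
  pop <- simulate_f2_population(cfg)
  b <- build_bulks(pop)
  unlinked <- pop$snp_map$chrom == "chr2"
  f_mut <- rowSums(pop$geno[unlinked, b$mutant_bulk]) / (2 * b$size)
  f_wt <- rowSums(pop$geno[unlinked, b$wt_bulk]) / (2 * b$size)
  expect_lt(abs(mean(f_mut) - 0.5), 0.05)
  expect_lt(abs(mean(f_wt) - 0.5), 0.05)
})

test_that("expression simulator honours truth labels and the NB limit", {
  expect_error(simulate_expression_counts(fold = 0), "fold")
  s0 <- simulate_expression_counts(200, 3, de_fraction = 0, seed = 1)
  expect_false(any(s0$is_de))
  # dispersion -> 0 at large mean approaches Poisson: variance/mean -> 1
  sp <- simulate_expression_counts(2000, 10, de_fraction = 0,
                                   dispersion = 1e-6,
                                   mean_range = c(500, 500), seed = 2)
  vm <- apply(sp$counts, 1, stats::var) / rowMeans(sp$counts)
  expect_lt(abs(mean(vm) - 1), 0.05)
  # fold applied in the labelled direction
  s1 <- simulate_expression_counts(2000, 5, de_fraction = 0.2, fold = 4,
                                   dispersion = 0.01, seed = 3)
  up <- which(s1$true_direction == "up")
  lfc <- log2(rowMeans(s1$counts[up, 6:10]) / rowMeans(s1$counts[up, 1:5]))
  expect_lt(abs(mean(lfc) - 2), 0.2)
})

test_that("peak simulator implants the motif only where asked", {
  genes <- simulate_gene_models(n_genes = 50, seed = 4)
  pk0 <- simulate_peaks_and_sequences(genes, n_peaks = 50, n_target = 0,
                                      seed = 4)
  hits <- sum(vapply(pk0$seqs, function(s) grepl("CTTGC", s), logical(1)))
  # chance occurrences only: ~200 positions x (1/4)^5 per peak
  expect_lt(hits, 15)
  pk <- simulate_peaks_and_sequences(genes, n_peaks = 50, n_target = 20,
                                     seed = 4)
  expect_length(pk$target_genes, 20)
  expect_true(all(grepl("CTTGC", pk$seqs[1:20])))
  expect_error(simulate_peaks_and_sequences(genes, n_target = 100),
               "n_target")
})

test_that("target peaks fall inside the putative-target window by construction", {
  genes <- simulate_gene_models(n_genes = 80, seed = 6)
  pk <- simulate_peaks_and_sequences(genes, n_peaks = 40, n_target = 20,
                                     window = c(-2000, 500), seed = 6)
  asg <- assign_peaks(pk$peaks, genes)
  tg <- putative_targets(asg)
  expect_true(all(pk$target_genes %in% tg))
})
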