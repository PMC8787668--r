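test_that("signed TSS distances are strand-aware and mirror-symmetric", {
  expect_equal(signed_tss_distance(5000, 5000, "+"), 0)
  expect_equal(signed_tss_distance(5100, 5000, "-"), -100)
  expect_equal(signed_tss_distance(4900, 5000, "+"), -100)
  # reflecting coordinates around any pivot and flipping strand preserves
  # the signed distance
  pivot <- 1e6
  expect_equal(signed_tss_distance(pivot - 5100, pivot - 5000, "+"),
               signed_tss_distance(5100, 5000, "-"))
})

mk_genes <- function() {
  data.frame(gene_id = c("gA", "gB", "gC"),
             chrom = c("chr1", "chr1", "chr2"),
             strand = c("+", "-", "+"),
             tss = c(10000, 50000, 30000))
}

mk_peak <- function(anchor1, chrom = "chr1", id = "p1", w = 200) {
  # BED interval whose 1-based midpoint equals anchor1
  data.frame(peak_id = id, chrom = chrom,
             start = anchor1 - w / 2 - 1, end = anchor1 + w / 2 - 1,
             score = 100)
}

test_that("peaks are assigned to nearest TSS with inclusive windows", {
  genes <- mk_genes()
  # 1,060 bp upstream of a + strand gene: putative target
  a <- assign_peaks(mk_peak(10000 - 1060), genes)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$distance, -1060)
  expect_true(a$is_putative_target)
  # -2,500: genic window only
  a2 <- assign_peaks(mk_peak(10000 - 2500), genes)
  expect_true(a2$in_genic_window)
  expect_false(a2$is_putative_target)
  # +501: just outside the target window
  a3 <- assign_peaks(mk_peak(10000 + 501), genes)
  expect_equal(a3$distance, 501)
  expect_false(a3$is_putative_target)
  # boundaries are inclusive
  a4 <- assign_peaks(mk_peak(10000 + 500), genes)
  expect_true(a4$is_putative_target)
  a5 <- assign_peaks(mk_peak(10000 - 2000), genes)
  expect_true(a5$is_putative_target)
  # upstream of a minus-strand gene means larger coordinate
  a6 <- assign_peaks(mk_peak(50000 + 1000), genes)
  expect_equal(a6$gene_id, "gB")
  expect_equal(a6$distance, -1000)
  expect_error(assign_peaks(mk_peak(100), genes[0, ]), "empty gene set")
})

test_that("assignment is invariant under whole-genome translation", {
  genes <- mk_genes()
  pk <- rbind(mk_peak(9000, id = "p1"), mk_peak(48000, id = "p2"),
              mk_peak(29000, chrom = "chr2", id = "p3"))
  a <- assign_peaks(pk, genes)
  shift <- 12345
  genes2 <- genes; genes2$tss <- genes2$tss + shift
  pk2 <- pk; pk2$start <- pk2$start + shift; pk2$end <- pk2$end + shift
  a2 <- assign_peaks(pk2, genes2)
  expect_equal(a2$gene_id, a$gene_id)
  expect_equal(a2$distance, a$distance)
})

test_that("ties at equal distance resolve to the lexicographic gene id", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      strand = "+", tss = c(11000, 9000))
  a <- assign_peaks(mk_peak(10000), genes)
  expect_equal(a$gene_id, "gA")
})

test_that("DEG intersection partitions targets by direction", {
  degs <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     is_deg = c(TRUE, TRUE, FALSE, TRUE),
                     direction = c("down", "up", "down", "down"))
  ov <- intersect_degs(c("g1", "g3", "g4", "g9"), degs)
  expect_equal(ov$down, c("g1", "g4"))
  expect_equal(ov$up, character(0))
  ov0 <- intersect_degs(c("gX"), degs)
  expect_equal(lengths(ov0), c(down = 0L, up = 0L))
  # constructed truth: 5 down-DEG targets recovered exactly
  sim <- simulate_expression_counts(200, 3, 0, seed = 3)
  d <- call_degs(sim$counts, sim$groups, sim$gene_lengths)
  d$is_deg[1:5] <- TRUE; d$direction[1:5] <- "down"
  ov5 <- intersect_degs(d$gene_id[1:20], d)
  expect_setequal(ov5$down, d$gene_id[1:5])
})

test_that("k-mer counting collapses strands onto canonical classes", {
  km <- kmer_enrichment(c("AAAA", "TTTT"), k = 1, n_shuffles = 2, seed = 1)
  # A and T collapse onto class "A": 8 total counts
  expect_equal(km$fg_count[km$kmer == "A"], 8)
  expect_error(kmer_enrichment(c("ACGT"), k = 5), "shortest")
})

test_that("an implanted motif is ranked first", {
  genes <- simulate_gene_models(n_genes = 60, seed = 2)
  pk <- simulate_peaks_and_sequences(genes, n_peaks = 120, n_target = 0,
                                     implant_all = TRUE, seed = 2)
  km <- kmer_enrichment(pk$seqs, k = 5, n_shuffles = 5, seed = 2)
  canon <- min("CTTGC", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("CTTGC"))))
  expect_equal(km$kmer[1], canon)
})

test_that("enrichment decreases monotonically with implant frequency", {
  genes <- simulate_gene_models(n_genes = 100, seed = 4)
  canon <- min("CTTGC", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("CTTGC"))))
  fracs <- c(1, 0.75, 0.5, 0.25, 0)
  scores <- vapply(fracs, function(fr) {
    pk <- simulate_peaks_and_sequences(genes, n_peaks = 100,
                                       n_target = round(100 * fr), seed = 4)
    km <- kmer_enrichment(pk$seqs, k = 5, n_shuffles = 5, seed = 4)
    km$score[km$kmer == canon]
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("purely random sequences yield no outlying top score", {
  set.seed(6)
  seqs <- vapply(1:80, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
    character(1))
  km <- kmer_enrichment(seqs, k = 5, n_shuffles = 5, seed = 6)
  # top canonical 5-mer shows only sampling-level enrichment, well below
  # the ~2.5-3 log2 units an implanted motif reaches
  expect_lt(km$score[1], 2)
})
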