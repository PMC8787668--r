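test_that("translation stops at the first stop codon", {
  expect_equal(translate_cds("ATGTGA"), "M")
  expect_equal(translate_cds("ATGTGGTAA"), "MW")
  expect_warning(translate_cds("TTGAAA"), "ATG")
  expect_error(translate_cds("AT"), "codon")
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
})

test_that("translation agrees with an independent codon-table route", {
  set.seed(17)
  codons <- names(bsamapr:::CODON_TABLE)
  for (i in 1:100) {
    cds <- paste(c("ATG", sample(codons, 99, TRUE)), collapse = "")
    ours <- translate_cds(cds)
    bs <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    bs <- sub("\\*.*$", "", bs)
    expect_identical(ours, bs)
  }
})

test_that("the synthetic stop gain truncates 447 aa to 223 aa losing one domain", {
  syn <- synthetic_ap2_gene()
  eff <- apply_snv_and_classify(syn$gene, syn$snv$pos, syn$snv$ref, syn$snv$alt)
  expect_equal(eff$class, "nonsense")
  expect_equal(eff$ref_aa, "W")
  expect_equal(eff$alt_aa, "*")
  expect_equal(eff$wt_protein_length, 447)
  expect_equal(eff$mut_protein_length, 223)
  expect_equal(eff$lost_domains, "AP2_2")
})

test_that("silent and missense variants are classified without truncation", {
  g <- gene_model_cds("ATGCTGTGGAAATAA",
                      data.frame(start = 1, end = 15))
  # CTG -> TTG is Leu -> Leu
  s <- apply_snv_and_classify(g, 4, "C", "T")
  expect_equal(s$class, "silent")
  expect_equal(s$wt_protein_length, s$mut_protein_length)
  # TGG -> TGC is Trp -> Cys
  m <- apply_snv_and_classify(g, 9, "G", "C")
  expect_equal(m$class, "missense")
  expect_equal(m$ref_aa, "W")
  expect_equal(m$alt_aa, "C")
  expect_error(apply_snv_and_classify(g, 4, "G", "T"), "mismatch")
})

test_that("intronic positions are rejected", {
  g <- gene_model_cds("ATGAAAGGGCCCTTTTAA",
                      data.frame(start = c(1, 13), end = c(6, 18)))
  expect_error(apply_snv_and_classify(g, 8, "G", "A"), "intronic")
})

test_that("moving a nonsense codon 5' never lengthens the product", {
  syn <- synthetic_ap2_gene()
  eff_late <- apply_snv_and_classify(syn$gene, syn$snv$pos, "G", "A")
  # find an earlier tryptophan to knock out, if present; otherwise use a
  # constructed CAA->TAA at a 5' codon via the raw genome
  g <- syn$gene
  # force codon 50 (exon 1, positions 148..150) to create an upstream stop:
  # mutate its first base to T only if that yields a stop from the real codon
  cds_pos <- 3 * 50 - 2
  base <- substr(g$genome_seq, cds_pos, cds_pos)
  mut <- g
  substr(mut$genome_seq, cds_pos, cds_pos) <- "T"
  p_early <- suppressWarnings(nchar(translate_cds(bsamapr:::model_cds_seq(mut))))
  expect_lte(p_early, eff_late$wt_protein_length)
  expect_lt(eff_late$mut_protein_length, eff_late$wt_protein_length)
})

test_that("minus-strand genes translate identically to their mirror", {
  syn <- synthetic_ap2_gene()
  g <- syn$gene
  n <- nchar(g$genome_seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g$genome_seq)))
  mirrored <- gene_model_cds(
    rc,
    data.frame(start = n - g$exons$end + 1, end = n - g$exons$start + 1),
    strand = "-")
  expect_identical(translate_cds(bsamapr:::model_cds_seq(mirrored)),
                   translate_cds(bsamapr:::model_cds_seq(g)))
})

test_that("isoform arithmetic matches the 447/408 architecture", {
  syn <- synthetic_ap2_gene()
  full <- splice_isoform(syn$gene, "full")
  expect_equal(full$protein_length, 447)
  skip9 <- splice_isoform(syn$gene, "exon_skip", 9)
  expect_equal(skip9$protein_length, 408)
  # in-frame skip preserves the flanking peptide exactly
  expect_identical(skip9$protein,
                   paste0(substr(full$protein, 1, 370),
                          substr(full$protein, 410, 447)))
})

test_that("intron retention terminates early when the intron has a stop in frame", {
  syn <- synthetic_ap2_gene()
  ir8 <- splice_isoform(syn$gene, "intron_retention", 8)
  full <- splice_isoform(syn$gene, "full")
  expect_lt(ir8$protein_length, full$protein_length)
  expect_equal(ir8$termination_aa, ir8$protein_length + 1)
  # the retained transcript is longer than the spliced CDS
  expect_equal(nchar(ir8$transcript), 1344 + 100)
})

test_that("skipping the first coding exon yields no product", {
  syn <- synthetic_ap2_gene()
  s1 <- splice_isoform(syn$gene, "exon_skip", 1)
  expect_true(s1$no_product)
  expect_error(splice_isoform(syn$gene, "exon_skip", 99), "invalid")
  expect_error(splice_isoform(syn$gene, "intron_retention", 10), "invalid")
})

test_that("miRNA target mismatches count non-Watson-Crick pairs", {
  mir <- "UGAAUCUUGAUGAUGCUGCAU"   # 21-nt miR172-like
  # perfect antiparallel complement of the site
  site <- "AUGCAGCAUCAUCAAGAUUCA"
  expect_equal(mir_target_mismatches(mir, site), 0)
  s1 <- site; substr(s1, 5, 5) <- "C"
  expect_equal(mir_target_mismatches(mir, s1), 1)
  # a SNP in the site raises the count by exactly one
  s2 <- s1; substr(s2, 10, 10) <- "G"
  expect_equal(mir_target_mismatches(mir, s2),
               mir_target_mismatches(mir, s1) + 1)
  # wobble counted as match only when configured
  sW <- site; substr(sW, 21, 21) <- "G"   # pairs U:G at the mirna 5' end
  expect_equal(mir_target_mismatches(mir, sW), 1)
  expect_equal(mir_target_mismatches(mir, sW, wobble_is_match = TRUE), 0)
  expect_error(mir_target_mismatches(mir, "AAA"), "length")
})
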