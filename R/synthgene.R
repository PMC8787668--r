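#' Synthetic AP2-domain gene model for effect-prediction demonstrations
#'
#' Builds a 10-exon plus-strand gene whose 1,344-nt spliced CDS encodes a
#' 447-aa protein carrying two AP2-like domains (aa 120-180 and 270-330).
#' Exon 9 is 117 nt and in frame, so skipping it yields a 408-aa product.
#' Codon 224 is fixed to TGG (Trp): the G-to-A transition at its middle
#' base creates a premature TAG stop, truncating the protein to 223 aa and
#' removing the second domain — the architecture of a classic EMS-induced
#' speltoid allele. Introns are 100 nt of random sequence.
#'
#' @param seed integer seed for the random codons and introns.
#' @return list with `gene` (a [gene_model_cds()]), `snv` (list `pos`,
#'   `ref = "G"`, `alt = "A"`, genomic coordinates of the stop-gain site)
#'   and `exon_lengths`.
#' @export
synthetic_ap2_gene <- function(seed = 42L) {
  set.seed(seed)
  exon_lens <- c(150, 150, 150, 150, 150, 120, 120, 120, 117, 117)
  stopifnot(sum(exon_lens) == 1344)
  n_codon <- sum(exon_lens) / 3

  non_stop <- setdiff(names(CODON_TABLE),
                      names(CODON_TABLE)[CODON_TABLE == "*"])
  codons <- sample(non_stop, n_codon, replace = TRUE)
  codons[1] <- "ATG"
  codons[n_codon] <- "TAA"
  codons[224] <- "TGG"       # stop-gain site: TGG -> TAG via G>A
  cds <- paste(codons, collapse = "")

  intron_len <- 100L
  introns <- vapply(seq_len(length(exon_lens) - 1L),
                    function(i) random_dna(intron_len), character(1))
  cds_ends <- cumsum(exon_lens)
  cds_starts <- cds_ends - exon_lens + 1L
  genome <- ""
  exon_start <- integer(length(exon_lens))
  gpos <- 1L
  for (i in seq_along(exon_lens)) {
    exon_start[i] <- gpos
    genome <- paste0(genome, substr(cds, cds_starts[i], cds_ends[i]))
    gpos <- gpos + exon_lens[i]
    if (i < length(exon_lens)) {
      genome <- paste0(genome, introns[i])
      gpos <- gpos + intron_len
    }
  }
  exons <- data.frame(start = exon_start, end = exon_start + exon_lens - 1L)
  domains <- data.frame(name = c("AP2_1", "AP2_2"),
                        aa_start = c(120, 270), aa_end = c(180, 330))
  gene <- gene_model_cds(genome, exons, strand = "+", domains = domains)

  # genomic coordinate of the middle base of codon 224 (CDS position 671)
  cds_pos <- 3L * 224L - 1L
  ex <- which(cds_starts <= cds_pos & cds_ends >= cds_pos)
  snv_pos <- exon_start[ex] + (cds_pos - cds_starts[ex])
  stopifnot(substr(genome, snv_pos, snv_pos) == "G")
  list(gene = gene,
       snv = list(pos = snv_pos, ref = "G", alt = "A"),
       exon_lengths = exon_lens)
}

#' Synthetic CAPS amplicon pair with a mutant-gained DdeI site
#'
#' A 395-bp random amplicon constructed so the wild-type allele carries no
#' DdeI (CTNAG) site while the mutant allele gains exactly one at the SNP,
#' mirroring a stop-gain mutation that creates a diagnostic restriction
#' site.
#'
#' @param len amplicon length bp (default 395).
#' @param site_at 1-based position of the gained site's first base.
#' @param seed integer seed.
#' @return list with `wt`, `mut` (sequences) and `snp_pos` (the single
#'   differing base).
#' @export
synthetic_caps_amplicons <- function(len = 395, site_at = 140, seed = 7L) {
  set.seed(seed)
  stopifnot(site_at >= 1, site_at + 4 <= len)
  enz <- list(recognition = "CTNAG", cut_offset = 1L)
  repeat {
    s <- random_dna(len)
    substr(s, site_at, site_at + 4) <- "CTCAG"   # mutant-allele site
    mut <- s
    wt <- s
    substr(wt, site_at + 3, site_at + 3) <- "G"  # CTCGG: site destroyed
    if (length(find_sites(wt, enz)) == 0 &&
        length(find_sites(mut, enz)) == 1) break
  }
  list(wt = wt, mut = mut, snp_pos = site_at + 3L)
}
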