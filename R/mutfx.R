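# Hard-coded standard genetic code, codon -> one-letter amino acid
# ("*" = stop). Kept explicit so translation is self-contained.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate a coding sequence
#'
#' Standard genetic code; translation stops at the first in-frame stop
#' codon and returns the peptide before it. A trailing incomplete codon is
#' ignored. A warning is emitted when the sequence does not start with ATG.
#'
#' @param cds nucleotide sequence (A/C/G/T), length >= 3.
#' @return the protein sequence (one-letter, no stop symbol).
#' @export
translate_cds <- function(cds) {
  check_dna(cds)
  if (nchar(cds) < 3) stop("CDS shorter than one codon", call. = FALSE)
  if (substr(cds, 1, 3) != "ATG") warning("CDS does not start with ATG")
  n_codon <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- CODON_TABLE[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

#' Construct a coding gene model
#'
#' A stranded multi-exon gene on an explicit genomic sequence, with
#' optional protein-domain annotations in amino-acid coordinates. Exons are
#' given in genomic coordinates (1-based inclusive), non-overlapping; for
#' minus-strand genes the CDS is the reverse complement read 3' to 5' along
#' the genome.
#'
#' @param genome_seq the genomic sequence the coordinates refer to.
#' @param exons data.frame `start`, `end` (1-based inclusive genomic).
#' @param strand `"+"` or `"-"`.
#' @param domains optional data.frame `name`, `aa_start`, `aa_end`.
#' @return object of class `gene_model_cds`.
#' @export
gene_model_cds <- function(genome_seq, exons, strand = "+", domains = NULL) {
  check_dna(genome_seq)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start > exons$end) ||
      any(utils::head(exons$end, -1) >= utils::tail(exons$start, -1))) {
    stop("exons must be non-overlapping and ordered", call. = FALSE)
  }
  if (max(exons$end) > nchar(genome_seq)) {
    stop("exon beyond genomic sequence", call. = FALSE)
  }
  structure(list(genome_seq = genome_seq, exons = exons,
                 strand = strand, domains = domains),
            class = "gene_model_cds")
}

# Spliced CDS of a gene model (exons joined 5'->3' on the coding strand).
model_cds_seq <- function(gene, exons = gene$exons) {
  parts <- substring(gene$genome_seq, exons$start, exons$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") rev_comp(s) else s
}

#' Predict the coding consequence of a point mutation
#'
#' Applies a single-nucleotide variant inside an exon, re-translates, and
#' classifies the effect as silent, missense or nonsense. For nonsense
#' effects, any annotated protein domain extending beyond the truncated
#' protein is reported as lost.
#'
#' @param gene a [gene_model_cds()].
#' @param genomic_pos 1-based genomic position of the variant.
#' @param ref,alt reference and alternate bases (forward genomic strand).
#' @return list of class `variant_effect`: `class`, `codon_index`,
#'   `ref_aa`, `alt_aa`, `wt_protein_length`, `mut_protein_length`,
#'   `lost_domains`.
#' @export
apply_snv_and_classify <- function(gene, genomic_pos, ref, alt) {
  stopifnot(inherits(gene, "gene_model_cds"))
  in_exon <- any(genomic_pos >= gene$exons$start & genomic_pos <= gene$exons$end)
  if (!in_exon) stop("position is intronic/intergenic; unsupported variant",
                     call. = FALSE)
  if (substr(gene$genome_seq, genomic_pos, genomic_pos) != ref) {
    stop("reference base mismatch at position ", genomic_pos, call. = FALSE)
  }
  mut_genome <- gene$genome_seq
  substr(mut_genome, genomic_pos, genomic_pos) <- alt

  cds_wt <- model_cds_seq(gene)
  mut_gene <- gene
  mut_gene$genome_seq <- mut_genome
  cds_mut <- model_cds_seq(mut_gene)

  # CDS coordinate of the variant
  diffs <- which(strsplit(cds_wt, "")[[1]] != strsplit(cds_mut, "")[[1]])
  stopifnot(length(diffs) == 1)
  codon_index <- (diffs - 1L) %/% 3L + 1L

  prot_wt <- translate_cds(cds_wt)
  prot_mut <- suppressWarnings(translate_cds(cds_mut))
  ref_aa <- CODON_TABLE[[substr(cds_wt, 3 * codon_index - 2, 3 * codon_index)]]
  alt_aa <- CODON_TABLE[[substr(cds_mut, 3 * codon_index - 2, 3 * codon_index)]]

  cls <- if (alt_aa == "*") "nonsense"
         else if (alt_aa == ref_aa) "silent"
         else "missense"
  lost <- character(0)
  if (!is.null(gene$domains) && nchar(prot_mut) < nchar(prot_wt)) {
    lost <- gene$domains$name[gene$domains$aa_end > nchar(prot_mut)]
  }
  structure(list(class = cls, codon_index = codon_index,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 wt_protein_length = nchar(prot_wt),
                 mut_protein_length = nchar(prot_mut),
                 lost_domains = lost),
            class = "variant_effect")
}

#' Enumerate a declared splice-isoform product
#'
#' Builds the transcript for a declared alternative-splicing event —
#' `"full"`, `exon_skip(k)` or `intron_retention(k)` — and translates it.
#' Intron k is the genomic gap between coding-strand exons k and k+1.
#' Skipping the first coding exon loses the start codon and is flagged as
#' producing no product.
#'
#' @param gene a [gene_model_cds()].
#' @param event `"full"`, `"exon_skip"` or `"intron_retention"`.
#' @param k exon or intron index (coding-strand order) for non-full events.
#' @return list of class `isoform_product`: `event`, `transcript`,
#'   `protein`, `protein_length`, `termination_aa` (position of the stop in
#'   the peptide frame, i.e. protein length + 1) and `no_product` flag.
#' @export
splice_isoform <- function(gene, event = c("full", "exon_skip", "intron_retention"),
                           k = NULL) {
  stopifnot(inherits(gene, "gene_model_cds"))
  event <- match.arg(event)
  n_ex <- nrow(gene$exons)
  # genomic-order exon index corresponding to coding-strand index k
  g_idx <- function(k) if (gene$strand == "+") k else n_ex - k + 1L

  if (event == "full") {
    exons <- gene$exons
  } else if (event == "exon_skip") {
    if (is.null(k) || k < 1 || k > n_ex) stop("invalid exon index", call. = FALSE)
    if (k == 1) {
      return(structure(list(event = "exon_skip", k = k, transcript = NA,
                            protein = NA, protein_length = NA_integer_,
                            termination_aa = NA_integer_, no_product = TRUE),
                       class = "isoform_product"))
    }
    exons <- gene$exons[-g_idx(k), , drop = FALSE]
  } else {
    if (is.null(k) || k < 1 || k > n_ex - 1) {
      stop("invalid intron index", call. = FALSE)
    }
    # retain the gap between coding exons k and k+1 by merging them
    i1 <- g_idx(k); i2 <- g_idx(k + 1L)
    lo <- min(i1, i2); hi <- max(i1, i2)
    exons <- gene$exons
    exons$end[lo] <- exons$end[hi]
    exons <- exons[-hi, , drop = FALSE]
  }
  tx <- model_cds_seq(gene, exons)
  prot <- suppressWarnings(translate_cds(tx))
  structure(list(event = event, k = k, transcript = tx, protein = prot,
                 protein_length = nchar(prot),
                 termination_aa = nchar(prot) + 1L, no_product = FALSE),
            class = "isoform_product")
}

#' Count mismatches between a miRNA and its target site
#'
#' Pairs the miRNA antiparallel against the target site (site read 5'->3',
#' miRNA reversed) and counts non-Watson-Crick pairs. G:U wobble pairs
#' count as full mismatches by default (`wobble_is_match = FALSE`); the
#' target site may be given as DNA (T) or RNA (U).
#'
#' @param mirna miRNA sequence 5'->3' (RNA or DNA alphabet).
#' @param site target-site sequence 5'->3', same length.
#' @param wobble_is_match treat G:U pairs as matches.
#' @return integer mismatch count.
#' @export
mir_target_mismatches <- function(mirna, site, wobble_is_match = FALSE) {
  m <- toupper(chartr("T", "U", mirna))
  s <- toupper(chartr("T", "U", site))
  if (nchar(m) != nchar(s)) {
    stop("miRNA and site lengths differ; gapped alignment unsupported",
         call. = FALSE)
  }
  mi <- rev(strsplit(m, "")[[1]])     # antiparallel
  si <- strsplit(s, "")[[1]]
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  match <- si == wc[mi]
  if (wobble_is_match) {
    match <- match | (mi == "G" & si == "U") | (mi == "U" & si == "G")
  }
  sum(!match)
}
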