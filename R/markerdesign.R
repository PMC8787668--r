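# Standard KASP fluorophore tails appended 5' of the allele-specific
# forward primers.
KASP_FAM_TAIL <- "GAAGGTGACCAAGTTCATGCT"
KASP_HEX_TAIL <- "GAAGGTCGGAGTCAACGGATT"

rev_comp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

check_dna <- function(seq) {
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains non-ACGT characters", call. = FALSE)
  }
  invisible(seq)
}

#' Built-in restriction enzyme table
#'
#' A small editable table of common enzymes: IUPAC recognition sequence and
#' the cut offset in bases after the recognition start on the matching
#' strand (DdeI = CTNAG, cut between C and T, offset 1).
#'
#' @return data.frame `name`, `recognition`, `cut_offset`.
#' @export
default_enzymes <- function() {
  utils::read.table(system.file("extdata", "enzymes.tsv", package = "bsamapr"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Find restriction sites on both strands
#'
#' Returns the 1-based start positions (forward-strand coordinates) of all
#' matches of the enzyme's IUPAC recognition sequence, on the forward
#' strand and — for non-self-complementary patterns — of its reverse
#' complement, deduplicated.
#'
#' @param seq amplicon sequence over A/C/G/T.
#' @param enzyme one row of an enzyme table (list or data.frame row with
#'   `recognition`, `cut_offset`).
#' @return sorted integer vector of site start positions.
#' @export
find_sites <- function(seq, enzyme) {
  check_dna(seq)
  subj <- Biostrings::DNAString(seq)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(enzyme$recognition), subj, fixed = FALSE))
  rc <- rev_comp(enzyme$recognition)
  rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(rc), subj, fixed = FALSE))
  sort(unique(c(fwd, rev)))
}

# Site positions split by matching strand; reverse-only sites are those not
# also matched forward (palindromic patterns collapse to forward).
sites_by_strand <- function(seq, enzyme) {
  subj <- Biostrings::DNAString(seq)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(enzyme$recognition), subj, fixed = FALSE))
  rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(rev_comp(enzyme$recognition)), subj, fixed = FALSE))
  list(fwd = sort(fwd), rev = sort(setdiff(rev, fwd)))
}

#' Digest a sequence and return fragment lengths
#'
#' One double-strand cut per recognition site: after `cut_offset` bases
#' from the site start on the strand where the recognition matched (mapped
#' to forward coordinates for reverse-strand sites). Fragment lengths
#' always partition the sequence.
#'
#' @inheritParams find_sites
#' @return sorted integer vector of fragment lengths (the whole length when
#'   no site exists).
#' @export
digest <- function(seq, enzyme) {
  check_dna(seq)
  n <- nchar(seq)
  s <- sites_by_strand(seq, enzyme)
  len <- nchar(enzyme$recognition)
  cuts <- c(s$fwd + enzyme$cut_offset - 1L,
            s$rev + len - enzyme$cut_offset - 1L)
  cuts <- sort(unique(cuts[cuts >= 1 & cuts < n]))
  frags <- diff(c(0L, cuts, n))
  stopifnot(sum(frags) == n)
  sort(frags)
}

#' Design CAPS assays from a wild-type/mutant amplicon pair
#'
#' For every enzyme whose site count differs between the two alleles,
#' predicts the digest banding of the three genotypes: homozygous
#' wild-type, homozygous mutant, and the heterozygote as the set union of
#' the homozygote bands (a het template is an equimolar mix of both
#' alleles). Assays are ranked by band separability — the minimal pairwise
#' difference among all distinct band lengths — so the easiest gel readout
#' comes first.
#'
#' @param amplicon_wt,amplicon_mut equal-length amplicons differing at
#'   >= 1 base.
#' @param enzymes enzyme table (default [default_enzymes()]).
#' @return data.frame of class `caps_assays`, one row per usable enzyme:
#'   `enzyme`, `n_sites_wt`, `n_sites_mut`, `bands_wt`, `bands_mut`,
#'   `bands_het` (comma-joined bp) and `min_band_sep`; zero rows when no
#'   enzyme discriminates.
#' @export
design_caps <- function(amplicon_wt, amplicon_mut, enzymes = default_enzymes()) {
  check_dna(amplicon_wt); check_dna(amplicon_mut)
  if (nchar(amplicon_wt) != nchar(amplicon_mut)) {
    stop("amplicons must have equal length", call. = FALSE)
  }
  if (amplicon_wt == amplicon_mut) {
    warning("amplicons identical; no CAPS assay possible")
  }
  rows <- lapply(seq_len(nrow(enzymes)), function(i) {
    e <- enzymes[i, ]
    sw <- find_sites(amplicon_wt, e)
    sm <- find_sites(amplicon_mut, e)
    if (length(sw) == length(sm)) return(NULL)
    bw <- digest(amplicon_wt, e)
    bm <- digest(amplicon_mut, e)
    bh <- sort(unique(c(bw, bm)))
    sep <- if (length(bh) > 1) min(diff(bh)) else Inf
    data.frame(enzyme = e$name,
               n_sites_wt = length(sw), n_sites_mut = length(sm),
               bands_wt = paste(bw, collapse = ","),
               bands_mut = paste(bm, collapse = ","),
               bands_het = paste(bh, collapse = ","),
               min_band_sep = sep)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(enzyme = character(), n_sites_wt = integer(),
                      n_sites_mut = integer(), bands_wt = character(),
                      bands_mut = character(), bands_het = character(),
                      min_band_sep = numeric())
  } else {
    out <- out[order(-out$min_band_sep, out$enzyme), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("caps_assays", "data.frame")
  out
}

#' Assemble a KASP assay for a SNP
#'
#' Two allele-specific forward primers end on the SNP base (their only
#' difference) and carry the standard FAM and HEX 5' tails; the common
#' reverse primer is the reverse complement of the start of the right
#' flank.
#'
#' @param flank_left sequence immediately 5' of the SNP (>= `primer_len` - 1
#'   bases).
#' @param allele1,allele2 the two SNP alleles (single distinct bases).
#' @param flank_right sequence immediately 3' of the SNP (>= `primer_len`
#'   bases).
#' @param primer_len genomic primer length (default 21).
#' @return list of class `kasp_assay`: `allele1_forward` (FAM),
#'   `allele2_forward` (HEX), `common_reverse`, `fam_allele`, `hex_allele`.
#' @export
design_kasp <- function(flank_left, allele1, allele2, flank_right,
                        primer_len = 21) {
  check_dna(flank_left); check_dna(flank_right)
  if (nchar(allele1) != 1 || nchar(allele2) != 1) {
    stop("alleles must be single bases", call. = FALSE)
  }
  if (allele1 == allele2) stop("alleles identical; not a SNP", call. = FALSE)
  if (nchar(flank_left) < primer_len - 1) {
    stop("left flank too short for primer design", call. = FALSE)
  }
  if (nchar(flank_right) < primer_len) {
    stop("right flank too short for primer design", call. = FALSE)
  }
  core <- substr(flank_left, nchar(flank_left) - primer_len + 2,
                 nchar(flank_left))
  f1 <- paste0(KASP_FAM_TAIL, core, allele1)
  f2 <- paste0(KASP_HEX_TAIL, core, allele2)
  stopifnot(substr(f1, nchar(KASP_FAM_TAIL) + 1, nchar(f1) - 1) ==
              substr(f2, nchar(KASP_HEX_TAIL) + 1, nchar(f2) - 1))
  structure(list(allele1_forward = f1, allele2_forward = f2,
                 common_reverse = rev_comp(substr(flank_right, 1, primer_len)),
                 fam_allele = allele1, hex_allele = allele2),
            class = "kasp_assay")
}
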