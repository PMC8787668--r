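#' Construct a validated SNP table
#'
#' The substrate of filtering and delta-SNP-index computation: one row per
#' biallelic locus with the two parents' genotype calls and depths and, per
#' bulk, the mutant-allele (alternate) read count and total depth. Parent A
#' is the mutant parent by convention, so the alternate allele is the allele
#' it carries.
#'
#' @param chrom,pos chromosome and 1-based position.
#' @param ref,alt single-base reference and alternate alleles.
#' @param parentA_gt,parentB_gt genotype calls: `"hom_ref"`, `"hom_alt"`,
#'   `"het"`, `"ambiguous"` or `"no_call"`.
#' @param parentA_dp,parentB_dp parental sequencing depths.
#' @param mut_bulk_alt,mut_bulk_dp,wt_bulk_alt,wt_bulk_dp per-bulk alternate
#'   read counts and total depths.
#' @return data.frame of class `snp_table`.
#' @export
snp_table <- function(chrom, pos, ref, alt,
                      parentA_gt, parentA_dp, parentB_gt, parentB_dp,
                      mut_bulk_alt, mut_bulk_dp, wt_bulk_alt, wt_bulk_dp) {
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = ref, alt = alt,
                  parentA_gt = parentA_gt, parentA_dp = as.integer(parentA_dp),
                  parentB_gt = parentB_gt, parentB_dp = as.integer(parentB_dp),
                  mut_bulk_alt = as.integer(mut_bulk_alt),
                  mut_bulk_dp = as.integer(mut_bulk_dp),
                  wt_bulk_alt = as.integer(wt_bulk_alt),
                  wt_bulk_dp = as.integer(wt_bulk_dp))
  if (any(x$pos < 1)) stop("positions must be >= 1", call. = FALSE)
  if (any(x$mut_bulk_alt > x$mut_bulk_dp | x$wt_bulk_alt > x$wt_bulk_dp)) {
    stop("allele reads exceed total depth", call. = FALSE)
  }
  if (any(c(x$parentA_dp, x$parentB_dp, x$mut_bulk_alt, x$wt_bulk_alt) < 0)) {
    stop("negative depths or counts", call. = FALSE)
  }
  class(x) <- c("snp_table", "data.frame")
  x
}

#' Call a parental genotype from per-allele read counts
#'
#' Inbred parent lines are expected to be homozygous; a locus is called
#' homozygous for its major allele when the major-allele read fraction is at
#' least `purity` (default 0.9), `"ambiguous"` otherwise, and `"no_call"`
#' at zero depth.
#'
#' @param allele_depths named numeric vector of per-allele read counts,
#'   e.g. `c(A = 9, G = 1)`.
#' @param purity minimum major-allele fraction for a homozygous call.
#' @return list with `call` (`"hom:<base>"`, `"ambiguous"` or `"no_call"`),
#'   `allele` (major allele or NA) and `depth`.
#' @export
call_parent_genotype <- function(allele_depths, purity = 0.9) {
  if (any(allele_depths < 0)) stop("negative allele depth", call. = FALSE)
  dp <- sum(allele_depths)
  if (dp == 0) {
    return(list(call = "no_call", allele = NA_character_, depth = 0L))
  }
  major <- which.max(allele_depths)
  frac <- allele_depths[major] / dp
  if (frac >= purity) {
    al <- names(allele_depths)[major]
    list(call = paste0("hom:", al), allele = al, depth = as.integer(dp))
  } else {
    list(call = "ambiguous", allele = NA_character_, depth = as.integer(dp))
  }
}

#' Remove loci with shallow parental coverage
#'
#' A locus is dropped when its sequencing depth is strictly below
#' `min_depth` in either parent (`rule = "either"`, the default) or only
#' when both parents are shallow (`rule = "both"`). The boundary is strict:
#' depth exactly `min_depth` is kept.
#'
#' @param table a `snp_table`.
#' @param min_depth minimum acceptable parental depth (default 4).
#' @param rule `"either"` or `"both"`.
#' @return list with `kept` (filtered table, original order) and `removed`
#'   (count).
#' @export
filter_by_parent_depth <- function(table, min_depth = 4, rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (nrow(table) == 0) return(list(kept = table, removed = 0L))
  if (any(table$parentA_dp < 0 | table$parentB_dp < 0)) {
    stop("negative parental depth", call. = FALSE)
  }
  low <- if (rule == "either") {
    table$parentA_dp < min_depth | table$parentB_dp < min_depth
  } else {
    table$parentA_dp < min_depth & table$parentB_dp < min_depth
  }
  list(kept = table[!low, , drop = FALSE], removed = sum(low))
}

#' Remove loci uninformative between the parents
#'
#' Drops loci where the two parents share the same genotype call, and —
#' conservatively, since the parents are inbred lines — loci where either
#' parental call is heterozygous, ambiguous or missing.
#'
#' @param table a `snp_table`.
#' @return list with `kept` and `removed`.
#' @export
filter_monomorphic <- function(table) {
  if (nrow(table) == 0) return(list(kept = table, removed = 0L))
  ok_calls <- c("hom_ref", "hom_alt")
  informative <- table$parentA_gt %in% ok_calls &
    table$parentB_gt %in% ok_calls &
    table$parentA_gt != table$parentB_gt
  list(kept = table[informative, , drop = FALSE], removed = sum(!informative))
}

#' Run the two SNP quality filters with conservation-checked accounting
#'
#' Applies the parental-depth filter, then the parental-monomorphism filter
#' to the survivors. The returned accounting always satisfies
#' `total == removed_low_depth + removed_monomorphic + retained`; violation
#' is an internal error.
#'
#' @inheritParams filter_by_parent_depth
#' @return list with `kept` (filtered `snp_table`) and `accounting`
#'   (one-row data.frame `total`, `removed_low_depth`, `removed_monomorphic`,
#'   `retained`).
#' @export
run_filters <- function(table, min_depth = 4, rule = c("either", "both")) {
  rule <- match.arg(rule)
  total <- nrow(table)
  d <- filter_by_parent_depth(table, min_depth, rule)
  m <- filter_monomorphic(d$kept)
  acc <- data.frame(total = total,
                    removed_low_depth = d$removed,
                    removed_monomorphic = m$removed,
                    retained = nrow(m$kept))
  stopifnot(acc$total == acc$removed_low_depth + acc$removed_monomorphic +
              acc$retained)
  list(kept = m$kept, accounting = acc)
}
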