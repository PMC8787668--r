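#' Score marker genotypes for an F2 population
#'
#' Extracts the genotype at each marker position from a simulated
#' population's genotype matrix. Marker positions must coincide with
#' simulated SNP positions (add them to the SNP set when configuring the
#' simulation).
#'
#' @param population an `f2_population`.
#' @param markers data.frame with `marker_id`, `chrom`, `pos`.
#' @param missing_rate fraction of genotype calls masked to missing
#'   (genotyping dropout; default 0).
#' @param seed seed used only when `missing_rate > 0`.
#' @return data.frame of class `marker_genotype_table`: one row per
#'   individual x marker with `marker_id`, `chrom`, `pos`, `individual`,
#'   `genotype` (`"AA"`, `"Aa"`, `"aa"` or `NA`; A = mutant-parent allele)
#'   and `phenotype`.
#' @export
genotype_markers <- function(population, markers, missing_rate = 0, seed = 1L) {
  stopifnot(inherits(population, "f2_population"))
  key <- paste(population$snp_map$chrom, population$snp_map$pos)
  rows <- match(paste(markers$chrom, markers$pos), key)
  if (anyNA(rows)) {
    stop("marker positions absent from the simulated SNP map: ",
         paste(markers$marker_id[is.na(rows)], collapse = ", "), call. = FALSE)
  }
  n_ind <- ncol(population$geno)
  gsym <- c("aa", "Aa", "AA")
  out <- do.call(rbind, lapply(seq_len(nrow(markers)), function(i) {
    data.frame(marker_id = markers$marker_id[i],
               chrom = markers$chrom[i], pos = markers$pos[i],
               individual = seq_len(n_ind),
               genotype = gsym[population$geno[rows[i], ] + 1L],
               phenotype = population$phenotype)
  }))
  if (missing_rate > 0) {
    set.seed(seed)
    out$genotype[stats::runif(nrow(out)) < missing_rate] <- NA_character_
  }
  class(out) <- c("marker_genotype_table", "data.frame")
  out
}

#' Count recombinants at a marker under a dominant causal model
#'
#' A recombinant is an individual whose marker genotype is incompatible
#' with the causal genotype implied by its phenotype: a normal
#' (recessive-phenotype) plant must be aa at the causal locus, so marker
#' AA or Aa counts as recombinant; a speltoid (dominant-phenotype) plant
#' carries at least one A, so only marker aa counts. Heterozygous markers
#' in speltoid plants are compatible (A_) and are not counted. Missing
#' genotypes are skipped.
#'
#' @param table a `marker_genotype_table`.
#' @param marker_id marker to score.
#' @return integer recombinant count (warns when every genotype is
#'   missing).
#' @export
count_recombinants <- function(table, marker_id) {
  sub <- table[table$marker_id == marker_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown marker id: ", marker_id, call. = FALSE)
  scored <- !is.na(sub$genotype)
  if (!any(scored)) {
    warning("all genotypes missing for marker ", marker_id)
    return(0L)
  }
  sub <- sub[scored, , drop = FALSE]
  rec <- (sub$phenotype == "normal" & sub$genotype %in% c("AA", "Aa")) |
    (sub$phenotype == "speltoid" & sub$genotype == "aa")
  sum(rec)
}

#' Delimit the candidate interval by flanking markers
#'
#' The marker with the fewest recombinants anchors the interval; walking
#' outward on each side, the nearest marker with strictly more recombinants
#' becomes the flank (or the chromosome end when none exists). Ties in the
#' minimal count widen the interval: the leftmost and rightmost tied
#' markers both act as anchors. If every marker has the same count the
#' whole chromosome is returned with a warning.
#'
#' @param table a `marker_genotype_table` for markers on one chromosome.
#' @param chrom_length chromosome length bp (used when a flank falls off
#'   the marker set).
#' @return list with `anchor` (marker id, first of the tied minima),
#'   `left_marker`, `right_marker` (ids or NA at chromosome ends),
#'   `start`, `end` (bp), `counts` (named per-marker recombinant counts).
#' @export
delimit_interval <- function(table, chrom_length) {
  mk <- unique(table[, c("marker_id", "chrom", "pos")])
  if (length(unique(mk$chrom)) != 1) {
    stop("markers must lie on a single chromosome", call. = FALSE)
  }
  if (nrow(mk) < 3) stop("need >= 3 markers", call. = FALSE)
  mk <- mk[order(mk$pos), , drop = FALSE]
  counts <- vapply(mk$marker_id, function(m) count_recombinants(table, m),
                   integer(1))
  names(counts) <- mk$marker_id
  lo <- min(counts)
  if (all(counts == lo)) {
    warning("all markers have equal recombinant counts; whole-chromosome interval")
    return(list(anchor = mk$marker_id[1],
                left_marker = NA_character_, right_marker = NA_character_,
                start = 1, end = chrom_length, counts = counts))
  }
  tied <- which(counts == lo)
  iL <- min(tied); iR <- max(tied)
  left <- rev(which(seq_len(nrow(mk)) < iL & counts > lo))
  right <- which(seq_len(nrow(mk)) > iR & counts > lo)
  left_i <- if (length(left)) left[1] else NA_integer_
  right_i <- if (length(right)) right[1] else NA_integer_
  list(anchor = mk$marker_id[iL],
       left_marker = if (is.na(left_i)) NA_character_ else mk$marker_id[left_i],
       right_marker = if (is.na(right_i)) NA_character_ else mk$marker_id[right_i],
       start = if (is.na(left_i)) 1 else mk$pos[left_i],
       end = if (is.na(right_i)) chrom_length else mk$pos[right_i],
       counts = counts)
}

#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' Pearson chi-square test of observed dominant:recessive counts against an
#' expected Mendelian ratio (default 3:1), with df = 1 and the p-value from
#' the upper tail of the chi-square distribution. Yates continuity
#' correction is off by default.
#'
#' @param n_dom,n_rec observed counts in the dominant- and
#'   recessive-phenotype classes.
#' @param ratio expected ratio as a length-2 numeric (default `c(3, 1)`).
#' @param yates apply the continuity correction.
#' @return list with `observed`, `expected`, `chi2`, `df`, `p_value`.
#' @export
chi_square_segregation <- function(n_dom, n_rec, ratio = c(3, 1),
                                   yates = FALSE) {
  if (n_dom < 0 || n_rec < 0) stop("negative counts", call. = FALSE)
  n <- n_dom + n_rec
  if (n == 0) stop("no observations", call. = FALSE)
  expd <- n * ratio / sum(ratio)
  obs <- c(n_dom, n_rec)
  dev <- abs(obs - expd)
  if (yates) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / expd)
  list(observed = obs, expected = expd, chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
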