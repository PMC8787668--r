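#' Per-bulk SNP-index
#'
#' The SNP-index of a bulk at a locus is the fraction of its reads carrying
#' the mutant-parent allele. Loci with depth below `min_depth` get `NA`
#' and are excluded from smoothing downstream.
#'
#' @param alt_reads mutant-allele read counts.
#' @param total_reads total read depths.
#' @param min_depth minimum bulk depth for a defined index (default 1).
#' @return numeric vector in \[0, 1\] with `NA` at shallow loci.
#' @export
snp_index <- function(alt_reads, total_reads, min_depth = 1) {
  if (any(alt_reads > total_reads, na.rm = TRUE)) {
    stop("alt reads exceed depth", call. = FALSE)
  }
  out <- ifelse(total_reads >= min_depth, alt_reads / total_reads, NA_real_)
  as.numeric(out)
}

#' Per-locus delta-SNP-index track
#'
#' For every locus computes the SNP-index in each bulk, their difference
#' (mutant minus wild-type) and its absolute value. At a locus fully linked
#' to a dominant causal allele the expected delta is 2/3 (mutant bulk 2/3,
#' since speltoid plants are AA:Aa = 1:2; wild-type bulk 0); at unlinked
#' loci it is 0.
#'
#' @param table a `snp_table` (typically the output of [run_filters()]).
#' @param min_depth minimum per-bulk depth for a defined index.
#' @return data.frame of class `delta_index_track`: `chrom`, `pos`,
#'   `index_mut`, `index_wt`, `delta`, `abs_delta` (and, after
#'   [loess_fit_track()], `fitted`).
#' @export
delta_snp_index <- function(table, min_depth = 1) {
  idx_m <- snp_index(table$mut_bulk_alt, table$mut_bulk_dp, min_depth)
  idx_w <- snp_index(table$wt_bulk_alt, table$wt_bulk_dp, min_depth)
  out <- data.frame(chrom = table$chrom, pos = table$pos,
                    index_mut = idx_m, index_wt = idx_w,
                    delta = idx_m - idx_w,
                    abs_delta = abs(idx_m - idx_w))
  class(out) <- c("delta_index_track", "data.frame")
  out
}

#' LOESS-smooth the |delta-SNP-index| along each chromosome
#'
#' Fits a tricube-weighted local polynomial (LOESS) of `abs_delta` against
#' position, independently per chromosome so no smoothing crosses a
#' chromosome boundary. Robustness iterations use bisquare reweighting
#' (`iterations > 0` selects the symmetric family). Fitted values are
#' clipped to \[0, 1\]; loci with missing index are excluded from the fit
#' and keep `NA` fitted values. Chromosomes with fewer points than the
#' local window supports are skipped with a warning.
#'
#' @param track a `delta_index_track`.
#' @param span fraction of each chromosome's loci in the local window.
#' @param degree local polynomial degree (1 = local linear).
#' @param iterations robustness (bisquare) iterations; 0 = plain least
#'   squares.
#' @return the track with a `fitted` column added.
#' @export
loess_fit_track <- function(track, span = 0.1, degree = 1, iterations = 2) {
  track$fitted <- NA_real_
  fam <- if (iterations > 0) "symmetric" else "gaussian"
  ctrl <- stats::loess.control(surface = "direct",
                               iterations = iterations + 1L)
  for (chr in unique(track$chrom)) {
    rows <- which(track$chrom == chr & !is.na(track$abs_delta))
    # need at least a handful of points and a window of >= degree + 2
    if (length(rows) < max(4, ceiling(span * length(rows)), degree + 2)) {
      warning(sprintf("chromosome %s: too few informative loci, skipped", chr))
      next
    }
    ord <- rows[order(track$pos[rows])]
    fit <- stats::loess(track$abs_delta[ord] ~ track$pos[ord],
                        span = span, degree = degree,
                        family = fam, control = ctrl)
    track$fitted[ord] <- pmin(1, pmax(0, stats::fitted(fit)))
  }
  track
}

#' Call candidate regions from the smoothed track
#'
#' The threshold is the genome-wide empirical `quantile` of the fitted
#' values; maximal runs of consecutive loci (per chromosome, position
#' order) with fitted value >= threshold become candidate regions, bounded
#' by their first and last qualifying positions. If all fitted values are
#' tied the track is degenerate: each chromosome is returned as one region
#' flagged `degenerate`, with a warning.
#'
#' @param track output of [loess_fit_track()].
#' @param quantile genome-wide quantile defining the threshold
#'   (default 0.99).
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `peak_pos`, `peak_fitted`, `threshold`, `n_loci`, `degenerate`; zero
#'   rows for an empty track.
#' @export
call_candidate_regions <- function(track, quantile = 0.99) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_pos = integer(), peak_fitted = numeric(),
                      threshold = numeric(), n_loci = integer(),
                      degenerate = logical())
  ok <- !is.na(track$fitted)
  if (!any(ok)) return(empty)
  fitted_all <- track$fitted[ok]
  degenerate <- length(unique(fitted_all)) == 1L
  thr <- stats::quantile(fitted_all, quantile, names = FALSE)
  if (degenerate) {
    warning("all fitted values tied; returning whole-chromosome regions flagged degenerate")
  }
  out <- list()
  for (chr in unique(track$chrom)) {
    rows <- which(track$chrom == chr & ok)
    if (!length(rows)) next
    rows <- rows[order(track$pos[rows])]
    above <- track$fitted[rows] >= thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- rows[starts[k]:ends[k]]
      pk <- seg[which.max(track$fitted[seg])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start = track$pos[seg[1]],
        end = track$pos[seg[length(seg)]],
        peak_pos = track$pos[pk],
        peak_fitted = track$fitted[pk],
        threshold = thr,
        n_loci = length(seg),
        degenerate = degenerate)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Permutation calibration of the candidate-region threshold
#'
#' Re-draws the bulk allele counts under the null of no phenotype-genotype
#' association (bulk membership shuffled across phenotypes) and returns the
#' distribution of genome-wide maxima of the fitted |delta-SNP-index|,
#' usable as an empirical significance reference for observed peaks.
#'
#' @param population an `f2_population`.
#' @param n_perm number of permutations.
#' @param span,degree,iterations smoothing parameters, as
#'   [loess_fit_track()].
#' @param seed integer seed.
#' @return numeric vector of per-permutation genome-wide maxima.
#' @export
permutation_null_max <- function(population, n_perm = 20,
                                 span = 0.1, degree = 1, iterations = 2,
                                 seed = NULL) {
  if (is.null(seed)) seed <- stage_seed(population$config$seed, "permute")
  bsz <- population$config$bulk_size
  vapply(seq_len(n_perm), function(i) {
    set.seed(seed + i)
    ids <- sample(seq_along(population$phenotype), 2 * bsz)
    fake <- structure(list(mutant_bulk = ids[seq_len(bsz)],
                           wt_bulk = ids[bsz + seq_len(bsz)],
                           size = bsz), class = "bulk_pair")
    tab <- simulate_bulk_readcounts(population, fake, seed = seed + 1000L + i)
    tr <- loess_fit_track(delta_snp_index(tab), span, degree, iterations)
    max(tr$fitted, na.rm = TRUE)
  }, numeric(1))
}
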