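#' Relative expression by the 2^-ddCT method
#'
#' Technical replicates are paired by index: each replicate's dCT is the
#' target CT minus the reference-gene CT, replicates are averaged per
#' condition, and relative expression is 2^-(dCT_sample - dCT_calibrator),
#' assuming perfect doubling per cycle. Replicate scatter is propagated:
#' the SD of ddCT is the quadrature sum of the two conditions' dCT standard
#' errors of the mean, and the SD of relative expression is
#' `log(2) * rel * sd_ddct` (delta method).
#'
#' @param sample,calibrator data.frames with numeric columns `target_ct`
#'   and `reference_ct`, one row per technical replicate.
#' @return list with `relative_expression`, `ddct`, `sd_ddct`,
#'   `sd_relative`.
#' @export
delta_delta_ct <- function(sample, calibrator) {
  need <- c("target_ct", "reference_ct")
  if (!all(need %in% names(sample)) || !all(need %in% names(calibrator))) {
    stop("both conditions need target_ct and reference_ct columns",
         call. = FALSE)
  }
  dct <- function(x) {
    d <- x$target_ct - x$reference_ct
    list(mean = mean(d),
         sem = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else 0)
  }
  s <- dct(sample); k <- dct(calibrator)
  ddct <- s$mean - k$mean
  sd_ddct <- sqrt(s$sem^2 + k$sem^2)
  rel <- 2^(-ddct)
  list(relative_expression = rel, ddct = ddct, sd_ddct = sd_ddct,
       sd_relative = log(2) * rel * sd_ddct)
}

#' FPKM from a count matrix
#'
#' FPKM\[g, s\] = count\[g, s\] * 1e9 / (length\[g\] * total\[s\]), with
#' per-sample totals defaulting to the column sums of the matrix.
#'
#' @param counts genes x samples matrix of fragment counts.
#' @param gene_lengths exonic lengths in bp (> 0).
#' @param totals per-sample total mapped fragments; default `colSums(counts)`.
#' @return numeric matrix of FPKM values, same dimnames as `counts`.
#' @export
fpkm <- function(counts, gene_lengths, totals = colSums(counts)) {
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (any(totals <= 0)) stop("per-sample totals must be > 0", call. = FALSE)
  sweep(counts / gene_lengths, 2, totals, "/") * 1e9
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, preserving input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Vectorized Welch two-sample t-test over matrix rows.
row_welch <- function(x, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, g2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & m1 == m2] <- 1       # constant, identical groups
  list(diff = m2 - m1, t = t, df = df, p = p)
}

#' Call differentially expressed genes (fold change + FDR rule)
#'
#' Converts counts to FPKM, drops genes below an expression floor (mean
#' FPKM >= `min_fpkm` in at least one group), tests each remaining gene
#' with a Welch two-sample t statistic on log2(FPKM + 1), adjusts p-values
#' by Benjamini-Hochberg across tested genes, and flags DEGs whose
#' absolute fold change is at least `fc_threshold` and q-value below
#' `q_threshold`. `log2fc` and `direction` are group 2 relative to group 1
#' (first level order of appearance in `groups`).
#'
#' @param counts genes x samples count matrix.
#' @param groups length-ncol character/factor with exactly two levels and
#'   >= 2 replicates each; for characters the reference (group 1) is the
#'   alphabetically first label, for factors the first level — so swapping
#'   the two labels flips every fold change's sign.
#' @param gene_lengths exonic lengths bp.
#' @param fc_threshold fold-change threshold (default 2, i.e. |log2FC| >= 1).
#' @param q_threshold BH FDR threshold (default 0.05).
#' @param min_fpkm expression floor (mean FPKM in some group).
#' @return data.frame of class `deg_table`: `gene_id`, `mean_fpkm_1`,
#'   `mean_fpkm_2`, `log2fc`, `p_value`, `q_value`, `direction`, `is_deg`,
#'   `tested`.
#' @export
call_degs <- function(counts, groups, gene_lengths,
                      fc_threshold = 2, q_threshold = 0.05, min_fpkm = 1) {
  lv <- levels(factor(groups))
  if (length(lv) != 2) stop("need exactly two groups", call. = FALSE)
  g1 <- which(groups == lv[1]); g2 <- which(groups == lv[2])
  if (length(g1) < 2 || length(g2) < 2) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  fk <- fpkm(counts, gene_lengths)
  m1 <- rowMeans(fk[, g1, drop = FALSE])
  m2 <- rowMeans(fk[, g2, drop = FALSE])
  tested <- m1 >= min_fpkm | m2 >= min_fpkm

  lf <- log2(fk + 1)
  out <- data.frame(gene_id = rownames(counts), mean_fpkm_1 = m1,
                    mean_fpkm_2 = m2, log2fc = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    direction = NA_character_, is_deg = FALSE,
                    tested = tested, row.names = NULL)
  if (any(tested)) {
    w <- row_welch(lf[tested, , drop = FALSE], g1, g2)
    out$log2fc[tested] <- w$diff
    out$p_value[tested] <- w$p
    out$q_value[tested] <- bh_adjust(w$p)
    out$direction[tested] <- ifelse(w$diff >= 0, "up", "down")
    out$is_deg[tested] <- abs(w$diff) >= log2(fc_threshold) &
      out$q_value[tested] < q_threshold
  }
  class(out) <- c("deg_table", "data.frame")
  out
}
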