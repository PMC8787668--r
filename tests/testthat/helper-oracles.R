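# Independent oracles used across tests: deliberately naive implementations
# kept separate from the package's code paths.

# Benjamini-Hochberg by the definition: q_i = min over j >= i (sorted) of
# p_(j) * m / j, capped at 1, mapped back to input order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# Sliding-window IUPAC matcher on one strand.
iupac_match_one_strand <- function(seq, pattern) {
  sb <- strsplit(seq, "")[[1]]
  pb <- strsplit(pattern, "")[[1]]
  L <- length(pb)
  hits <- integer(0)
  for (i in seq_len(length(sb) - L + 1)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(sb[i + j - 1] %in% IUPAC_SETS[[pb[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

revcomp_brute <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# Both-strand site finder: forward matches of the pattern plus forward
# matches of its reverse complement, deduplicated.
iupac_sites_brute <- function(seq, pattern) {
  sort(unique(c(iupac_match_one_strand(seq, pattern),
                iupac_match_one_strand(seq, revcomp_brute(pattern)))))
}

# Exact goodness-of-fit p-value for a 2-class ratio by binomial
# enumeration: P(chi2(K) >= chi2(obs)) with K ~ Binomial(n, ratio).
exact_gof_p <- function(n_dom, n_rec, ratio = c(3, 1)) {
  n <- n_dom + n_rec
  p1 <- ratio[1] / sum(ratio)
  chi2 <- function(k) {
    e1 <- n * p1; e2 <- n - e1
    (k - e1)^2 / e1 + ((n - k) - e2)^2 / e2
  }
  obs <- chi2(n_dom)
  k <- 0:n
  sum(stats::dbinom(k[chi2(k) >= obs - 1e-12], n, p1))
}

# Small hand-specified SNP table: 5 loci, 2 failing the depth filter,
# 1 of the remainder monomorphic, 2 retained.
toy_snp_table <- function() {
  snp_table(chrom = rep("chr1", 5), pos = 1:5 * 100,
            ref = rep("G", 5), alt = rep("A", 5),
            parentA_gt = c("hom_alt", "hom_alt", "hom_alt", "hom_alt", "hom_alt"),
            parentA_dp = c(3, 10, 10, 4, 9),
            parentB_gt = c("hom_ref", "hom_ref", "hom_alt", "hom_ref", "hom_ref"),
            parentB_dp = c(10, 2, 8, 4, 7),
            mut_bulk_alt = c(5, 5, 5, 5, 5), mut_bulk_dp = rep(10, 5),
            wt_bulk_alt = c(0, 0, 0, 0, 0), wt_bulk_dp = rep(10, 5))
}

# Random SNP table with independent category labels, for filter properties.
random_snp_table <- function(n, seed = 1) {
  set.seed(seed)
  snp_table(chrom = sample(c("chr1", "chr2"), n, TRUE),
            pos = sample.int(1e6, n),
            ref = rep("G", n), alt = rep("A", n),
            parentA_gt = sample(c("hom_alt", "hom_ref", "ambiguous"), n, TRUE),
            parentA_dp = stats::rpois(n, 6),
            parentB_gt = sample(c("hom_ref", "hom_alt"), n, TRUE),
            parentB_dp = stats::rpois(n, 6),
            mut_bulk_alt = rep(3, n), mut_bulk_dp = rep(10, n),
            wt_bulk_alt = rep(3, n), wt_bulk_dp = rep(10, n))
}
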