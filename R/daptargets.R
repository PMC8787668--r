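#' Signed distance from a peak anchor to a gene's TSS
#'
#' Strand-aware: for a `+` strand gene the distance is anchor - TSS, for a
#' `-` strand gene TSS - anchor, so negative distances are always upstream
#' of the gene. Vectorized over peaks x one gene or pairwise equal-length
#' vectors.
#'
#' @param anchor peak anchor positions (1-based bp).
#' @param tss gene TSS positions (1-based bp).
#' @param strand gene strands (`"+"`/`"-"`).
#' @return signed distances in bp.
#' @export
signed_tss_distance <- function(anchor, tss, strand) {
  ifelse(strand == "+", anchor - tss, tss - anchor)
}

#' Assign peaks to their nearest gene by TSS distance
#'
#' Each peak's anchor (interval midpoint by default, or a `summit` column
#' when present and `use_summit = TRUE`) is assigned to the same-chromosome
#' gene minimizing the absolute signed TSS distance; ties are broken by
#' lexicographic gene id. Two windows are flagged: the genic window
#' (distance in \[-10,000, +5,000\]) and the putative-target window
#' (distance in \[-2,000, +500\]), both inclusive.
#'
#' @param peaks data.frame `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open, BED convention), optional `summit`.
#' @param genes data.frame `gene_id`, `chrom`, `strand`, `tss`.
#' @param genic_window,target_window signed inclusive windows (bp).
#' @param use_summit anchor on the `summit` column instead of the midpoint.
#' @return data.frame of class `tss_assignment`: `peak_id`, `gene_id`,
#'   `distance`, `in_genic_window`, `is_putative_target`.
#' @export
assign_peaks <- function(peaks, genes,
                         genic_window = c(-10000, 5000),
                         target_window = c(-2000, 500),
                         use_summit = FALSE) {
  if (nrow(genes) == 0) stop("empty gene set", call. = FALSE)
  if (any(peaks$start >= peaks$end)) stop("peak start must be < end", call. = FALSE)
  anchor <- if (use_summit && "summit" %in% names(peaks)) peaks$summit
            else floor((peaks$start + peaks$end) / 2)
  # midpoint of the 0-based half-open interval, reported 1-based
  anchor1 <- anchor + 1L

  out <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      return(data.frame(peak_id = peaks$peak_id[i], gene_id = NA_character_,
                        distance = NA_real_, in_genic_window = FALSE,
                        is_putative_target = FALSE))
    }
    d <- signed_tss_distance(anchor1[i], g$tss, g$strand)
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1) best <- best[order(g$gene_id[best])[1]]
    data.frame(peak_id = peaks$peak_id[i], gene_id = g$gene_id[best],
               distance = d[best],
               in_genic_window = d[best] >= genic_window[1] &
                 d[best] <= genic_window[2],
               is_putative_target = d[best] >= target_window[1] &
                 d[best] <= target_window[2])
  })
  res <- do.call(rbind, out)
  # window flags must be consistent with the distances
  stopifnot(all(res$is_putative_target ==
                  (!is.na(res$distance) & res$distance >= target_window[1] &
                     res$distance <= target_window[2])))
  class(res) <- c("tss_assignment", "data.frame")
  res
}

#' Putative target genes from a peak assignment
#'
#' @param assignment a `tss_assignment`.
#' @return character vector of unique gene ids with a peak in the
#'   putative-target window.
#' @export
putative_targets <- function(assignment) {
  sort(unique(assignment$gene_id[assignment$is_putative_target &
                                   !is.na(assignment$gene_id)]))
}

#' Intersect putative targets with differentially expressed genes
#'
#' @param targets character vector of target gene ids.
#' @param degs a `deg_table` from [call_degs()].
#' @return list with `down` and `up` gene-id vectors (targets that are
#'   DEGs, split by direction).
#' @export
intersect_degs <- function(targets, degs) {
  hit <- degs[degs$is_deg & degs$gene_id %in% targets, , drop = FALSE]
  list(down = sort(hit$gene_id[hit$direction == "down"]),
       up = sort(hit$gene_id[hit$direction == "up"]))
}

# Canonical (strand-collapsed) form of each k-mer: the lexicographic
# smaller of the k-mer and its reverse complement.
canonical_kmer <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

count_kmers <- function(seqs, k) {
  m <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                            width = k)
  tot <- colSums(m)
  canon <- canonical_kmer(colnames(m))
  tapply(tot, canon, sum)
}

# First-order Markov resample of each sequence: preserves each sequence's
# expected dinucleotide composition (transition frequencies), used as the
# shuffled background for k-mer enrichment. Vectorized across sequences of
# equal length; mixed lengths are handled per length group.
dinuc_shuffle <- function(seqs) {
  lens <- nchar(seqs)
  out <- character(length(seqs))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    out[idx] <- markov_shuffle_equal(seqs[idx], L)
  }
  out
}

markov_shuffle_equal <- function(seqs, L) {
  n <- length(seqs)
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  m <- matrix(code[utf8ToInt(paste(seqs, collapse = ""))],
              nrow = n, ncol = L, byrow = TRUE)
  rows <- seq_len(n)
  # per-sequence transition counts (smoothed), cumulative within each
  # current-base block of 4 columns; linear indexing into the n x 16 matrix
  tcount <- matrix(0.1, n, 16)
  for (j in seq_len(L - 1)) {
    lin <- ((m[, j] - 1L) * 4L + m[, j + 1L] - 1L) * n + rows
    tcount[lin] <- tcount[lin] + 1
  }
  pcum <- tcount
  for (b in 0:3) {
    cols <- b * 4L + 1:4
    csum <- tcount[, cols[1]]
    for (k in 2:4) {
      csum <- csum + tcount[, cols[k]]
      pcum[, cols[k]] <- csum
    }
    pcum[, cols] <- pcum[, cols] / csum
  }
  res <- matrix(0L, n, L)
  res[, 1] <- m[, 1]
  for (j in 2:L) {
    b0 <- (res[, j - 1L] - 1L) * 4L
    u <- stats::runif(n)
    nxt <- 1L + (u > pcum[b0 * n + rows]) +
      (u > pcum[(b0 + 1L) * n + rows]) +
      (u > pcum[(b0 + 2L) * n + rows])
    res[, j] <- nxt
  }
  lett <- c("A", "C", "G", "T")
  chars <- matrix(lett[res], n, L)
  do.call(paste0, lapply(seq_len(L), function(j) chars[, j]))
}

#' Rank k-mer enrichment in peak sequences against a shuffled background
#'
#' Counts every k-mer in the peak sequences with both strands collapsed to
#' a canonical form, builds a background from `n_shuffles`
#' dinucleotide-composition-preserving shuffles of each sequence, and
#' scores each canonical k-mer as `log2((c_fg + 1) / (c_bg / n_shuffles + 1))`.
#' Results are sorted by decreasing score, ties broken lexicographically.
#'
#' @param seqs character vector of peak sequences (all of length >= `k`).
#' @param k k-mer size (default 5).
#' @param n_shuffles background shuffles per sequence (default 10).
#' @param seed integer seed for the shuffles.
#' @return data.frame of class `motif_hits`: `kmer` (canonical),
#'   `fg_count`, `bg_count`, `score`, `rank`.
#' @export
kmer_enrichment <- function(seqs, k = 5, n_shuffles = 10, seed = 1L) {
  if (min(nchar(seqs)) < k) {
    stop("k exceeds the shortest sequence", call. = FALSE)
  }
  set.seed(seed)
  fg <- count_kmers(seqs, k)
  bg_seqs <- unlist(lapply(seq_len(n_shuffles),
                           function(i) vapply(seqs, dinuc_shuffle,
                                              character(1))))
  bg <- count_kmers(bg_seqs, k)
  kmers <- sort(unique(c(names(fg), names(bg))))
  c_fg <- ifelse(kmers %in% names(fg), fg[kmers], 0)
  c_bg <- ifelse(kmers %in% names(bg), bg[kmers], 0)
  score <- log2((c_fg + 1) / (c_bg / n_shuffles + 1))
  out <- data.frame(kmer = kmers, fg_count = as.integer(c_fg),
                    bg_count = as.integer(c_bg), score = score)
  out <- out[order(-out$score, out$kmer), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}
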