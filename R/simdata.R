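#' Simulation configuration for an F2 bulked-segregant experiment
#'
#' Bundles and validates every constant the simulator needs: the synthetic
#' genome, SNP density, the causal locus, population and bulk sizes, the
#' sequencing depth model and the genetic map rate.
#'
#' The defaults describe a desk-scale version of a biparental F2 mapping
#' cross: a single dominant causal allele, two chromosomes of 50 Mb at
#' 1 cM/Mb, 500 SNPs per chromosome, 50-plant phenotype-pure bulks and
#' Poisson sequencing depth with mean 50x per bulk.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param snps_per_chrom number of polymorphic SNP loci simulated per
#'   chromosome (uniformly placed, causal position always included).
#' @param causal_chrom,causal_pos location of the causal locus (bp).
#' @param dominant logical; is the mutant allele dominant for the phenotype?
#' @param n_f2 number of F2 individuals.
#' @param bulk_size plants per phenotype bulk.
#' @param depth_lambda mean sequencing depth per locus per bulk (Poisson).
#' @param parent_depth_lambda mean sequencing depth per locus per parent.
#' @param cm_per_mb genetic map rate; 0 disables recombination.
#' @param misclass_rate probability a plant's phenotype is recorded wrongly
#'   (0 = full penetrance, the default).
#' @param seed integer master seed; all randomness flows from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chromosomes = data.frame(name = c("chr1", "chr2"),
                                                length = c(50e6, 50e6)),
                       snps_per_chrom = 500,
                       causal_chrom = "chr1",
                       causal_pos = 40e6,
                       dominant = TRUE,
                       n_f2 = 300,
                       bulk_size = 50,
                       depth_lambda = 50,
                       parent_depth_lambda = 20,
                       cm_per_mb = 1,
                       misclass_rate = 0,
                       seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) {
    stop("all chromosome lengths must be > 0", call. = FALSE)
  }
  if (!is.na(causal_chrom)) {
    if (!causal_chrom %in% chromosomes$name) {
      stop("causal locus must lie on a declared chromosome", call. = FALSE)
    }
    clen <- chromosomes$length[match(causal_chrom, chromosomes$name)]
    if (causal_pos < 1 || causal_pos > clen) {
      stop("causal position outside its chromosome", call. = FALSE)
    }
  }
  if (n_f2 <= 0) stop("n_f2 must be positive", call. = FALSE)
  if (bulk_size > n_f2 / 2) {
    stop("bulk_size must be <= n_f2 / 2", call. = FALSE)
  }
  if (depth_lambda <= 0) stop("depth_lambda must be > 0", call. = FALSE)
  if (misclass_rate < 0 || misclass_rate > 1) {
    stop("misclass_rate must be in [0, 1]", call. = FALSE)
  }
  structure(list(chromosomes = chromosomes,
                 snps_per_chrom = snps_per_chrom,
                 causal_chrom = causal_chrom,
                 causal_pos = causal_pos,
                 dominant = dominant,
                 n_f2 = as.integer(n_f2),
                 bulk_size = as.integer(bulk_size),
                 depth_lambda = depth_lambda,
                 parent_depth_lambda = parent_depth_lambda,
                 cm_per_mb = cm_per_mb,
                 misclass_rate = misclass_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic sub-seed for a named simulation stage, derived from the
# master seed so that independent stages draw from independent streams.
# Kept well below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  offs <- c(population = 11L, bulks = 23L, readcounts = 37L,
            expression = 53L, peaks = 71L, permute = 89L)
  o <- offs[[stage]]
  as.integer((as.numeric(seed) * 1009 + o * 9176) %% 2147480000)
}

# Simulate gamete haplotypes (0 = wild-type parent, 1 = mutant parent) at
# sorted `positions` for `n_gam` independent meioses on one chromosome:
# crossover count ~ Poisson(length in Morgans), crossover positions
# uniform, starting phase fair Bernoulli (Haldane model, no interference).
# Returns a length(positions) x n_gam integer matrix. Vectorized: the
# matrix starts at each gamete's phase and every crossover flips the
# haplotype distal to it.
sim_gametes <- function(positions, n_gam, chrom_len, cm_per_mb) {
  morgans <- chrom_len / 1e6 * cm_per_mb / 100
  start <- sample.int(2L, n_gam, replace = TRUE) - 1L
  h <- matrix(start, nrow = length(positions), ncol = n_gam, byrow = TRUE)
  if (morgans <= 0) return(h)
  n_xo <- stats::rpois(n_gam, morgans)
  if (sum(n_xo) > 0) {
    gam <- rep.int(seq_len(n_gam), n_xo)
    xo <- stats::runif(sum(n_xo), 0, chrom_len)
    cut <- findInterval(xo, positions) + 1L   # first position beyond the xo
    npos <- length(positions)
    for (i in seq_along(gam)) {
      if (cut[i] <= npos) {
        rng <- cut[i]:npos
        h[rng, gam[i]] <- 1L - h[rng, gam[i]]
      }
    }
  }
  h
}

#' Simulate an F2 population segregating one dominant causal allele
#'
#' Each F2 individual is the union of two independent F1 gametes. Meiosis
#' follows the Haldane model: the crossover count on a chromosome is
#' Poisson with mean equal to its genetic length in Morgans, crossovers are
#' placed uniformly, and there is no interference. Genotypes are scored at
#' the configured SNP positions as the mutant-allele dosage (0, 1, 2);
#' expected frequencies at any locus are 1:2:1. The phenotype is dominant:
#' plants carrying at least one mutant allele at the causal locus are
#' `"speltoid"`, others `"normal"` (optionally flipped at `misclass_rate`).
#'
#' @param config a [sim_config()].
#' @return an object of class `f2_population`: a list with `snp_map`
#'   (data.frame `chrom`, `pos`, flag `is_causal`), `geno` (integer matrix,
#'   loci x individuals, mutant-allele dosage), `phenotype` (character
#'   vector) and the config.
#' @export
simulate_f2_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "population"))

  snp_map <- do.call(rbind, lapply(seq_len(nrow(config$chromosomes)), function(i) {
    nm <- config$chromosomes$name[i]
    len <- config$chromosomes$length[i]
    pos <- sort(unique(round(seq(1, len, length.out = config$snps_per_chrom))))
    if (!is.na(config$causal_chrom) && nm == config$causal_chrom) {
      pos <- sort(unique(c(pos, config$causal_pos)))
    }
    data.frame(chrom = nm, pos = pos)
  }))
  snp_map$is_causal <- !is.na(config$causal_chrom) &
    snp_map$chrom == config$causal_chrom & snp_map$pos == config$causal_pos

  geno <- matrix(0L, nrow = nrow(snp_map), ncol = config$n_f2)
  for (i in seq_len(nrow(config$chromosomes))) {
    nm <- config$chromosomes$name[i]
    len <- config$chromosomes$length[i]
    rows <- which(snp_map$chrom == nm)
    pos <- snp_map$pos[rows]
    geno[rows, ] <- sim_gametes(pos, config$n_f2, len, config$cm_per_mb) +
      sim_gametes(pos, config$n_f2, len, config$cm_per_mb)
  }

  if (!is.na(config$causal_chrom)) {
    causal_row <- which(snp_map$is_causal)
    carrier <- geno[causal_row, ] >= 1L
    phenotype <- ifelse(carrier, "speltoid", "normal")
    if (config$misclass_rate > 0) {
      flip <- stats::runif(config$n_f2) < config$misclass_rate
      phenotype[flip] <- ifelse(phenotype[flip] == "speltoid",
                                "normal", "speltoid")
    }
  } else {
    # no causal locus: a non-genetic 3:1 phenotype, the null for BSA
    phenotype <- ifelse(stats::runif(config$n_f2) < 0.75,
                        "speltoid", "normal")
  }

  structure(list(snp_map = snp_map, geno = geno,
                 phenotype = phenotype, config = config),
            class = "f2_population")
}

#' Assemble two phenotype-pure bulks from an F2 population
#'
#' Samples `bulk_size` speltoid plants into the mutant bulk and `bulk_size`
#' normal plants into the wild-type bulk, without replacement, so the bulks
#' are disjoint and 100% phenotype-pure (as recorded).
#'
#' @param population an `f2_population`.
#' @param bulk_size plants per bulk; defaults to the population's config.
#' @param seed sampling seed; defaults to a sub-seed of the config seed.
#' @return a list of class `bulk_pair` with integer id vectors `mutant_bulk`
#'   and `wt_bulk`.
#' @export
build_bulks <- function(population, bulk_size = population$config$bulk_size,
                        seed = NULL) {
  stopifnot(inherits(population, "f2_population"))
  if (is.null(seed)) seed <- stage_seed(population$config$seed, "bulks")
  spel <- which(population$phenotype == "speltoid")
  norm <- which(population$phenotype == "normal")
  if (length(spel) < bulk_size) {
    stop(sprintf("insufficient speltoid plants: need %d, have %d",
                 bulk_size, length(spel)), call. = FALSE)
  }
  if (length(norm) < bulk_size) {
    stop(sprintf("insufficient normal plants: need %d, have %d",
                 bulk_size, length(norm)), call. = FALSE)
  }
  set.seed(seed)
  structure(list(mutant_bulk = sort(sample(spel, bulk_size)),
                 wt_bulk = sort(sample(norm, bulk_size)),
                 size = as.integer(bulk_size)),
            class = "bulk_pair")
}

#' Simulate pooled whole-exome allele depths for a bulk pair
#'
#' Emulates post-alignment allele counting in pooled sequencing: at each
#' locus and bulk the total depth is Poisson(`depth_lambda`) and the
#' mutant-allele read count is Binomial(depth, f), where f is the true
#' mutant-allele frequency among the bulk's members at that locus. Parents
#' are recorded as fixed homozygotes (mutant parent carries the alternate
#' allele everywhere) with their own Poisson depths.
#'
#' At a locus fully linked to the causal allele the expected f is 2/3 in
#' the mutant bulk (speltoid plants are AA:Aa = 1:2) and 0 in the
#' wild-type bulk; at unlinked loci both expectations are 1/2.
#'
#' @param population an `f2_population`.
#' @param bulks a `bulk_pair` from [build_bulks()].
#' @param depth_lambda,parent_depth_lambda Poisson depth means; default from
#'   the population's config.
#' @param seed sub-seed; defaults from the config seed.
#' @return a `snp_table` data.frame (see [snp_table()]).
#' @export
simulate_bulk_readcounts <- function(population, bulks,
                                     depth_lambda = population$config$depth_lambda,
                                     parent_depth_lambda = population$config$parent_depth_lambda,
                                     seed = NULL) {
  stopifnot(inherits(population, "f2_population"),
            inherits(bulks, "bulk_pair"))
  if (is.null(seed)) seed <- stage_seed(population$config$seed, "readcounts")
  set.seed(seed)
  n <- nrow(population$snp_map)

  f_mut <- rowSums(population$geno[, bulks$mutant_bulk, drop = FALSE]) /
    (2 * bulks$size)
  f_wt <- rowSums(population$geno[, bulks$wt_bulk, drop = FALSE]) /
    (2 * bulks$size)

  dp_mut <- stats::rpois(n, depth_lambda)
  dp_wt <- stats::rpois(n, depth_lambda)
  ad_mut <- stats::rbinom(n, dp_mut, f_mut)
  ad_wt <- stats::rbinom(n, dp_wt, f_wt)

  # Alternate allele = the EMS-induced allele of the mutant parent.
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)

  snp_table(chrom = population$snp_map$chrom,
            pos = population$snp_map$pos,
            ref = ref, alt = alt,
            parentA_gt = rep("hom_alt", n),
            parentA_dp = stats::rpois(n, parent_depth_lambda),
            parentB_gt = rep("hom_ref", n),
            parentB_dp = stats::rpois(n, parent_depth_lambda),
            mut_bulk_alt = ad_mut, mut_bulk_dp = dp_mut,
            wt_bulk_alt = ad_wt, wt_bulk_dp = dp_wt)
}

#' Simulate a two-group RNA-seq count matrix with implanted fold changes
#'
#' Counts are negative-binomial with gene-wise means drawn log-uniform
#' between `mean_range`; a `de_fraction` of genes have their mean multiplied
#' by `fold` in the second group (half up-, half down-regulated). Truth
#' labels are returned for FDR/recall evaluation of the DEG caller.
#'
#' @param n_genes,n_reps genes and biological replicates per group
#'   (`n_reps >= 2`).
#' @param de_fraction fraction of genes that are truly differential.
#' @param fold fold change applied to differential genes (> 0, != 1 to have
#'   an effect).
#' @param dispersion negative-binomial dispersion (rnbinom size = 1/dispersion);
#'   as dispersion -> 0 the counts approach Poisson.
#' @param mean_range range of baseline gene means (counts).
#' @param gene_length_bp transcript lengths (recycled), used downstream for
#'   FPKM; default 1,000 bp for all genes.
#' @param seed integer seed.
#' @return list with `counts` (genes x 2*n_reps), `groups`, `gene_lengths`,
#'   `is_de` (logical truth) and `true_direction`.
#' @export
simulate_expression_counts <- function(n_genes = 2000, n_reps = 3,
                                       de_fraction = 0.1, fold = 2,
                                       dispersion = 0.05,
                                       mean_range = c(20, 2000),
                                       gene_length_bp = 1000,
                                       seed = 1L) {
  if (fold <= 0) stop("fold must be > 0", call. = FALSE)
  if (n_reps < 2) stop("need >= 2 replicates per group", call. = FALSE)
  set.seed(seed)
  base_mu <- exp(stats::runif(n_genes, log(mean_range[1]), log(mean_range[2])))
  n_de <- round(de_fraction * n_genes)
  is_de <- rep(FALSE, n_genes)
  true_direction <- rep(NA_character_, n_genes)
  mu2 <- base_mu
  if (n_de > 0) {
    idx <- sample.int(n_genes, n_de)
    is_de[idx] <- TRUE
    up <- idx[seq_len(ceiling(n_de / 2))]
    down <- setdiff(idx, up)
    mu2[up] <- base_mu[up] * fold
    mu2[down] <- base_mu[down] / fold
    true_direction[up] <- "up"
    true_direction[down] <- "down"
  }
  size <- if (dispersion > 0) 1 / dispersion else Inf
  draw <- function(mu) {
    if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
    else stats::rpois(length(mu), mu)
  }
  counts <- cbind(
    matrix(draw(rep(base_mu, n_reps)), ncol = n_reps),
    matrix(draw(rep(mu2, n_reps)), ncol = n_reps))
  rownames(counts) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(counts) <- c(paste0("ctrl_", seq_len(n_reps)),
                        paste0("case_", seq_len(n_reps)))
  list(counts = counts,
       groups = factor(rep(c("ctrl", "case"), each = n_reps),
                       levels = c("ctrl", "case")),
       gene_lengths = rep_len(gene_length_bp, n_genes),
       is_de = is_de,
       true_direction = true_direction)
}

# Random DNA of given length and (optionally) base composition.
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

#' Simulate a gene annotation for peak-assignment tests
#'
#' Places `n_genes` non-overlapping gene models of length `gene_len` on the
#' given chromosomes with random strands; the TSS is the 5' end (start for
#' `+` genes, end for `-` genes).
#'
#' @param chromosomes data.frame `name`, `length`.
#' @param n_genes total genes.
#' @param gene_len gene body length bp.
#' @param seed integer seed.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`
#'   (1-based).
#' @export
simulate_gene_models <- function(chromosomes = data.frame(name = c("chr1", "chr2"),
                                                          length = c(50e6, 50e6)),
                                 n_genes = 200, gene_len = 3000, seed = 1L) {
  set.seed(seed)
  per <- diff(round(seq(0, n_genes, length.out = nrow(chromosomes) + 1)))
  out <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    k <- per[i]
    if (k == 0) return(NULL)
    len <- chromosomes$length[i]
    # evenly spaced slots with jitter keep genes non-overlapping
    slot <- len / k
    start <- round((seq_len(k) - 1) * slot +
                     stats::runif(k, gene_len, pmax(gene_len + 1, slot - 2 * gene_len)))
    data.frame(chrom = chromosomes$name[i], start = start,
               end = start + gene_len - 1,
               strand = sample(c("+", "-"), k, replace = TRUE))
  }))
  out$gene_id <- sprintf("gene%04d", seq_len(nrow(out)))
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
}

#' Simulate DAP-seq peaks with an implanted binding motif
#'
#' `n_target` peaks are centred so that their anchor (midpoint) falls inside
#' `window` of a chosen gene's TSS (strand-aware); the remaining peaks are
#' placed uniformly along the chromosomes. Each target peak's sequence
#' carries one copy of `motif` at a random offset; non-target sequences are
#' random. With `implant_all = TRUE` every peak (target or not) carries the
#' implant, the regime used for motif-recovery checks.
#'
#' @param genes gene table from [simulate_gene_models()].
#' @param chromosomes data.frame `name`, `length`.
#' @param n_peaks,n_target total peaks and TSS-proximal target peaks.
#' @param motif implanted motif (default the 5-mer "CTTGC").
#' @param window signed window (bp, relative to TSS; negative = upstream)
#'   inside which target-peak anchors are placed.
#' @param peak_width peak width bp.
#' @param implant_all implant the motif in every peak, not just targets.
#' @param seed integer seed.
#' @return list with `peaks` (data.frame `peak_id`, `chrom`, `start`, `end`
#'   0-based half-open, `score`), `seqs` (named character vector of peak
#'   sequences) and `target_genes` (gene ids whose TSS the target peaks hit).
#' @export
simulate_peaks_and_sequences <- function(genes,
                                         chromosomes = data.frame(name = c("chr1", "chr2"),
                                                                  length = c(50e6, 50e6)),
                                         n_peaks = 200, n_target = 20,
                                         motif = "CTTGC",
                                         window = c(-2000, 500),
                                         peak_width = 200,
                                         implant_all = FALSE,
                                         seed = 1L) {
  if (nchar(motif) < 3) stop("motif length must be >= 3", call. = FALSE)
  if (n_target > nrow(genes)) stop("n_target exceeds gene count", call. = FALSE)
  set.seed(seed)
  tgt <- if (n_target > 0) sample(seq_len(nrow(genes)), n_target) else integer(0)

  mk_anchor <- function(g) {
    off <- round(stats::runif(1, window[1], window[2]))
    if (genes$strand[g] == "+") genes$tss[g] + off else genes$tss[g] - off
  }
  anchors <- vapply(tgt, mk_anchor, numeric(1))
  chroms <- genes$chrom[tgt]

  n_bg <- n_peaks - n_target
  if (n_bg > 0) {
    ci <- sample(seq_len(nrow(chromosomes)), n_bg, replace = TRUE)
    bg_anchor <- round(stats::runif(n_bg, peak_width,
                                    chromosomes$length[ci] - peak_width))
    anchors <- c(anchors, bg_anchor)
    chroms <- c(chroms, chromosomes$name[ci])
  }

  # BED 0-based start chosen so the interval midpoint (1-based) equals the
  # intended anchor exactly
  start0 <- pmax(0, round(anchors - peak_width / 2) - 1L)
  peaks <- data.frame(peak_id = sprintf("peak%04d", seq_len(n_peaks)),
                      chrom = chroms, start = start0,
                      end = start0 + peak_width,
                      score = round(stats::runif(n_peaks, 10, 1000)))
  carries <- if (implant_all) rep(TRUE, n_peaks)
             else seq_len(n_peaks) <= n_target
  seqs <- vapply(seq_len(n_peaks), function(i) {
    s <- random_dna(peak_width)
    if (carries[i]) {
      off <- sample.int(peak_width - nchar(motif) + 1L, 1L)
      substr(s, off, off + nchar(motif) - 1L) <- motif
    }
    s
  }, character(1))
  names(seqs) <- peaks$peak_id
  list(peaks = peaks, seqs = seqs,
       target_genes = genes$gene_id[tgt])
}
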