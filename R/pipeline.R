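#' Default end-to-end pipeline configuration
#'
#' Every tunable threshold of the pipeline surfaced as a nested key-value
#' list; [run_all()] accepts this list, a modified copy, or a YAML file
#' with the same structure.
#'
#' @param seed master seed propagated to every stage.
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_f2 = 300, bulk_size = 50, snps_per_chrom = 500,
                    depth_lambda = 50, parent_depth_lambda = 20,
                    causal_chrom = "chr1", causal_pos = 40e6,
                    cm_per_mb = 1, misclass_rate = 0),
    filter = list(min_depth = 4, rule = "either"),
    scan = list(span = 0.1, degree = 1, iterations = 2, quantile = 0.99,
                min_bulk_depth = 1),
    map = list(n_markers = 7),
    markers = list(primer_len = 21),
    express = list(n_genes = 2000, n_reps = 3, de_fraction = 0.1, fold = 4,
                   dispersion = 0.05, fc_threshold = 2, q_threshold = 0.05,
                   min_fpkm = 1),
    targets = list(n_genes = 200, n_peaks = 200, n_target = 20,
                   motif = "CTTGC", k = 5, n_shuffles = 10,
                   genic_window = c(-10000, 5000),
                   target_window = c(-2000, 500)))
}

manifest_entry <- function(stage, files, t0, warnings = character(0)) {
  list(stage = stage,
       files = as.list(stats::setNames(unname(tools::md5sum(files)), files)),
       elapsed_sec = round(as.numeric(Sys.time()) - t0, 3),
       warnings = warnings)
}

stage_complete <- function(manifest_old, stage, outdir) {
  if (is.null(manifest_old)) return(FALSE)
  e <- Filter(function(x) x$stage == stage, manifest_old$stages)
  if (!length(e)) return(FALSE)
  f <- e[[1]]$files
  all(vapply(names(f), function(p) {
    file.exists(p) && identical(unname(tools::md5sum(p)), f[[p]])
  }, logical(1)))
}

#' Run the full mapping-and-characterization pipeline
#'
#' Executes the stages in dependency order — simulate, filter, scan, map,
#' markers, effects, express, targets — under a single master seed, writing
#' each stage's outputs under `outdir` and a machine-readable JSON manifest
#' (config snapshot, per-stage file checksums, timings, warnings)
#' sufficient to verify bit-identical re-runs. When `resume = TRUE` and a
#' previous manifest is present, stages whose recorded output checksums
#' still match on disk are skipped.
#'
#' @param config a [pipeline_config()] list or the path of a YAML file with
#'   the same structure.
#' @param outdir output directory (created if missing).
#' @param resume skip stages whose outputs are intact.
#' @return the manifest, invisibly; written as `manifest.json` in `outdir`.
#' @export
run_all <- function(config = pipeline_config(), outdir = tempfile("bsarun"),
                    resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pathto <- function(f) file.path(outdir, f)
  manifest_path <- pathto("manifest.json")
  old <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else NULL
  stages <- list()
  warns <- character(0)
  wh <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  push <- function(stage, files, t0) {
    stages[[length(stages) + 1L]] <<- manifest_entry(stage, files, t0, warns)
    warns <<- character(0)
  }

  sc <- config$simulate
  simcfg <- sim_config(n_f2 = sc$n_f2, bulk_size = sc$bulk_size,
                       snps_per_chrom = sc$snps_per_chrom,
                       depth_lambda = sc$depth_lambda,
                       parent_depth_lambda = sc$parent_depth_lambda,
                       causal_chrom = sc$causal_chrom,
                       causal_pos = sc$causal_pos,
                       cm_per_mb = sc$cm_per_mb,
                       misclass_rate = sc$misclass_rate,
                       seed = config$seed)

  ## simulate -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  pop <- wh(simulate_f2_population(simcfg))
  bulks <- wh(build_bulks(pop))
  vcf <- pathto("snps.vcf")
  truth <- pathto("truth.yaml")
  if (!(resume && stage_complete(old, "simulate", outdir) &&
        file.exists(vcf))) {
    tab <- wh(simulate_bulk_readcounts(pop, bulks))
    write_snp_vcf(tab, vcf)
    yaml::write_yaml(list(causal_chrom = simcfg$causal_chrom,
                          causal_pos = simcfg$causal_pos,
                          n_speltoid = sum(pop$phenotype == "speltoid"),
                          n_normal = sum(pop$phenotype == "normal")),
                     truth)
  }
  push("simulate", c(vcf, truth), t0)

  ## filter -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  tab <- read_snp_vcf(vcf)
  flt <- run_filters(tab, config$filter$min_depth, config$filter$rule)
  fvcf <- pathto("snps_filtered.vcf")
  facc <- pathto("filter_accounting.tsv")
  write_snp_vcf(flt$kept, fvcf)
  write_tsv(flt$accounting, facc)
  push("filter", c(fvcf, facc), t0)

  ## scan ---------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  track <- wh(loess_fit_track(
    delta_snp_index(flt$kept, config$scan$min_bulk_depth),
    span = config$scan$span, degree = config$scan$degree,
    iterations = config$scan$iterations))
  regions <- wh(call_candidate_regions(track, config$scan$quantile))
  ftrack <- pathto("delta_index_track.tsv")
  freg <- pathto("candidate_regions.bed")
  write_tsv(track, ftrack)
  if (nrow(regions)) write_regions_bed(regions, freg) else writeLines(character(0), freg)
  push("scan", c(ftrack, freg), t0)

  ## map ----------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fmk <- pathto("marker_genotypes.tsv")
  fint <- pathto("interval.tsv")
  if (nrow(regions)) {
    top <- regions[which.max(regions$peak_fitted), ]
    cand_chr <- top$chrom
    cpos <- pop$snp_map$pos[pop$snp_map$chrom == cand_chr]
    sel <- cpos[round(seq(1, length(cpos), length.out = config$map$n_markers))]
    markers <- data.frame(marker_id = sprintf("M%02d", seq_along(sel)),
                          chrom = cand_chr, pos = sel)
    mtab <- genotype_markers(pop, markers)
    clen <- simcfg$chromosomes$length[simcfg$chromosomes$name == cand_chr]
    iv <- wh(delimit_interval(mtab, clen))
    write_tsv(mtab, fmk)
    write_tsv(data.frame(chrom = cand_chr, anchor = iv$anchor,
                         left_marker = iv$left_marker,
                         right_marker = iv$right_marker,
                         start = iv$start, end = iv$end), fint)
  } else {
    writeLines("no candidate region; mapping skipped", fint)
    writeLines(character(0), fmk)
    warns <- c(warns, "no candidate region; mapping skipped")
  }
  push("map", c(fmk, fint), t0)

  ## markers ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  amp <- synthetic_caps_amplicons(seed = config$seed + 3L)
  caps <- design_caps(amp$wt, amp$mut)
  kasp <- design_kasp(substr(amp$wt, 1, amp$snp_pos - 1),
                      substr(amp$wt, amp$snp_pos, amp$snp_pos),
                      substr(amp$mut, amp$snp_pos, amp$snp_pos),
                      substr(amp$wt, amp$snp_pos + 1, nchar(amp$wt)),
                      primer_len = config$markers$primer_len)
  fcaps <- pathto("caps_assays.tsv")
  fkasp <- pathto("kasp_assay.tsv")
  famp <- pathto("amplicons.fasta")
  write_tsv(caps, fcaps)
  write_tsv(data.frame(field = names(unclass(kasp)),
                       value = unlist(unclass(kasp))), fkasp)
  write_fasta(c(amplicon_wt = amp$wt, amplicon_mut = amp$mut), famp)
  push("markers", c(fcaps, fkasp, famp), t0)

  ## effects ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  syn <- synthetic_ap2_gene(seed = config$seed + 5L)
  eff <- apply_snv_and_classify(syn$gene, syn$snv$pos, syn$snv$ref, syn$snv$alt)
  isoforms <- list(full = splice_isoform(syn$gene, "full"),
                   skip9 = splice_isoform(syn$gene, "exon_skip", 9),
                   ir8 = splice_isoform(syn$gene, "intron_retention", 8))
  feff <- pathto("variant_effect.tsv")
  fiso <- pathto("isoforms.tsv")
  fprot <- pathto("proteins.fasta")
  write_tsv(data.frame(class = eff$class, codon_index = eff$codon_index,
                       ref_aa = eff$ref_aa, alt_aa = eff$alt_aa,
                       wt_protein_length = eff$wt_protein_length,
                       mut_protein_length = eff$mut_protein_length,
                       lost_domains = paste(eff$lost_domains, collapse = ",")),
            feff)
  write_tsv(do.call(rbind, lapply(names(isoforms), function(nm) {
    x <- isoforms[[nm]]
    data.frame(isoform = nm, event = x$event,
               protein_length = x$protein_length,
               termination_aa = x$termination_aa)
  })), fiso)
  write_fasta(stats::setNames(
    vapply(isoforms, function(x) if (isTRUE(x$no_product)) "" else x$protein,
           character(1)), names(isoforms)), fprot, type = "aa")
  push("effects", c(feff, fiso, fprot), t0)

  ## express ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  ec <- config$express
  sim <- simulate_expression_counts(ec$n_genes, ec$n_reps, ec$de_fraction,
                                    ec$fold, ec$dispersion,
                                    seed = stage_seed(config$seed, "expression"))
  degs <- call_degs(sim$counts, sim$groups, sim$gene_lengths,
                    ec$fc_threshold, ec$q_threshold, ec$min_fpkm)
  fcnt <- pathto("counts.tsv")
  fdeg <- pathto("deg_table.tsv")
  write_tsv(data.frame(gene_id = rownames(sim$counts), sim$counts,
                       is_de = sim$is_de), fcnt)
  write_tsv(degs, fdeg)
  push("express", c(fcnt, fdeg), t0)

  ## targets ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  tc <- config$targets
  genes <- simulate_gene_models(simcfg$chromosomes, tc$n_genes,
                                seed = stage_seed(config$seed, "peaks"))
  pk <- simulate_peaks_and_sequences(genes, simcfg$chromosomes,
                                     n_peaks = tc$n_peaks,
                                     n_target = tc$n_target,
                                     motif = tc$motif,
                                     seed = stage_seed(config$seed, "peaks") + 1L)
  asg <- assign_peaks(pk$peaks, genes, tc$genic_window, tc$target_window)
  tg <- putative_targets(asg)
  # re-use the DEG table by mapping gene ids (shared namespace by index)
  km <- kmer_enrichment(pk$seqs, k = tc$k, n_shuffles = tc$n_shuffles,
                        seed = stage_seed(config$seed, "peaks") + 2L)
  fgff <- pathto("genes.gff3")
  fbed <- pathto("peaks.bed")
  fpseq <- pathto("peak_seqs.fasta")
  fasg <- pathto("assignments.tsv")
  ftg <- pathto("targets.tsv")
  fkm <- pathto("kmer_enrichment.tsv")
  fov <- pathto("deg_overlap.tsv")
  write_gene_gff3(genes, fgff)
  write_peaks_bed(pk$peaks, fbed)
  write_fasta(pk$seqs, fpseq)
  write_tsv(asg, fasg)
  write_tsv(data.frame(gene_id = tg), ftg)
  write_tsv(utils::head(km, 50), fkm)
  ov <- intersect_degs(tg, degs)
  write_tsv(data.frame(direction = c(rep("down", length(ov$down)),
                                     rep("up", length(ov$up))),
                       gene_id = c(ov$down, ov$up)), fov)
  push("targets", c(fgff, fbed, fpseq, fasg, ftg, fkm, fov), t0)

  manifest <- list(config = config, stages = stages)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
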