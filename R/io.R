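#' Write a SNP table as minimal VCF 4.2
#'
#' Four samples in fixed order — parent_mut, parent_wt, mut_bulk, wt_bulk —
#' with AD (ref,alt) and DP fields. Parental AD is reconstructed from the
#' genotype call and depth (hom_alt = all alternate reads); bulk AD carries
#' the simulated or observed allele counts.
#'
#' @param table a `snp_table`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(table, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  "parent_mut\tparent_wt\tmut_bulk\twt_bulk"))
  pa_alt <- ifelse(table$parentA_gt == "hom_alt", table$parentA_dp,
                   ifelse(table$parentA_gt == "het",
                          round(table$parentA_dp / 2), 0L))
  pb_alt <- ifelse(table$parentB_gt == "hom_alt", table$parentB_dp,
                   ifelse(table$parentB_gt == "het",
                          round(table$parentB_dp / 2), 0L))
  fmt <- function(alt, dp) sprintf("%d,%d:%d", dp - alt, alt, dp)
  lines <- paste(table$chrom, table$pos, ".", table$ref, table$alt,
                 ".", "PASS", ".", "AD:DP",
                 fmt(pa_alt, table$parentA_dp),
                 fmt(pb_alt, table$parentB_dp),
                 fmt(table$mut_bulk_alt, table$mut_bulk_dp),
                 fmt(table$wt_bulk_alt, table$wt_bulk_dp),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SNP table back from the minimal VCF
#'
#' Inverse of [write_snp_vcf()]; genotype calls are re-derived from the
#' parental allele depths with [call_parent_genotype()] semantics (major
#' fraction >= `purity`).
#'
#' @param path VCF path.
#' @param purity homozygosity threshold for the re-derived parental calls.
#' @return a `snp_table`.
#' @export
read_snp_vcf <- function(path, purity = 0.9) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, "AD")
  dp <- function(col) {
    parts <- strsplit(ad[, col], ",", fixed = TRUE)
    ref <- as.integer(vapply(parts, `[`, character(1), 1L))
    alt <- as.integer(vapply(parts, `[`, character(1), 2L))
    list(ref = ref, alt = alt, dp = ref + alt)
  }
  pa <- dp("parent_mut"); pb <- dp("parent_wt")
  mb <- dp("mut_bulk"); wb <- dp("wt_bulk")
  callgt <- function(x) {
    frac_alt <- ifelse(x$dp > 0, x$alt / x$dp, NA_real_)
    ifelse(x$dp == 0, "no_call",
           ifelse(frac_alt >= purity, "hom_alt",
                  ifelse(1 - frac_alt >= purity, "hom_ref", "ambiguous")))
  }
  snp_table(chrom = fix$CHROM, pos = as.integer(fix$POS),
            ref = fix$REF, alt = fix$ALT,
            parentA_gt = callgt(pa), parentA_dp = pa$dp,
            parentB_gt = callgt(pb), parentB_dp = pb$dp,
            mut_bulk_alt = mb$alt, mut_bulk_dp = mb$dp,
            wt_bulk_alt = wb$alt, wt_bulk_dp = wb$dp)
}

#' Write gene models as GFF3
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene`-type features; the TSS is the 5' end by strand.
#'
#' @param path GFF3 path.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  out <- data.frame(gene_id = gr$ID,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out
}

#' Write peaks as BED 6
#'
#' @param peaks data.frame `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end),
    name = peaks$peak_id, score = peaks$score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read peaks from BED 6
#'
#' @param path BED path.
#' @return data.frame `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `score`.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(peak_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = gr$score)
}

#' Write candidate regions as BED (0-based half-open on disk)
#'
#' @param regions output of [call_candidate_regions()] (1-based inclusive
#'   internally).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end),
    name = sprintf("region%02d", seq_len(nrow(regions))),
    score = round(regions$peak_fitted * 1000))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param type `"dna"` or `"aa"` (protein).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a headered TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
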