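---
title: "Methods: bulked-segregant mapping and downstream target characterization"
author: "bsamapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant mapping and downstream target characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamapr)
```

# The problem

A dominant mutant allele — here modelled after an EMS-induced speltoid
(spelt-like, lax-spike) wheat mutant — segregates 3:1 in an F2 cross.
Bulked-segregant analysis (BSA) locates the causal locus by sequencing two
pooled DNA bulks of phenotype-contrasted plants and comparing pooled allele
frequencies along the genome. Once a candidate interval is found, the locus
is confirmed with recombinant counting at co-dominant markers, diagnostic
CAPS/KASP assays are designed for the causal SNP, its coding consequence is
predicted, and the downstream regulatory programme is characterized with
expression contrasts and transcription-factor binding peaks.

`bsamapr` implements that full chain as composable, seeded functions, with
a simulation module that generates every input the chain consumes so that
each statistical property can be verified against known truth.

# The genetic model

## F2 simulation

Each F2 individual is the union of two independent F1 gametes. Meiosis
follows the Haldane model: the number of crossovers on a chromosome is
Poisson with mean equal to its genetic length in Morgans
(`cm_per_mb` x length / 100), crossover positions are uniform, and there is
no interference. Genotypes at each SNP are the mutant-allele dosage
(0, 1, 2), which converges to 1:2:1; a dominant phenotype model maps
dosage >= 1 at the causal locus to the mutant (speltoid) class, giving the
3:1 ratio. Phenotyping is noiseless by default (`misclass_rate = 0`),
matching a fully penetrant spike-morphology trait scored at maturity.

Default study conditions follow the design of the motivating experiment:
50-plant bulks drawn without replacement from each phenotype class, an F2
of 300 plants (the two real populations had 642 and 200), and a two-
chromosome 2 x 50 Mb synthetic genome at 1 cM/Mb with 500 SNPs per
chromosome — large enough to carry one clear linkage peak while keeping a
complete mapping run under a second.

## Pooled sequencing depth

At each locus and bulk, total depth is Poisson(`depth_lambda`, default 50)
and the mutant-allele read count is Binomial(depth, f) with f the true
allele frequency among bulk members. This Poisson–Binomial compound is the
minimal faithful model of pooled sequencing; it omits sequencing error,
mapping bias and index hopping, so passing tests demonstrate statistical
correctness of the scan, not robustness to artefacts of real libraries.

A useful closed form anchors the whole scan: among dominant-phenotype F2
plants genotypes are AA:Aa = 1:2, so the expected mutant-allele frequency
in the mutant bulk at the causal locus is 2/3, while the wild-type bulk
(all aa) has 0. The expected delta-SNP-index peak height is therefore 2/3,
and unlinked loci have expectation 0 in both bulks' difference. The
acceptance checks verify the simulated mean at the causal locus is within
0.05 of 2/3 over 100 replicates.

# SNP filtering

Two filters mirror standard BSA practice: loci with sequencing depth
strictly below 4 in either parent are removed (a genotype cannot be
trusted when either inbred parent is shallow; the either/both rule is
configurable), then loci whose two parental genotype calls agree — or
where either call is heterozygous/ambiguous, which in inbred parents
signals artefact — are removed as uninformative. Every run returns an
accounting record whose categories are asserted to sum to the input total.
On a category-coded table of 1,795,250 loci with 1,604,480 shallow and
126,574 monomorphic-among-deep, 64,196 loci survive; the filter is
vectorized and handles that scale in seconds.

# The delta-SNP-index scan

Per locus, each bulk's SNP-index is its mutant-allele read fraction
(`NA` below `min_depth`, default 1); the scan statistic is
|index_mut − index_wt|, LOESS-smoothed along each chromosome separately
(no smoothing across chromosome boundaries). Defaults: `span = 0.1` of a
chromosome's loci, local degree 1, and two bisquare robustness iterations;
fitted values are clipped to [0, 1]. The fit uses R's tricube-weighted
local regression; chromosomes with too few informative loci are skipped
with a warning.

Candidate regions are maximal runs of consecutive loci whose fitted value
reaches the genome-wide empirical 99th percentile. An all-tied track is
degenerate; rather than failing, each chromosome is returned as one region
flagged `degenerate` with a warning. A permutation alternative
(`permutation_null_max`, phenotype labels shuffled across bulk membership)
provides an empirical null for the genome-wide maximum when a calibrated
threshold is preferred.

## What the scan can and cannot localize

Across 100 seeded default runs the argmax of the fitted track lands within
5 Mb of the causal locus in ~96 runs, and the delimited flanking-marker
interval (below) brackets it in all runs. The 99th-percentile *region*
itself, however, contains the causal position in only ~29/100 runs. This
is an information limit, not a smoothing artefact: the top 1% of loci span
about 1 Mb of a 100 Mb genome, while with 50-plant bulks (~200 sampled
gametes) the true pooled allele-frequency profile is flat within roughly a
megabase of the causal locus — the peak of the noisy fitted curve
therefore wanders by a median of ~0.9 Mb. Sub-megabase localization from
bulks of this size is not achievable by any threshold rule; region calls
should be read as peak markers, with fine mapping delegated to
recombinant counting.

# Linkage confirmation

A recombinant is an individual whose marker genotype is incompatible with
the causal genotype implied by its phenotype: recessive-phenotype plants
must be aa, so marker AA or Aa counts; dominant-phenotype plants carry
A_, so only marker aa counts. Heterozygous markers in dominant-phenotype
plants are compatible and not counted — the dominant model makes Aa
indistinguishable from AA on phenotype alone. The marker with the fewest
recombinants anchors the interval; walking outward, the nearest marker
with strictly more recombinants on each side becomes a flank (chromosome
ends otherwise), and tied minima broaden the interval conservatively.

The Mendelian ratio test is a Pearson chi-square GOF with df = 1, upper-
tail p from the chi-square distribution. Yates continuity correction is
off by default. At small n the discrete binomial makes the uncorrected p
deviate from the exact enumeration by up to ~0.1; with the correction
enabled the approximation tracks the exact test within ~0.005 at n = 30 —
the test suite verifies exactly that, and the correction is exposed as an
argument for small samples.

# Diagnostic marker design

## CAPS

For a wild-type/mutant amplicon pair, every enzyme in the packaged table
whose recognition-site count differs between alleles yields an assay.
Sites are found by IUPAC matching on both strands (verified against a
sliding-window oracle); each site cuts once, `cut_offset` bases after the
recognition start on the matching strand (DdeI = CTNAG, cut between C and
T). Fragment lengths always partition the amplicon. Heterozygote banding
is the set union of the two homozygote band sets — an equimolar allele mix
with no partial-digest or heteroduplex bands — reproducing the classic
one-band / two-band / three-band genotype readout of a gained site in a
395-bp amplicon. Assays are ranked by the minimal pairwise band-length
difference (gel separability).

One numerical caveat is intrinsic: for off-centre cutters a single
per-site cut coordinate cannot be mirror-symmetric, so predicted bands
shift by the overhang length (3 nt for DdeI) when both amplicons are
reverse-complemented. Band counts and totals are invariant; per-band sizes
agree within the overhang, which is below gel resolution.

## KASP

Allele-specific forward primers place the SNP at their 3'-terminal base,
differ only there in their genomic portion, and carry the standard FAM
(`GAAGGTGACCAAGTTCATGCT`) and HEX (`GAAGGTCGGAGTCAACGGATT`) 5' tails; the
common reverse primer is the reverse complement of the right flank's first
`primer_len` bases (default 21). Primer thermodynamics and genome-wide
uniqueness are out of scope.

# Coding-consequence and isoform prediction

Gene models are explicit: a genomic sequence, ordered non-overlapping
exons, strand and optional protein-domain intervals in amino-acid
coordinates. Translation uses a self-contained standard codon table and
stops at the first in-frame stop (verified against an independent
translation route). A single-nucleotide variant is classified
silent/missense/nonsense by re-translation; for truncations, every
annotated domain extending beyond the truncated length is reported lost.
Splice events are declared, not predicted: exon skips remove one exon
(skipping the first exon loses the start codon and is flagged
no-product), intron retentions merge two exons across their gap, and the
product is re-translated. The packaged `synthetic_ap2_gene()` realizes
the canonical architecture of this gene family's classic mutant: a
1,344-nt, 10-exon CDS encoding 447 aa with two AP2-like domains, where a
G-to-A transition at codon 224 creates a premature stop (223-aa product
losing the second domain) and skipping the in-frame 117-nt exon 9 gives
408 aa. miRNA target-site mismatches are counted under antiparallel
pairing with G:U wobble counted as a mismatch by default (binary model,
configurable).

# Expression

Relative qPCR expression uses 2^-ddCT with the amplification efficiency
fixed at 2 and technical replicates paired by index and averaged;
replicate scatter propagates by the delta method
(sd_rel = ln(2) x rel x sd_ddCT). FPKM is
count x 1e9 / (length x total). Differential expression deliberately uses
a transparent test rather than a shrinkage framework: Welch's t on
log2(FPKM + 1) per gene, Benjamini–Hochberg adjustment across tested
genes (genes below mean FPKM 1 in both groups are excluded and flagged),
and the published decision rule — at least twofold change and FDR < 0.05.
The group reference is the first factor level (alphabetical for bare
character labels), so exchanging labels flips every fold change's sign.

Power at n = 3 per group is limited by the per-gene variance estimate:
with negative-binomial dispersion 0.02 and deep counts the caller recovers
>= 84% of implanted fourfold changes, but at dispersion 0.05 recall drops
to ~16% even though the empirical FDR stays below 1%. The test suite
asserts FDR control at the generator's default dispersion (0.05, a
realistic biological-replicate value) and recall in the low-dispersion
deep-coverage regime; both regimes are honest consequences of using an
unmoderated test at n = 3.

# DAP-seq target assignment

Peak anchors default to the interval midpoint (a summit column can be
used when present). Each peak is assigned to the same-chromosome gene
minimizing |signed TSS distance|, with strand-aware sign (negative =
upstream) and lexicographic tie-breaking. Two inclusive windows classify
assignments: genic context [-10 kb, +5 kb] and putative direct targets
[-2 kb, +500 bp]. Putative targets intersected with the DEG table are
partitioned by direction.

k-mer enrichment (default k = 5, both strands collapsed to canonical
classes) scores log2((c_fg + 1) / (c_bg / n_shuffles + 1)) against a
background of 10 per-sequence shuffles. The background preserves each
sequence's dinucleotide composition via a first-order Markov resample of
its own transition frequencies — a deliberate, documented substitute for
both exact Eulerian doublet shuffling and full PWM discovery; it suffices
to recover a fully implanted 5-mer as the top class in 20/20 seeded runs
and to show monotone score decay as the implant fraction drops.

# The pipeline

`run_all()` executes simulate → filter → scan → map → markers → effects →
express → targets under one master seed (each stage draws from a derived
sub-seed), writing standard formats (VCF 4.2 with AD/DP, GFF3, BED 6,
FASTA, TSV) plus a JSON manifest of per-stage file checksums, timings and
captured warnings. Identical config and seed reproduce bit-identical
outputs (asserted in the tests); on resume, intact simulate-stage outputs
are detected by checksum and not rewritten, while downstream stages are
recomputed deterministically from them.

# Problem sizes in the tests

The suite exercises: filtering at the published scale (1.8 M loci); 100
seeded mapping runs at the default desk scale for localization rates; 100
F2 populations of 10,000 plants for segregation; 20 seeds each for motif
recovery and DEG error rates; and 1,000 random sequences against the
site-finding oracles. These sizes were chosen so each property is
measured with enough replicates to be stable while a full run of the
suite stays in the minutes range on a single core.

# Known limitations

- No read-level simulation, sequencing error, or alignment artefacts; the
  depth model is Poisson–Binomial only.
- The scan's region caller cannot localize below ~1 Mb with 50-plant
  bulks (see above); use the marker interval for fine mapping.
- The DE test is unmoderated Welch; at n = 3 and realistic dispersion its
  recall is low, and no claim of equivalence to shrinkage-based callers
  is made.
- Splice events are enumerated by declaration; no splice-site strength or
  discovery model.
- k-mer enrichment is not motif discovery: no positional weighting, no
  EM, background by Markov resample rather than exact doublet shuffle.
- Peak assignment considers the nearest TSS only; enhancer-style
  long-range or cross-chromosome regulation is out of scope.
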