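---
title: "Detecting selective sweeps with sweepscan: models, statistics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Domestication leaves a characteristic footprint in a genome: around the
targets of sustained artificial selection, the domestic population loses
genetic diversity relative to its wild relatives, allele frequencies
diverge, and the site-frequency spectrum shifts toward rare variants.
`sweepscan` implements the standard window-based workflow for finding such
regions from whole-genome resequencing data of a wild and a domestic group
(the motivating system is waterfowl: wild mallard-type ducks versus
domestic egg- and meat-type breeds, but nothing in the package is specific
to birds): hard-filter SNPs from a multi-sample VCF, compute per-window
diversity and differentiation statistics, call joint outlier windows,
merge them into candidate selected regions, and attach the overlapping
genes. Around that core it provides the companion analyses such a study
reports -- SNP functional annotation, LD decay, and an individual-level
neighbor-joining tree -- and, crucially, a coalescent simulator with
planted sweeps so that every stage can be validated against ground truth
without any real dataset.

## Data model

Everything operates on a *genotype matrix*: per-site, per-sample diploid
alternate-allele dosages in {0, 1, 2, NA} plus site metadata (position,
alleles, phred site quality, aggregate depth). `read_vcf()` keeps SNP
records only (all alleles single bases); `apply_site_filters()` implements
the resequencing-style hard filter -- site quality >= 20 and aggregate
depth in [2, 1000] by default, biallelic records only. Two interpretation
choices are deliberate and documented rather than prescribed by any
standard: the depth filter applies to the site-level aggregate DP (a
single 2--1000 range matches an aggregate quantity, and that is what
mpileup-style callers emit), and missing genotypes are excluded from
chromosome counts, never imputed. Multiallelic records are dropped rather
than split, because every downstream formula assumes biallelic sites.

## Window statistics

Statistics are computed in sliding windows (default 40 kb with 20-kb
step). Per population and site with `n` genotyped chromosomes and `a`
alternate alleles, the per-site heterozygosity is `2a(n-a)/(n(n-1))`;
summed over the window and divided by the *full window length* it gives
per-bp nucleotide diversity (theta-pi). Watterson's estimator is
`S/(a1 L)` with `S` the segregating sites and `a1` the harmonic number of
`n - 1`. Tajima's D follows the classical variance normalization; because
missingness lets `n` vary by site while the normalizing constants need a
single `n`, the constants are evaluated at the window-median chromosome
count (a robust single summary; D is reported missing when `S = 0` or the
median falls below 4). Normalizing by full window length rather than
callable sites is a stated limitation: without an accessibility mask,
per-bp values are slight underestimates wherever coverage is incomplete.

FST uses ratio-of-sums aggregation: per-site variance components are
summed across the window before the ratio is taken, the standard choice in
resequencing scans because per-site ratios are noisy. Two estimators are
available: Weir--Cockerham (default) in its allele-count form -- the
random-union-of-gametes variant, since the allele-count substrate carries
no heterozygote counts -- and Hudson's estimator in the ratio-of-averages
form recommended by Bhatia and colleagues, which has the clean pairwise
interpretation `1 - Hw/Hb` used by the calibration below. Negative
estimates are reported as computed, never clamped.

The sweep scan combines FST with `log2(theta_pi_wild/theta_pi_domestic)`;
positive values mark diversity loss in the domestic group. Windows where
either diversity is zero have an undefined ratio and are excluded from
quantiles.

## The scan

Thresholds are *realized* empirical quantiles (type-7 interpolation; the
default is the upper 5% of each arm) computed over the windows where both
statistics are defined. Published scans report the realized cutoffs their
data produced; since these are data-dependent quantities, `sweepscan`
computes and logs them rather than hard-coding any number. A window is an
outlier when it reaches both cutoffs; overlapping or book-ended outlier
windows merge into one candidate region (windows, not sites, are the unit
of selection). Genes overlap a region when their transcript span shares at
least one bp -- book-ended gene/region pairs do not count. The Tajima's D
contrast assigns each gene the mean D of its overlapping windows and
compares selected genes against all remaining genes with a two-sided
Mann--Whitney U test: exact enumeration when both groups have at most 8
untied values, otherwise the normal approximation with tie correction (no
continuity correction).

## Annotation

Sites are classified with the usual variant-annotation vocabulary and
precedence: exonic (inside a CDS) > splicing (intronic, within 2 bp of a
junction) > UTR (exon minus CDS) > intronic > upstream/downstream (within
1 kb of the transcript bounds, strand-aware) > intergenic. The 2-bp
splicing window, 1-kb flank and precedence order follow the conventions of
the widely used annotators; one transcript per gene is assumed, and where
several genes cover a site the most severe category wins. Coding effects
rebuild the codon around the site (strand-aware), substitute the
alternate base and compare amino acids under the standard genetic code;
any change, including stop gain/loss, is nonsynonymous. The tests verify
every possible single-base CDS substitution of a two-exon gene against an
independent full-CDS translation oracle on both strands.

## LD decay

Haplotype-phase information is generally unavailable in this setting, so
`pair_r2()` uses composite (Rogers--Huff) LD: the squared Pearson
correlation of diploid dosages over pairwise-complete samples. This is the
standard phase-free surrogate for haplotype r2 and differs from tools that
estimate two-locus haplotypes by EM; that divergence is deliberate and
means absolute r2 levels are comparable within, not across, methods. Rare
variants make r2 erratic, so a minor-allele-frequency floor of 0.05
(configurable) is applied before pairing; pairs up to 500 kb apart are
binned by distance. Under independence the expected composite r2 is
`1/(n-1)` for `n` diploids -- the null the validation suite checks.

## Trees

The individual-level distance is the allele-sharing p-distance,
`sum |g_i - g_j| / (2 m)` over the `m` jointly genotyped sites -- the
natural "proportion of differing allele copies" for unphased diploid
dosages, lying in [0, 1]. Neighbor joining is the classical Saitou--Nei
algorithm with the Q-criterion; ties are broken by the lexicographically
smallest pair of representative labels so results never depend on input
order, and negative branch estimates are clamped to zero with the deficit
moved to the sibling edge. Bootstrap support resamples SNP columns with
replacement (default 1000 replicates) and scores each internal edge by the
percentage of replicates containing the same leaf bipartition, ignoring
branch lengths.

## The synthetic-data generator

The generator draws one independent Kingman genealogy per 40-kb locus
(within demes at rate `k(k-1)/2 / (2 Ne)`), with either a clean split --
two isolated demes merging into a single ancestral deme of size `Ne` at
time `T` looking backward -- or symmetric island migration. Infinite-sites
mutations fall on branches as a Poisson process and chromosomes are paired
into diploids. Defaults are chosen to emulate a wild/domestic duck-style
resequencing design and are fixed once: `mu = 1.6e-9` per bp per
generation with a one-year generation time (the rate used for waterfowl
demographic inference), `Ne = 78125` so that the neutral per-bp diversity
`4 Ne mu = 5e-4` matches the order observed in such genomes, 20 wild and
30 domestic diploid individuals (the pooled group sizes of a ten-per-breed
design), and a split `T = 0.2 Ne` generations ago giving a genome-wide
Hudson FST around 0.09 -- the order of a wild/domestic livestock
contrast.

Sweeps are planted as *star genealogies*: in designated loci the domestic
lineages are withheld from coalescence until `tau` and then merged
simultaneously. This is not a trajectory-conditioned sweep model, but it
produces exactly the detection signature the scan looks for -- expected
per-bp diversity `2 mu tau` in the swept deme, strongly negative Tajima's
D, elevated FST -- with closed-form ground truth. What the generator does
*not* emulate: intra-locus recombination (loci are internally fully
linked, so within-window LD is complete), sequencing error, alignment
artifacts, and accessibility variation. Passing the validation suite
therefore demonstrates the correctness of the estimators and the scan
logic under the stated model, not robustness to the technical noise of
real data.

Two analytic calibrations close the loop between generator and
estimators. First, neutral single-deme simulations must recover
`theta_pi` and `theta_W` near `4 Ne mu`. Second, under a clean split the
expected pairwise between-deme coalescence time is `T + 2 Ne`, so Hudson's
`1 - Hw/Hb` has expectation `T/(T + 2 Ne)` -- 0.2, 0.5 and 0.8 at
`T = 0.5 Ne, 2 Ne, 8 Ne`.

One empirical subtlety is worth recording: windowed Tajima's D has a small
*negative* expectation under neutrality at these problem sizes (about
-0.1 for 20 chromosomes and `theta L = 20` per locus without
recombination). This is the familiar finite-S skew of D's studentization,
not a bug; an independent coalescent library reproduces it to within
Monte-Carlo error. Averages of windowed D over a genome should therefore
be expected slightly below zero even without any selection.

## Validation problem sizes and numerical choices

The shipped validation suite uses desk-scale problem sizes chosen so the
whole suite runs in minutes on one core: 500 neutral 40-kb windows for
estimator recovery (Monte-Carlo standard error about 2% of theta), 300
windows per split time for FST calibration, and 1000 windows with ten
planted 200-kb sweep regions (five consecutive loci each, so the 50 swept
windows match the scan's 5% outlier budget) for end-to-end recovery. The
sweep-recovery scan uses non-overlapping 40-kb windows aligned to the
simulator's locus grid, since loci are unlinked by construction and
half-overlapping windows would only blur the planted truth. On synthetic
data these settings recover 10/10 planted regions with the full reported
region span inside planted territory.

Other numerical conventions: empirical quantiles are type 7 (R's
default linear interpolation); window tiling emits a trailing truncated
window only when it covers new bp, and truncated windows are normalized by
their true length; degenerate inputs (no segregating site, a monomorphic
locus in `pair_r2()`, zero synonymous sites in the annotation ratio)
return missing values rather than errors; and all randomness flows from a
single user-supplied seed, giving byte-identical VCF/TSV/BED/Newick
outputs on reruns.

## A worked example

```{r example}
library(sweepscan)

params <- coalescent_params(seed = 1)        # wild/domestic split defaults
sweeps <- sweep_spec(data.frame(start = 2000001, end = 2200000),
                     tau = 0.02 * 2 * 78125, deme = "domestic")
ds <- simulate_dataset(params, sweep = sweeps, dir = "simdata")

cfg <- list(vcf = ds$paths[["vcf"]], popmap = ds$paths[["popmap"]],
            gff = ds$paths[["genes"]], fasta = ds$paths[["fasta"]],
            outdir = "out", seed = 1, pair = c("wild", "domestic"))
run_pipeline(cfg, stages = c("filter", "annotate", "stats", "sweep",
                             "ld", "tree"))
```

The run log records the realized cutoffs and counts; `out/cdrs.bed` holds
the merged candidate regions and `out/selected_genes.tsv` the overlapping
genes.

## Known limitations

* Per-bp normalization by full window length ignores callability.
* The Weir--Cockerham estimator is the allele-count variant; with strong
  inbreeding or genotyping artifacts the genotypic form would differ.
* Composite r2 is not haplotype r2; compare LD curves only within-method.
* One transcript per gene in annotation; overlapping isoforms collapse to
  the most severe call.
* The simulator's loci are non-recombining islands: it validates window
  statistics, not methods that look across windows.
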