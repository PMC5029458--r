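---
title: "Calling random allelic expression imbalance in clonal cell panels"
author: "raex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling random allelic expression imbalance in clonal cell panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raex)
```

# The measurement model

Most autosomal genes express both alleles. A minority instead commit, clone
by clone, to one allele — genomically imprinted genes always silence a fixed
parental allele, cis-regulatory variants skew expression toward the same
allele in every cell, X inactivation silences one X per cell, and a small
set of genes makes a *stochastic* choice: sister clones grown from single
cells of the same culture express opposite alleles, or one clone is
monoallelic where another is biallelic. `raex` implements the full analysis
for detecting this **random allelic expression imbalance (AEI)** from
two-channel SNP genotyping arrays run on paired genomic DNA (gDNA) and cDNA
of clonal cell lines, and for relating it to promoter DNA methylation.

The quantitative unit is the allele fraction
$$\beta = \frac{X}{X+Y},$$
where $X$ and $Y$ are the scanned intensities of the two allele channels at
a SNP probe. For a heterozygous SNP, gDNA gives $\beta \approx 0.5$; the
cDNA $\beta$ moves toward 0 or 1 as expression becomes allele-specific. The
per-SNP statistic is
$$\Delta\beta = \beta_{\text{cDNA}} - \beta_{\text{gDNA}},$$
which cancels probe-specific chemistry bias; its gene-level score is the
mean of $|\Delta\beta|$ over all informative SNPs of the gene (isoform-level
aggregation is available, and a penalty hook `penaltyConfig()` can shrink
scores of SNP-rich transcripts by $n/(n+k)$).

Processing order: channel intensities are quantile-normalized (all
sample-and-channel columns of one material pooled into a single reference
distribution, so X and Y become directly comparable), cells whose total
intensity $X+Y$ does not strictly exceed 750 are discarded as background,
heterozygous SNPs are selected from gDNA ($\beta \in [0.3, 0.7]$ by default,
configurable — genotyping itself is the array platform's job and these bands
are deliberately generous), and gene scores are classified:

| class | gene score $\bar{|\Delta\beta|}$ | allele fold-ratio |
|-------|------------------|--------------------|
| BA (biallelic) | $< 0.1$ | $< 1.5$ |
| SK (skewed) | $[0.1, 0.2)$ | $1.5$ – $2.3$ |
| MA (monoallelic) | $\ge 0.2$ | $\ge 2.3$ |
| ND (not detected) | no informative SNP passing the filter | — |

The fold-ratio mapping assumes a heterozygous gDNA $\beta$ of 0.5:
$r = (0.5+\Delta\beta)/(0.5-\Delta\beta)$, so `deltaToRatio(0.1) == 1.5`.
Note that the traditional "2.85-fold" anchor quoted for the MA boundary is
not consistent with this symmetric mapping ($r(0.2) \approx 2.33$;
$r = 2.85$ corresponds to $\Delta\beta \approx 0.24$); the $\Delta\beta$
thresholds are authoritative here because classification is defined on
$\Delta\beta$, and the ratios are reported for orientation only. The class
intervals are lower-closed ($0.1 \mapsto$ SK, $0.2 \mapsto$ MA) — a
measure-zero convention made explicit because the defining inequalities
alone leave the boundary points unassigned.

Imprinted genes and the α/γ protocadherin clusters (whose overlapping gene
annotations would double-count probes) are flagged and excluded from the
autosomal summaries via user-supplied gene lists; chromosome X genes are
excluded from autosomal statistics but kept in a separate report
(`chrXReport()`) whose strongly bimodal $|\Delta\beta| \approx 0.5$
distribution is a useful calibration check for the MA threshold.

# Sister-clone comparison and frequency estimators

Within one developmental state, `detectRandomAEI()` categorizes every gene
across sister clones:

* **RANDOM_MA** — monoallelic in two or more clones with *opposite*
  expressed alleles (both alleles demonstrably functional);
* **RANDOM_AEI** — monoallelic in at least one clone with a biallelic
  sister clone;
* **CONSTANT_MA** — monoallelic with one direction wherever detected and no
  biallelic sister: the cis-genetic (eQTL-like) candidate class;
* **INDETERMINATE_MA** — monoallelic somewhere but undetected in every
  other clone, which blocks the random call rather than supporting it;
* **NOT_MA** otherwise.

A clone that is monoallelic next to a *skewed* (not biallelic) sister of
the same direction stays CONSTANT_MA: we require a clean biallelic sister
before calling randomness, the conservative reading. A gene monoallelic in
several clones with the remainder undetected is INDETERMINATE_MA for the
same reason.

Two frequency estimators are provided. The **clonal estimator**
(`summarizeFrequencies()`) counts, over all non-excluded autosomal genes
expressed in at least one clone of the group, how many are MA in any clone
and how many of those qualify as random AEI. The **polyclonal estimator**
(`polyclonalEstimate()`) exploits mixing: in a population grown from many
founder cells, independent fair allele choices average out, so a gene MA in
a clone but biallelic in the polyclonal sample is a random-AEI candidate,
while one still MA (or skewed) in the polyclonal sample is a cis-genetic
candidate. Transitions between developmental states
(`transitionAnalysis()`) classify each gene's state-consensus pair —
RESET (MA→BA), RETAINED, TO_SKEWED, LOST, DE_NOVO, STABLE_BA — where the
consensus of a state is MA if any clone is MA, else SK, else BA, else ND.
Set overlap against externally defined gene sets (e.g. reprogramming
hotspots) uses the exact hypergeometric test (`hotspotOverlap()`, two-sided
Fisher convention: the sum of point probabilities not exceeding the
observed table's).

**Rounding conventions.** Every percentage in a report is re-derivable from
the counts next to it. Genome-wide gene-frequency percentages are printed
truncated at two decimals ($126/7334 \to 1.71\%$, $62/7334 \to 0.84\%$),
which is the convention evident in the published figures this style of
analysis reports; coarser percentages (whole and one-decimal) are rounded
half-up ($42/48 \to 88\%$, $37/63 \to 58.7\%$). `aeiPercent()` exposes both
modes explicitly rather than hiding the mixture.

# Methylation comparisons

Methylation β matrices (CpG probe × sample, values in $[0,1]$) are consumed
as produced by upstream 450K preprocessing; `raex` applies list-based probe
filters (cross-hybridizing probes), counts differentially methylated
positions ($|\Delta\beta| > 0.3$, strict), summarizes autosomal non-CpG
methylation (elevated non-CpG methylation marks the pluripotent state), and
clusters samples by $1 - r$ Pearson distance with average linkage.

The central test pairs, per CpG probe of a gene-region annotation (TSS200,
first exon, gene body, or CpG-island membership), the mean β over the
clones where the gene is MA against the mean over its biallelic sister
clones, and applies a Wilcoxon **signed-rank** test to the per-probe paired
differences. The probe is the pairing unit (averaging within each clone
group first) because it maximizes the number of pairs and matches how
probes are attached to gene regions; a paired test is used because the
design pairs MA clones with their own sister clones. Zero differences are
dropped, direction follows the sign of the median difference, and p-values
are exact up to 50 nonzero pairs. The exact null is computed by convolving
the (possibly tied, average-rank) rank distribution — `stats::wilcox.test`
declines to be exact under ties, but tied paired differences are routine in
β data, and conditioning on the observed rank vector handles them exactly
(six equal positive differences give the textbook $2/2^6 = 0.03125$).
Beyond 50 pairs the normal approximation with continuity correction takes
over. The unpaired rank-sum analogue (`promoterSignalCompare()`) serves the
promoter chromatin-signal comparisons, on per-gene signals over
strand-aware promoter windows (TSS −1000/+500 bp, 1-based inclusive,
upstream on the larger-coordinate side for minus-strand genes).

# The synthetic generator

`simulatePanel()` produces raw two-channel gDNA and cDNA intensity sets, a
probe and sample manifest, and a truth table, fully determined by one seed.
What it emulates, and the defaults chosen:

* heterozygous gDNA β centred at 0.5 (per-probe bias sd 0.01); 15% of
  probes homozygous in the background, hence uninformative;
* cDNA β per gene class: biallelic at 0.5; cis-skewed at a per-gene ratio
  drawn on $[1.6, 2.2]$ — inside the skewed band and clear of both class
  boundaries, since ratios above 2.33 would be MA by the $\Delta\beta$
  thresholds themselves; imprinted and random-MA genes at ratio 5 (a clear
  monoallelic signal whose 100-founder binomial mixture still lands inside
  the biallelic band); X-inactivated genes at ratio 99, giving the bimodal
  near-0.5 $|\Delta\beta|$ pattern. Platform noise sd 0.02 per probe;
* random-MA allele choice: an independent fair coin per gene and clone
  (`pMaCommit` < 1 optionally leaves a clone biallelic first, emulating
  imbalance established in only some sister clones, which is what gives
  within-state MA/BA sister pairs for the methylation contrast);
* whole-X inactivation: one active-X draw per clone, with a per-gene
  orientation flip because the manifest's A/B labeling is arbitrary per SNP;
* in iPSC states, each random-MA gene is reset to biallelic with
  probability 0.85, emulating epigenetic reprogramming;
* log-normal total intensities (median 3000, log-sd 0.4) with 5% of cells
  pushed below the 750 filter, and 3% gene × clone expression dropout;
* class proportions default to a *calibration mix* (8% random-MA, 5%
  skewed, 5% X, 2% imprinted). Real genome-wide rates put random AEI
  below 1% of genes; enriching the rare classes keeps truth-recovery
  statistics estimable on 1000-gene panels, which is the panel size the
  test suite uses to keep runs fast. What passing recovery tests shows is
  therefore calibration of the *caller*, not a forecast of genome-wide
  frequencies.

`simulatePolyclonal()` re-draws the clone-level allele choice per founder
cell (default 100 founders) and averages: random choices mix toward 0.5
while cis-driven skews persist — the logic the polyclonal estimator relies
on. `simulateMethylation()` elevates TSS200/first-exon (island) probes by
0.2 and depresses gene-body probes by 0.1 in clones where a gene is
monoallelic, adds beta-distributed noise (sd 0.05), elevates non-CpG probes
in iPSC-state samples, and gives each developmental state a small shared
probe-level deviation so samples cluster by state.

# Numerical choices and degenerate inputs

* β is undefined (absent, never 0/0) where $X+Y=0$; missing cells propagate
  as absent with no imputation.
* The background filter is strictly "greater than 750"; a total of exactly
  750 fails. DMP counting is likewise strictly $>0.3$, guarded against
  binary representation error so a difference of exactly 0.3 never counts.
* `deltaToRatio` computes $(5+10\Delta\beta)/(5-10\Delta\beta)$ so the
  decimal thresholds map to exact binary values; $\Delta\beta \ge 0.5$
  reports `Inf` (complete monoallelism).
* Classification needs `minInformative` (default 1) passing SNPs; below
  that the call is ND, with no score.
* Sample clustering orders samples by id before computing distances so tie
  handling is deterministic, and refuses constant β vectors by name.
* All stochastic stages of a pipeline run are governed by one seed;
  `writeReportBundle()` output is byte-identical across reruns of the same
  config.

# Known limitations

* **Quantile normalization of degenerate inputs.** With zero measurement
  noise the simulated intensity distribution is a set of discrete clouds
  separated by empty gaps; channel-pooled quantile normalization then maps
  small rank misalignments (composition imbalance between the X and Y
  columns) across whole gaps, corrupting roughly 1% of probe β values
  regardless of panel size. The classifier itself recovers zero-noise truth
  exactly when fed β values; through the raw-intensity route we assert
  ≥ 98% class agreement at zero noise. Real arrays have continuous,
  overlapping intensity distributions, where this artifact is negligible —
  but it is why normalized β should not be treated as exact at the third
  decimal.
* **Polyclonal calls at platform noise.** The binomial mixing bound (over
  99% of random-MA genes inside the biallelic band at 100 founders) applies
  to the mixture allele fraction. Measured through the intensity layer,
  single-SNP genes add platform noise (combined sd ≈ 0.04), so a percent or
  two of borderline calls is expected and the pipeline-level fraction
  should be read accordingly.
* Direction calls assume the probe manifest's A alleles are consistently
  phased within a gene; unphased manifests make within-gene directions
  incoherent (they surface as DISCORDANT) without affecting the magnitude
  score.
* The generator does not model reprogramming biology beyond the per-state
  reset coin — no passage drift, no aberrant-reprogramming hotspots — and
  the methylation model couples promoter hypermethylation to the MA state
  deterministically; passing tests show the statistics behave as designed,
  not that real clones obey the model.

# Problem sizes used by the test suite

Unit and property tests run on panels of 60–200 genes; calibration
(recovery, polyclonal mixing) uses 600–2000 genes and 2–5 clones; the
methylation power check uses 100 replicates of 50 TSS200 probe pairs at
effect 0.2 and noise 0.05. These sizes were chosen to estimate each
property with comfortable binomial margins while keeping a full suite run
around half a minute.
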