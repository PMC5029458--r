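# raex — random allelic expression imbalance in clonal cell panels

Most autosomal genes express both alleles, but a small set makes a
stochastic, mitotically stable choice of one allele during lineage
commitment: sister clones grown from single cells of the same culture can
express opposite alleles of the same gene, while a polyclonal population of
the same cells looks biallelic because independent choices average out.
`raex` is an R package for detecting this **random allelic expression
imbalance (random AEI / random monoallelic expression)** from two-channel
SNP genotyping arrays run on paired genomic DNA and cDNA of clonal cell
lines — e.g. neural stem cell clones before and after reprogramming to
induced pluripotency — and for relating allelic state to promoter DNA
methylation.

## The statistic at the core

For a SNP probe with channel intensities *X* (A allele) and *Y* (B allele),
the allele fraction is β = X/(X+Y). After channel-pooled quantile
normalization and a background filter (X+Y must exceed 750), the per-SNP
statistic at heterozygous SNPs is

    Δβ = β_cDNA − β_gDNA

and a gene's score is the mean |Δβ| over its informative SNPs. Genes are
classified **BA** (biallelic, score < 0.1), **SK** (skewed, 0.1–0.2), **MA**
(monoallelic, ≥ 0.2; fold-ratio ≥ (0.5+0.2)/(0.5−0.2)) or **ND** (not
detected). Across sister clones of one state, a gene MA in one clone with a
biallelic sister (`RANDOM_AEI`), or MA in two clones with opposite alleles
(`RANDOM_MA`), is random AEI; constant-direction MA without a biallelic
sister is the cis-genetic candidate class. Genome-wide frequency is
estimated two ways: from the clones alone, and from clone-MA genes that
collapse to biallelic signal in a polyclonal sample. Methylation support
comes from a paired (per-CpG-probe) Wilcoxon signed-rank contrast of
MA-expressing clones against their biallelic sisters at TSS200 / first-exon
/ CpG-island / gene-body probes, with exact p-values under ties.

A seeded synthetic-data generator (`simulatePanel()`,
`simulatePolyclonal()`, `simulateMethylation()`) produces clone panels,
polyclonal mixtures and methylation matrices with known ground truth for
calibration; it is first-class, tested code, not a fixture.

## Worked example

Deterministic worked-example panels (five iPSC-derived neural stem cell
clones, 7334 expressed genes, plus a polyclonal sample) ship with the
package:

```r
library(raex)
ex  <- exampleStudyPanels()
aei <- detectRandomAEI(ex$nsc, "iPSC_NSC")
summarizeFrequencies(ex$nsc, "iPSC_NSC", aei)
#>      group n_expressed n_ma_any_clone n_random_aei pct_ma pct_random_aei estimator
#> 1 iPSC_NSC        7334            126           48   1.71           0.65    clonal
```

Of 7334 expressed genes, 126 (1.71%) are monoallelic in at least one clone
and 48 (0.65%) qualify as random AEI. The polyclonal estimator agrees from
the other direction — 42 of the 48 random-AEI genes (88%) collapse to a
biallelic signal in the polyclonal sample, and counting every clone-MA gene
that is polyclonal-biallelic gives the higher estimate of 0.84% of
expressed genes:

```r
polyclonalEstimate(ex$nsc, "iPSC_NSC", ex$polyclonal, aei)[,
  c("n_poly_ba", "pct_random_aei", "n_random_aei_poly_ba", "pct_random_aei_poly_ba")]
#>   n_poly_ba pct_random_aei n_random_aei_poly_ba pct_random_aei_poly_ba
#> 1        62           0.84                   42                     88
```

An end-to-end simulated run (raw intensities → normalization → genotypes →
Δβ → classes → AEI → methylation):

```r
bundle <- runPipeline(list(seed = 1,
                           simulate = list(nGenes = 300, pMaCommit = 0.6),
                           polyclonal = TRUE, methylation = TRUE))
bundle$methylation$region_tests
#>    region n_pairs statistic      p_value direction mean_difference
#> 1  TSS200      54      1428 3.679355e-09 MA_higher      0.13836373
#> 2 1stExon      36       627 2.205488e-07 MA_higher      0.13062503
#> 3    Body      72       285 7.850987e-09 BA_higher     -0.06510202
#> 4  Island     108      5324 2.951941e-13 MA_higher      0.11117327
```

Promoter-proximal and island probes are hypermethylated in the clones
expressing a gene monoallelically, the gene body the other way around —
exactly the structure the generator embeds. `writeReportBundle(bundle, dir)`
serializes everything reproducibly (byte-identical given the same config
and seed).

See the methods vignette (`vignettes/random-allelic-imbalance.Rmd`) for the
model, parameter defaults, rounding conventions and known limitations.

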