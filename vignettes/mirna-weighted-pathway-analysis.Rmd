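---
title: "miRNA-informed weighted pathway analysis of case/control GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA-informed weighted pathway analysis of case/control GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirgsa)
```

## The problem

Single-marker genome-wide association scans of psychiatric phenotypes such
as bipolar disorder leave most heritability unexplained: individual SNPs
rarely reach genome-wide significance, yet association signal is often
spread across functionally related genes. Pathway (gene-set) analysis
aggregates that signal. This package implements a pathway analysis that
additionally injects *prior regulatory knowledge*: genes predicted to be
targets of disease-class-associated microRNAs (miRNA target genes, miTGs)
are up-weighted wherever they carry an excess of association signal within
a pathway.

The pipeline has five stages:

1. **Association scan.** Each biallelic SNP is tested with the
   Cochran–Armitage trend test (scores 0, 1, 2 on minor-allele dosage),
   the standard closed-form realisation of an additive single-marker
   model. Missing genotypes are dropped per SNP; monomorphic or otherwise
   degenerate SNPs are *flagged* (statistic 0, p-value 1) rather than
   silently removed, and flagged SNPs never enter the significant-SNP
   denominators.
2. **Gene-level reduction.** SNPs are assigned to every gene whose
   interval, extended by a 5 kb flank on both sides, contains them
   (1-based, boundaries inclusive). A gene's statistic is
   $P_{\min}$, the smallest SNP p-value in its region, and the gene-wise
   statistic $t_j$ is the $\chi^2$ of the SNP achieving it.
3. **miTG selection.** miRNAs annotated to the psychiatric or
   neurological disease classes are selected; their target-site
   predictions are filtered by the miRanda/mirSVR criteria
   (alignment score $\ge 140$, seed-site length $\ge 6$, free energy
   $\le -17$ kcal/mol, conservation $\ge 0.57$, all boundary-inclusive).
   A gene is a miTG if any of its sites survives. A second,
   DIANA-microT-style score (miTG score $> 19$, strict) is used
   downstream to tighten reported predictions.
4. **Weighting.** For each pathway, covered genes are partitioned into
   $n$ miTGs and $m$ non-miTGs, with $K_n$ and $K_m$ *informative* genes
   in each class. A gene is informative when its fraction of SNPs with
   $p < 0.05$ strictly exceeds the genome-wide fraction. If
   $K_n/n > K_m/m$ (and $K_m > 0$), the harmonic average
   $$H = \frac{1}{\frac{1}{m K_n} + \frac{1}{n K_m}}$$
   normalises the class weights $w_\text{miTG} = m K_n / H$ and
   $w_\text{non} = n K_m / H$; algebraically
   $w_\text{miTG} = 1 + (K_n/n)/(K_m/m)$, so the up-weighting grows with
   the excess of informative signal among the miTGs. If $K_m = 0 < K_n$,
   non-miTGs get weight 1 and miTGs an integer weight 1–6 binned on
   $K_n/n$ at cutoffs 0.1, 0.3, 0.5, 0.7, 0.9. Otherwise both classes
   get weight 1.
5. **Pathway tests.** Two complementary tests are run with and without
   weighting: a *competitive* GSEA enrichment score (weighted
   Kolmogorov–Smirnov running sum over the genome-wide ranking by
   $t'_j$, exponent 1, hits add $|t'_j| / N_R$, misses subtract
   $1/(N - N_H)$; ES is the maximum of the running sum, or 0 if never
   positive) and a *self-contained* SUM statistic
   $\sum_{i \in S} t'_i$. Significance is assessed by permutation
   (empirical $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$, the
   add-one convention, so $p \ge 1/(B+1)$ and BH remains valid) and
   Benjamini–Hochberg FDR is applied within each of the four scenarios.
   Pathways with fewer than 10 or more than 380 annotated genes are
   excluded beforehand; boundaries are kept.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `flank` | 5000 bp | SNP-to-gene window on both sides of a gene |
| `alpha` | 0.05 | per-SNP threshold behind the informative-gene flag |
| `size_min`, `size_max` | 10, 380 | annotated pathway size filter (inclusive) |
| `permutations` | 5000 | permutation count `B`; the study convention |
| `mode` | `"gene_label"` | permutation unit (see below) |
| `gsea_exponent` | 1 | running-sum weighting exponent |
| `fdr_threshold` | 0.01 | reporting cutoff on q-values |
| miRanda thresholds | 140 / 6 / −17 / 0.57 | filtering cascade, boundary-inclusive |
| miTG score | > 19 (strict) | DIANA-style post-filter |

## Design choices where the design was open

**Which single-marker test.** "Additive model" is realised as the
Cochran–Armitage trend test rather than logistic regression: it is
deterministic, closed-form, fast enough to recompute inside
phenotype-mode permutations, and yields the 1-df $\chi^2$ that the
gene-wise statistic $t_j$ requires. Logistic regression is a natural
extension point but not needed for any quantity the package reports.

**How weights enter the statistics.** The weighting scheme assigns class
weights but not a mechanism. Here weights multiply the gene-wise
statistic, $t'_j = w_{c(j)} t_j$ for pathway members (weight 1 outside).
Multiplicative scaling is the simplest contract that reduces exactly to
the unweighted statistics at $w = 1$ — a reduction the test suite
asserts end-to-end — and affects the GSEA ranking mass and the SUM in
the same direction. After weighting, the GSEA ranking is recomputed on
$t'$ (descending, ties broken by gene symbol for determinism).

**Permutation unit.** Both a fast `gene_label` mode (permute the
assignment of statistics to gene symbols; informative flags and weights
held fixed, preserving exchangeability of what the permutation moves)
and a full `phenotype` mode (permute case/control labels and replay
scan, gene statistics, genome-wide baseline, informative flags and
weights per permutation) are implemented and labelled in the output.
Neither is privileged; `gene_label` is the default for desk-scale runs
because a phenotype permutation costs a full genome scan each.

**Boundary conventions.** Coordinates are 1-based inclusive and the
5 kb flank is inclusive at its boundary; the flank is symmetric (strand
ignored), since a strand-aware rule is not needed to reproduce a
"within 5 kb" window and none is specified. All printed-threshold
comparisons follow the printed inequality directions: the miRanda
filters keep their boundary values, the miTG score filter and all
significance comparisons ($p < 0.05$, $P_{\min} < 0.01$,
informative $>$ baseline, FDR $< 0.01$) are strict. Argmin ties inside
a gene break by smallest p, then lowest position, then SNP id. The
$K_m = 0$ weight bins are right-open except the last
($[0.9, 1] \to 6$). Percentages and correlations round half-up to the
printed precision (1 and 2 decimals).

**miTG universe.** The miTG set is formed from the filtered predictions
and then intersected with the GWAS-covered genes pathway by pathway, so
a pathway's $n + m$ equals its covered size, which is at most its
annotated size — the convention that reproduces the reference tables'
count structure. The pathway *size filter*, by contrast, uses the
annotated size.

## What the synthetic generator emulates — and what it does not

`sim_study()` generates every pipeline input from one root seed (via
named substreams, so each component is independently reproducible):
case/control dosages under per-SNP Hardy–Weinberg binomial sampling;
gene intervals with SNPs guaranteed in all three strata (gene body,
5 kb flank, outside); pathway collections whose sizes straddle the
10–380 filter; miRanda- and DIANA-style prediction tables in which every
pair is planted to pass or to fail the cascade; and a miRNA
disease-class table. Planted signal applies a per-allele odds ratio to
SNPs in causal genes through the retrospective tilt
$p' = \mathrm{OR}\,p/(1 - p + \mathrm{OR}\,p)$ of the case allele
frequency — the standard simulation of a multiplicative per-allele
effect with fixed case/control counts.

Deliberately *not* emulated: linkage disequilibrium (the analysis
operates on per-SNP statistics and a per-gene minimum; LD would change
the effective multiplicity within genes but not the correctness of any
operation), population stratification, genotyping error and QC,
imputation, and sex chromosomes. Passing calibration and recovery tests
on this generator therefore show that the machinery is correct and
calibrated under idealised sampling, not that real GWAS data would meet
the same error rates: in real data, LD makes $P_{\min}$ statistics
dependent within and across genes, which the gene-label permutation
only partially respects.

## Simulation sizes used by the tests

The test suite and acceptance script run at desk scale, chosen once:
null calibration uses three replicate studies of 1,001 cases / 1,034
controls, 2,000 SNPs, 200 genes and 100 pathways with $B = 199$
(checking the fraction of pathways with empirical $p < 0.05$ per
scenario against the exact binomial 99% interval); parameter recovery
uses 500/500 samples, 2,600 SNPs, 300 genes and 15 pathways (5 causal,
30% causal genes, OR 1.6) with $B = 499$. Fifteen pathways follow from
the BH floor: with $B = 499$ the smallest attainable empirical p is
$1/500$, so five causal pathways can only reach $q < 0.01$ when the
collection has fewer than 25 members, and 15 leaves headroom. The
recovery experiment samples pathways *disjointly*
(`disjoint_pathways = TRUE`) so that planted signal stays confined to
the causal sets; with overlapping sampling from a small gene pool,
causal genes genuinely recur in other pathways and those pathways are
then correctly, but unhelpfully, enriched.

## Known limitations

* $P_{\min}$ discards all but one SNP per gene; long genes with many
  SNPs have stochastically smaller minima, which the permutation null
  only absorbs in phenotype mode.
* The GSEA score is the positive-deviation maximum without
  normalisation; no normalised enrichment score or ES-pooling FDR is
  computed (BH on empirical p-values is used instead, as in the study
  design this follows).
* Weight recomputation inside permutations happens only in phenotype
  mode; in gene-label mode weights are fixed at their observed values.
* The miRanda/mirSVR and DIANA scores are inputs, not recomputed;
  the package filters predictions, it does not predict targets.
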