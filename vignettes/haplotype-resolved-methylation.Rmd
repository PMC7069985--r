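---
title: "Haplotype-resolved methylation from long-read bisulfite amplicons: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved methylation from long-read bisulfite amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
models, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations.

## The measurement model

Bisulfite treatment deaminates unmethylated cytosine to uracil, read as T
after PCR; 5-methylcytosine is protected.  A long amplicon read in plus
orientation therefore shows, relative to the reference,

* C→T at unmethylated cytosines of the **original top (OT)** template
  strand, or
* G→A at unmethylated cytosines of the **original bottom (OB)** template
  strand,

and nothing else systematic.  For a cytosine site $s$ on haplotype $h$ of
subject $i$ the methylation level is the binomial point estimate

$$ M_{ihs} = \frac{\#\,\text{unconverted reads}}{\#\,\text{reads covering } s}, $$

computed only from reads whose bisulfite strand can observe $s$ (OT reads
see plus-strand cytosines, OB reads minus-strand cytosines).  CpH (non-CpG)
methylation is treated as strand-specific throughout: the two cytosines of
a CpG dyad, and any CpH, are separate sites and are never pooled by
default.  An optional depth-weighted merged-CpG summary exists but is not
used by the pipeline driver, because amplicon-level cytosine accounting in
this field is ambiguous about strand pooling and keeping strands separate
is the conservative choice.

## Alignment: conversion-aware global DP

Because the amplicon references are known, genome mapping is unnecessary:
each read is aligned globally (Needleman–Wunsch with affine gaps, Gotoh
recursion, implemented in C++) against its amplicon, twice — once with
OT-aware scoring (reference C matched by read C *or* T at the full match
score) and once OB-aware (reference G matched by G or A).  The
higher-scoring strand is the inferred bisulfite strand; on clean simulated
reads of realistic length this inference is error-free because hundreds of
converted positions discriminate the two hypotheses.

Scoring defaults, chosen once and stated so results are reproducible
bit-for-bit: match +2, mismatch −3, gap open −6, gap extend −1 (a gap of
length $k$ costs $-6 - k$), conversion-consistent pair +2.  Alignment
identity counts conversion-consistent pairs as matches and divides by
alignment columns; reads under 50 bp or under 90% identity are rejected.
A banded mode (half-width in bp, widened automatically by the read/reference
length difference) restricts the DP to a diagonal corridor; the pipeline
driver uses a 15 bp band, which is exact for amplicon reads whose true
alignments deviate from the diagonal by at most a few indels, and the test
suite verifies band/full-matrix agreement on simulated reads and full-DP
agreement with an independent dynamic-programming oracle.

## Reading genotypes through conversion

A variant whose two alleles differ only by C/T cannot be read on OT — an
observed T is either the T allele or a converted unmethylated C — and a
G/A variant is symmetric on OB.  Marker resolution therefore uses the
truth table "allele X is observed as X, or as T if X = C (OT) / as A if
X = G (OB)": if both alleles are compatible with the observed base the
marker is *ambiguous* and contributes nothing.  This also covers the
subtler masquerade (a C/G variant's C allele read as T on OT is still
unambiguously the C allele, because the G allele can never appear as T).
Indels are resolved from the alignment gap pattern near the marker; the
detection window extends several bases around the marker because an
inserted base whose content is altered by conversion (an inserted G read
as A on OB) can merge into an adjacent match run, and an affine-gap
aligner then floats the gap to the end of that run.

A read is assigned to a haplotype only if **exactly one** catalog
haplotype is compatible with every resolved marker and at least
`min_informative = 2` markers were resolved (single-marker assignment is
possible only by explicit configuration).  Two compatible haplotypes yield
`multi_compatible`, none `conflict`; either way the read is unassigned
rather than guessed — on simulated data this makes assignments correct or
absent, never wrong, which is the property the depth rules below rely on.

Genotypes are the two best-supported haplotypes; a subject is analysable
when each carried haplotype has ≥ 5 assigned reads.  The per-haplotype
rule is the default and a per-strand variant is available, because the
5x rule in this design can be read either way; we do not claim to know
which variant any particular study used.  A second haplotype supported by
fewer than 10% of a subject's assigned reads is treated as assignment
noise rather than a real allele, so rare mis-assignments cannot turn a
homozygote into a spurious heterozygote.  Homozygotes are genotyped and
kept in group-level summaries but excluded from within-subject ASM
contrasts, mirroring the heterozygote-focused design of ASM studies.

## Masking

A (haplotype, site) pair is *masked* — the record is absent, not zero —
when

* the cytosine does not exist on that haplotype (a C/T allele removed it,
  or it sits in a deleted segment), or
* a variant sits on the cytosine itself and is conversion-confounded on
  the site's only informative strand (an unmethylated C indistinguishable
  from a T allele).

Absence rather than NA-zero is deliberate: downstream tests cannot
silently include a masked cell.  Allele-averaged values are missing when
either allele's record is masked.

## The statistical battery

All tests are two-sided.  Per site in the analysis set
($0.01 < \bar M < 0.99$):

* **ASM**: ties-corrected Kruskal–Wallis across haplotype groups (H
  defined as 0 when all values tie); Mann–Whitney U (normal approximation
  with tie correction, no continuity correction) for risk haplotype vs
  pooled others.  With two groups the KW p equals the MW p, which the
  tests verify.
* **Covariate screens**: sex and smoking by Mann–Whitney (subjects with
  unknown smoking status drop from that screen only), age by Spearman
  rank correlation with the t-approximation.
* **Diagnosis**: logistic regression of case status on allele-averaged M
  plus age, sex and haplotype dosages (counts of each non-reference
  haplotype; the dosage coding is a choice — a categorical diplotype
  factor is equally defensible but spends more degrees of freedom at
  amplicon-scale sample sizes).  Wald p for the M term; separation or
  non-convergence flags the site untestable instead of emitting a p.
* **Coverage-matched pairs**: cases in seeded random order are greedily
  matched to the unused control with the identical genotype minimizing
  the absolute mean-coverage difference (ties to the smallest control
  id), then a Wilcoxon signed-rank test on the paired M.  Greedy matching
  (not optimal assignment) matches the informal "a control of the same
  haplotype and about the same coverage" design; the exhaustive optimal
  matcher exists only as a test oracle.
* **Cognition**: OLS of the cognitive T-score on a predictor + age + sex
  + diagnosis, with the haplotype predictor coded either as the full
  genotype factor or as risk-allele dosage 0/1/2, or with a site's
  allele-averaged M as the predictor.
* **FDR**: Benjamini–Hochberg within one fragment x one test family
  (the narrowest defensible reading of "per type of analysis"); the
  report states the family used.

The pooled-variance two-sample t from summary statistics is included for
report tables and for validating simulated cohorts against published
phenotype summaries.

## Factor and network structure

Methylation proportions are far from Gaussian, so structure analyses run
on nonparanormal normal scores $\Phi^{-1}(r/(n+1))$ with average ranks for
ties.  Factor retention uses parallel analysis (0.95 quantile of
eigenvalues from 1000 standard-normal datasets of identical shape — both
conventional defaults), extraction is maximum likelihood, rotation varimax
then promax with $\kappa = 4$.

The network estimator is the graphical lasso along a 100-point log-spaced
penalty path (from the largest absolute off-diagonal correlation down to
1% of it), selected by the extended BIC with $\gamma = 0.5$,

$$ \mathrm{EBIC} = -2\,\ell(\hat\Theta) + E \log n + 4 E \gamma \log p, $$

with edges reported as standardized partial correlations
$-\hat\Theta_{ij}/\sqrt{\hat\Theta_{ii}\hat\Theta_{jj}}$.  The blockwise
coordinate-descent solver is implemented in the package (no graphical-
lasso dependency is required).  After selection, edges below the
consistency bound $\sqrt{\log p / n}$ are suppressed by default — the
thresholded EBICglasso variant recommended in the network-psychometrics
literature to curb small spurious edges — because near the EBIC optimum
the penalized likelihood is almost flat and the raw support routinely
carries a handful of sub-noise edges.  Missing cells (masked sites) are
handled by pairwise-complete correlations with a 20-subject minimum
overlap; columns below the floor are dropped.

## MS-HRM difference curves

Melt curves are normalized by two-point linear mapping (pre-melt window
mean to 1, post-melt to 0; windows default to the first and last 2 °C of
the grid — instrument software algorithms are proprietary, so a stated
transparent convention is preferred).  The difference statistic for each
sample is its distance from the unmethylated standard at $t^\*$, the grid
temperature maximizing the separation between the unmethylated and fully
methylated standards (ties to the lowest temperature); genotype groups are
compared by the same Mann–Whitney routine as the ASM post-hocs.  Replicate
wells are averaged before testing; for curves on a shared grid averaging
and normalization commute, which the tests check.  The two-state simulator
behind the validation uses $F(T) = (1 + e^{(T - T_m)/s})^{-1}$ with
$T_m = T_{m0} + \Delta T_m \cdot (\text{methylated fraction})$ and equal-
weight mixtures for heterozygotes.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the study design
the pipeline targets:

* a deterministic 953 bp amplicon in a chr14-like frame with seven
  markers forming three haplotypes (`AGAGGCD`, `AGAGGCI`, risk
  `TAGAATI`), including a facilitated-methylation CpG cluster near the
  first marker, three CpGs destroyed by risk alleles (G→A at the CpG
  guanine), one CpG created from a CpH (A→G), one CpG gained through a
  single-base insertion, and one cytosine removed outright by a C/T
  allele (the maskable case);
* a packaged truth profile of per-haplotype methylation means at the 20
  sites with haplotype-specific methylation; unlisted CpGs default to
  0.90 and unlisted CpHs to 0.004 (non-CpG methylation in blood is
  essentially absent), both choices fixed a priori;
* cohorts with Hardy–Weinberg genotypes at haplotype frequencies
  (0.40, 0.30, 0.30) — carrier counts, not population frequencies, are
  what such studies print, so round frequencies reproducing comparable
  carrier numbers were fixed once;
* cognitive T-scores Normal(38.66, 6.53) for cases and Normal(49.63,
  5.04) for controls, ages 18–45 and sex balanced across groups;
* per molecule: haplotype uniform from the subject's two, strand OT/OB
  with probability 1/2, per-site Bernoulli methylation from the truth,
  conversion of unmethylated cytosines with efficiency 0.995, whole-
  molecule conversion failure at rate 0.01, i.i.d. substitution
  sequencing errors at 0.002/base, PCR duplicates at rate 0.1
  (byte-identical copies), dual 8-mer barcodes from an 8 x 12 catalog
  (at most 96 subjects per simulated run), constant Q40 qualities with
  an injectable low-quality fraction for exercising the Q30 filter;
* 40 reads per subject by default; read depth is a config knob, not a
  claim — published designs state only rough mean coverage.

What it deliberately does **not** emulate: CCS indel sequencing errors
(substitutions only, so the alignment module is exercised with injected
indels instead), off-target amplification, PCR thermodynamics, cell-type
mixtures, methylation at haplotype-specific cytosines that do not exist
in the reference (e.g. the minus-strand partner of an inserted base,
which the simulator leaves unmethylated), and between-subject variance in
the true methylation of a haplotype.  Passing tests therefore demonstrate
correct bookkeeping, calibrated statistics and parameter recovery under
this model — not robustness to raw-instrument artifacts.

## Numerical and scale choices

Test-suite and validation simulations are sized to run on one CPU in
minutes: the whole-pipeline parameter-recovery check pools two synthetic
96-subject sequencing runs (barcode plates), giving every haplotype well
over 40 analysable heterozygous carriers, and verifies the recovered
per-haplotype means at the three signature sites to ±0.03.  Null
calibration of each test family uses 2500 replicate sites so the Monte
Carlo error (~0.004) is small against the ±0.015 acceptance band around
the nominal 0.05.  Degenerate inputs are defined rather than left to
error: all-tied rank tests give p = 1, H = 0; molecules covering no CpH
pass the under-conversion filter with a warning flag; constant covariates
skip their screen with a reason.

## Limitations

Equivalence with any specific genome mapper or instrument software is not
claimed — only equivalence with the package's stated conventions, which
the oracle tests pin down.  The heterozygote restriction and 5x depth
rule reduce effective sample size at low coverage, and at amplicon scale
the per-site logistic models can be separation-prone; such sites are
reported untestable rather than given unstable p-values.  FDR families
are per fragment x test type; a global family is a configuration switch
away and is the more conservative choice when many fragments are
analysed together.
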