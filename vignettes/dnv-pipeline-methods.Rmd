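---
title: "Methods: trio DNV calling, gene-set significance and brain co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio DNV calling, gene-set significance and brain co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnvnet)
```

dnvnet implements the statistical core of a trio exome study of de novo
variants (DNVs) in schizophrenia: strict genotype- and site-level quality
control followed by Mendelian DNV extraction, aggregation of seven in-silico
pathogenicity predictors into a single damaging call, random-sampling
empirical significance for gene sets, exact hypergeometric enrichment, and
Spearman co-expression network connectedness across brain region ×
developmental-stage strata. This vignette records the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## Variant and genotype quality control

Input is a long genotype table (one row per sample × site) carrying the
VCF-level fields `GT:GQ:DP:AD` plus per-site quality, mapping quality and a
Phred-scaled strand-bias score (GATK `FS`-compatible, since the exclusion
threshold of 60 matches that scale). Two filter layers apply:

* **Genotype level** (`filter_genotypes()`): a call is set to missing when
  its Phred genotype quality is below 30, its depth is below 10×, a
  reference-homozygous call is supported by ≥ 5% alternative reads, a
  heterozygous call by ≤ 25%, or an alternative-homozygous call by ≤ 70%.
* **Site level** (`filter_variants()`): a site is excluded on site quality
  < 50, mapping quality < 20, strand bias > 60, call rate < 60% (fraction of
  samples non-missing after genotype filtering; no alternative definition is
  in use), or exact Hardy–Weinberg p < 10⁻⁵.

Every inequality is implemented exactly as written above, so boundary values
(GQ 30, DP 10, quality 50, MQ 20, FS 60, call rate 0.60, HWE p 10⁻⁵) pass;
this is the one free choice in the thresholds and it is fixed once here.
Both layers are idempotent, which the tests assert.

HWE is computed on founders (the parents) by default because probands are
not statistically independent of their parents; `hwe_samples = "all"` is
available. The test itself is the two-sided exact test on genotype counts:
conditional on the allele counts, all heterozygote configurations are
enumerated and the probabilities of configurations no more likely than the
observed one are summed. A DNV is a site where the proband is heterozygous
or alternative-homozygous and both parents are reference-homozygous; a trio
with any missing member call at a site contributes nothing there.

`mutation_rate()` divides the DNV count by 2 × callable bases × trios. The
callable-base denominator is an explicit argument because capture target,
CCDS subset and well-covered fraction differ by a factor of ~1.7 and the
choice dominates the estimate; the package takes no position on it.

## Damaging aggregation and cohort summaries

A non-synonymous variant is *damaging* when at least one of the seven
predictors assigns a damaging/deleterious/disease-causing class to at least
one transcript: SIFT D; PolyPhen-2 (HDIV or HVAR) D or P; LRT D;
MutationTaster D; MutationAssessor H or M; FATHMM D. The per-transcript
reduction is an existence claim ("any transcript damaging"), PolyPhen-2's
"possibly damaging" P counts as damaging while MutationAssessor L/N and LRT
U do not, and missing calls contribute nothing — in particular frameshift
indels, which these missense predictors cannot score, are never classified
by the rule and instead carry `functional_class = "frameshift"` so pipelines
can treat them separately. Applied to the packaged 47-variant table the rule
marks 39 of the first 40 variants: one variant (LRRC10B) sits among the
damaging-called rows of the source table without carrying any damaging
code. The package asserts the per-row outcomes and documents this
discrepancy rather than forcing the aggregate.

The allele-frequency filter keeps records whose maximal reference-panel
frequency is missing (never observed: the strongest rarity evidence) or
strictly below 1%.

`poisson_fit()` summarises per-trio DNV counts: mean rate λ̂, a normal
approximation 95% CI (λ̂ ± 1.96·√(λ̂/n)), and a binned likelihood-ratio
goodness-of-fit statistic over count categories 0/1/2/≥3 (configurable)
against Poisson(λ̂) expectations, referred to χ² with (categories − 2)
degrees of freedom. With ~30 trios the tail bin expects ~2.5 counts and the
χ² reference is known to be mildly anti-conservative: in our calibration
simulations the α = 0.05 rejection rate under a true Poisson null is about
0.067 rather than 0.050. We keep the likelihood-ratio form because it is the
method's stated test; users wanting exact calibration at small n should
bootstrap.

## Empirical significance for gene sets

The engine (`empirical_set_test()`) computes a statistic (mean, sum or
count) over the m case genes, draws t same-size sets from a null universe —
each draw without replacement within itself, draws independent of one
another — and reports the add-one estimator p = (s + 1)/(t + 1), where s
draws are at least as extreme as observed. The exceedance direction is an
explicit parameter because the same engine serves haploinsufficiency and
recessive probability (case mean larger than random) and RVIS (case mean
smaller, since negative scores mean intolerant). The default t = 100,000
matches the scale at which such resampling distributions are usually drawn;
p can never fall below 1/(t + 1). For the score suite the null universe is
all scored genes (whole-genome sampling, cases included), the closest
literal reading of sampling "a random set of genes with the same size on the
whole genome"; genes missing a score are dropped pairwise with a logged
count.

List overlaps use the exact hypergeometric upper tail P(X ≥ k) via
`stats::phyper`, numerically exact at universe sizes ~2 × 10⁴ (the tests
compare against direct pmf summation at 10⁻¹² tolerance). GO-term
enrichment applies Bonferroni over the tested terms only — no DAG
propagation, and no FDR procedures, which matches the analysis being
reproduced.

## Co-expression networks and the connectedness test

Expression samples are stratified by brain subregion and developmental age.
Ages are canonicalised to days post conception (birth at 40 gestational
weeks; months/years post-natal) and the three canonical windows are
prenatal 8–37 post-conception weeks, infancy-to-childhood 4 months–11
years, and adolescence-to-adulthood 13–23 years, bounds inclusive. A
12-year-old sample falls in no canonical stage; custom windows are
supported.

Within a stratum, the network over a gene list keeps every unordered pair
with |Spearman r| ≥ 0.8 as a signed edge. The absolute value is used, and
the boundary is inclusive — negative co-expression is displayed and counted
alongside positive, and at float precision the boundary choice is
immaterial but must be fixed. Ties receive average ranks. Genes with
constant expression in a stratum (Spearman undefined) are excluded from
both the case and the null networks, keeping the two comparable; genes
absent from the matrix are dropped with a logged count. Because the
statistic is rank-based, networks are invariant to sample reordering and to
any strictly monotone per-gene transform, which the tests assert.

`connectedness_test()` counts the case network's edges and compares against
t same-size subsets of a control gene list (by default the 240-gene
control-DNV list, not the whole genome, matching the comparison the
analysis makes; the rank-correlation matrix over case ∪ control genes is
computed once so each draw only indexes it). The empirical p is the same
add-one estimator. `connectedness_suite()` runs several strata and applies
Bonferroni with family size defaulting to the number of strata tested; the
corrected values in the reproduced analysis correspond to a family of 12 (4
regions × 3 stages), so `n_tests = 12` reproduces e.g. 4.0 × 10⁻³ → 0.048.
Region-level tests pool the samples of the region's subregions (the
alternative — averaging subregion networks — is not offered).

Merging networks unions nodes and edges, keeps the strongest |r| per edge
and records source strata; hubs are nodes with degree ≥ 9 by default.

## The synthetic-data generator

The generator exists so every stage is testable offline with known truth.
Defaults are fixed at the study conditions of the reproduced cohort: 45
trios (32 sporadic), per-proband DNV rate 57/45, damaging fraction 40/47
among non-synonymous DNVs, a 19,043-gene universe, a 240-gene control list,
reference lists of 1000/1744/733 genes with planted case overlaps of 8/8/4,
108 GWAS loci with one planted case-gene hit, and four frontal/temporal
subregions (VFC, MFC, OFC, ITC) × three stages at 30 samples per stratum,
with a 20-gene case module planted in the prenatal strata at factor loading
0.9 and noise scale 0.3 (pairwise Pearson correlation
0.9²/(0.9² + 0.3²) = 0.9, putting sample Spearman correlations at 30
samples almost surely above the 0.8 cutoff). The callable-base default is
3 × 10⁷ per haploid exome, a well-covered-CCDS-scale figure consistent with
the cohort's rate estimate given its DNV counts.

Planted DNVs pass every QC threshold by construction; contaminants
(optional, on by default) add Mendelian-consistent inherited variants plus
exactly one deliberate violation of each genotype-level and each site-level
QC rule, each crafted to trigger only its own rule — e.g. the
Hardy–Weinberg violation is a founders-split site with no heterozygous
parents, which is also Mendelian-consistent so it tests the site filter and
not the caller. The truth ledger records every planted DNV and violation by
site, and the acceptance tests require the caller to recover exactly the
planted set (precision = recall = 1) and each rule to remove exactly its
violations.

Expression values are generated on a continuous Gaussian scale and make no
attempt to mimic RNA-seq count distributions: every downstream statistic is
rank-based and only sees the ordering. A single master seed fans out to
per-generator sub-streams keyed by label, so adding one generator never
perturbs another's draws. What the generator does **not** emulate — read-level
error, batch structure, correlated background co-expression, realistic
linkage between sites, transcript-level annotation ambiguity — bounds what
passing tests show: they validate the statistical machinery under the
assumed model, not robustness to the full messiness of real sequencing or
BrainSpan data, which users supply through the documented loaders.

## Numerical and testing choices

* **Calibration of the connectedness test** is checked with case and
  control genes drawn from identical independent noise (40 vs 240 genes, 30
  samples, t = 2000). This experiment runs at an edge cutoff of 0.3 rather
  than the pipeline's 0.8: under independence at n = 30 the probability of
  |Spearman r| ≥ 0.8 is ~10⁻⁷, so at 0.8 every network has zero edges and
  every p-value is exactly 1 — a degenerate statistic cannot measure
  calibration. At 0.3 the null edge count averages ~80 with real spread,
  and the add-one p-value distribution is required to pass a
  Kolmogorov–Smirnov uniformity test with an α = 0.05 type-I rate between
  0.03 and 0.07. Power, by contrast, is checked at the pipeline cutoff 0.8
  with the planted module (loading 0.9), requiring p < 0.01 in ≥ 95% of
  replicates.
* **Problem sizes in the test suite** (replicate counts of 200–400,
  t of 10³–10⁵, small enumeration universes) were chosen so the full suite
  and the acceptance script each complete in minutes on one CPU while
  keeping Monte-Carlo error well inside the asserted tolerances.
* **Degenerate inputs** are defined rather than left to chance: zero depth
  fails the depth filter; an all-zero count vector fits λ = 0 with GOF p = 1
  and a warning; a constant expression vector yields NA correlation and
  exclusion; a zero-variance DNV burden or an undefined NS:S ratio is an
  explicit error; monomorphic sites have HWE p = 1.
* **Determinism**: all user-facing randomness takes a `seed`; fixed seeds
  give bit-identical results, and suites derive independent per-component
  sub-seeds from one master seed.

## Known limitations

Reproducing the real study's network node/edge counts and headline
co-expression p-values requires the actual BrainSpan matrices and the
external 240-gene control list, which the loaders accept but the package
does not ship. The binned LRT GOF is anti-conservative at small n (above).
Multi-allelic sites should be decomposed to biallelic records upstream; the
QC thresholds are per-allele. The evidence ranking's flag definitions
(empirical RVIS p < 0.05; hub degree ≥ 9 in the merged prenatal network)
are defaults mirroring the described evidence lines, and are configurable
rather than asserted against any external ranking.
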