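---
title: "Q+K candidate-gene association mapping of frost tolerance in winter rye"
author: "ryeassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Q+K candidate-gene association mapping of frost tolerance in winter rye}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryeassoc)
```

# The scientific setting

Frost tolerance (FT) in winter rye is a polygenic trait measured here on
three phenotyping platforms with very different error structures: a
*controlled* platform (climate-chamber freeze tests scored 0-5 for
recovery), a *semi-controlled* platform (% plants with undamaged leaves,
scored repeatedly over winter months in outdoor boxes), and a *field*
platform (% winter survival in multi-location trials).  The genetic
material is a *gamete-capture* panel: plants from five cross-pollinated
breeding populations (44, 68, 33, 41 and 15 plants; 201 genotypes in
total) were each crossed to one homozygous common parent, so every
testcross individual carries exactly one gamete of its source population.
Subtracting the common parent's alleles from the diploid testcross call
recovers that gamete — and hence fully phased candidate-gene haplotypes —
without statistical phasing.

Candidate genes come from the frost-responsive regulatory network (the
Cbf transcription-factor family, the upstream inducer Ice2, dehydrins,
Dreb2, Vrn1): 12 genes carrying 161 SNPs and 9 Indels, 170 polymorphic
sites in all, with Indels treated as ordinary single sites.  Population
structure (a membership matrix Q, rows summing to one) and kinship (an
allele-similarity matrix K from 37 SSR markers) absorb the stratification
and relatedness that would otherwise produce spurious associations.

# The model

All association tests are one-stage Gaussian linear mixed models fitted
to raw replicate-level phenotypes:

$$ y = \beta_0 + X_{SNP}\,\beta_{SNP} + Q\,\beta_{STRUCT} +
   X_{PLAT}\,\beta_{PLAT} + Z_{PLAT}\,\gamma_{PLAT} +
   Z_{GENO}\,\gamma_{GENO} + \varepsilon, $$

with $\gamma_{GENO} \sim N(0, K\sigma^2_g)$,
$\gamma_{PLAT} \sim N(0, D\sigma^2)$ and
$\varepsilon \sim N(0, I\sigma^2)$.  The kinship-structured genotype
effect is implemented by multiplying the genotype incidence design with a
covariance root $L$ of $K$ ($LL' = K$), which turns the block into an
ordinary iid block on the transformed design — the package's engine
verifies this embedding against a dense-covariance oracle
(`directLogLik()`) to $10^{-10}$.

Per platform the fixed and random recipes are:

* controlled: year + temperature fixed; chamber random (7 chambers, 3 in
  the first year, 4 in the second); 5 replicates per temperature-year.
* semi-controlled: year + a linear month trend + year$\times$trend fixed;
  replication random plus a correlated random intercept and month trend
  per test unit (unstructured 2$\times$2 covariance); 3 replicates per
  year; months Jan/Feb/Apr and Feb/Mar.
* field: a full set of environment indicators (no separate intercept);
  block-within-environment random; 6 environments with 2 or 3 replicates.

Inference: allelic and haplotype effects are Wald $t = \hat\beta/SE$ with
two-sided P from the standard normal reference (the original analyses
report $t$ values without denominator degrees of freedom; a Student-t
reference with $n-p$ df is available via `pReference = "tresid"`).
Haplotype overall tests and gene$\times$gene epistasis use ML
likelihood-ratio tests (REML likelihoods are not comparable across
fixed-effect sets and the package refuses to compare them); variance
components and variance explained come from REML.  Variance-component
LRTs use the plain $\chi^2_1$ reference, which is deliberately
conservative because the asymptotic null on the boundary is a chi-square
mixture.  The variance explained by a marker is
$100\,(\hat\sigma^2_{g,\text{without}} -
\hat\sigma^2_{g,\text{with}})/\hat\sigma^2_{g,\text{without}}$, truncated
at zero since a variance component can also rise under adjustment.

# Kinship from SSR similarity

For one locus the similarity index between two diploid genotypes is 1
for identical unordered allele pairs and 0 for disjoint pairs; for
partially matching pairs the package scores the allele-sharing fraction
under the best pairing (0.5 for one shared allele).  The published
definition is binary and silent about partial matches; the sharing
fraction is the standard allele-similarity choice and a strict
\{0, 1\} mode is available (`hetMode = "strict"`).  The per-locus index
is averaged over jointly observed loci and standardized with the minimum
off-diagonal raw value $S_{min}$:
$\hat S_{xy} = (S_{xy} - S_{min})/(1 - S_{min})$.  The printed form of
this formula mixes a raw and a standardized minimum in one expression;
only the all-raw reading maps $[S_{min}, 1]$ onto $[0, 1]$, so that is
what the package computes.  The least related pair is therefore exactly 0
and the diagonal is pinned at 1 — a reported kinship *minimum* above zero
is incompatible with this standardization and is not reproduced.
Eigenvalue clipping (`ensurePSD()`) guarantees a positive semi-definite
matrix; at $n \approx 200$ this simple repair is adequate and
deterministic.

# The mixed-model engine

Estimation maximizes the profiled (restricted) likelihood over variance
*ratios* $\lambda_b = \sigma^2_b/\sigma^2$ on the log scale, with the
intercept-trend correlation mapped through $\tanh$; fixed effects and
$\sigma^2$ are profiled out by generalized least squares.  All
per-iteration work happens on $q \times q$ cross-products ($q$ = total
random-effect columns, about 1000 for the semi-controlled platform),
never on $n \times n$ covariances; the congruence transform of the
cross-product matrix with the relative-covariance factor is implemented
in C++.  The optimizer is the PORT quasi-Newton code (`nlminb`) with an
analytic gradient of the profiled deviance, three deterministic spread
starting points for cold fits (variance ratios 0.5, 0.02, 8), and a
single warm start for the many refits inside a scan (started from the
null model's optimum, whose variance ratios barely move when one marker
column is added).  Variance ratios are floored at $10^{-10}$ internally
and reported as 0 with a boundary flag when they end on the floor.
Numerical behaviour is pinned by three independent cross-checks in the
test suite: a dense-covariance likelihood oracle evaluated at random
parameter points, closed-form solutions (sample variance; balanced
one-way ANOVA REML), and agreement with lme4 on a shared model.

# What the synthetic cohort emulates

No accessions are distributed with the motivating study, so the package
ships a generator that reproduces the *statistical* structure the
analysis assumes, with stored ground truth for every estimand:

* five source populations of sizes 44/68/33/41/15; per-genotype admixture
  drawn from a population-specific Dirichlet (own-component concentration
  12, others 0.5), giving distinct but partially admixed clusters, and
  the true Q is retained;
* within-gene linkage disequilibrium from finite ancestral haplotype
  pools (4-8 per gene; pool 1 is always the common parent's string), with
  population-specific pool frequencies (Dirichlet, concentration 3).  The
  non-reference allele at each site is carried by one to two thirds of
  the non-parent pools, which keeps realized minor-allele frequencies
  well above the 5% filter — in the default cohort all 170 sites enter
  the scan;
* one "private" large-effect site (ScIce2 site 7) whose carrier pools are
  reweighted so the favourable allele segregates at about 55% in PR2733
  and about 6% elsewhere, echoing the study's most prominent finding;
* S0 testcross calls constructed as sampled gamete + parent allele, so
  phasing-by-subtraction can be verified exactly against the stored
  gamete matrix;
* SSR genotypes drawn from ancestry-specific allele frequencies, again
  with one parent allele per locus;
* phenotypes generated from exactly the platform models above, with a
  single standardized polygenic vector $N(0, K)$ shared across platforms
  (scaled by each platform's $\sigma_g$), so cross-platform concordance
  has a genetic component as in real data.  By default the generator uses
  the SSR-estimated K for the polygenic draw (self-consistent with the
  analysis); an identity or user-supplied relatedness is available for
  robustness checks.

Default effect magnitudes are chosen to sit inside the allelic-effect
ranges the study reports (recovery-score effects of a few tenths,
percentage effects of a few points, one large positive field effect of 4.3) and default
variance components give mid-range power; the study publishes no
within-platform heritabilities to calibrate against, so these defaults
are documented choices, not estimates.  Platform means are set so that
clipping to the outcome scales ([0, 5] and [0, 100]) touches under 1% of
draws (the generator reports the clipped fraction); this makes the
Gaussian model and the bounded outcome compatible by construction, at the
price of not reproducing the most extreme environment medians.  What the
generator deliberately does not emulate: selfing-generation differences
between years (treated as absorbed by year effects, as in the study),
coalescent-realistic LD decay, genotyping error or missingness (available
but off by default), and climate covariates.  Passing tests on this
cohort therefore demonstrate correctness of the estimators under the
assumed model, not robustness to real-data pathologies.

# Numerical and design choices

* Month-trend coding: calendar spacing (Jan/Feb/Apr as 1/2/4), centered
  within year; rank spacing is available (`trendCoding = "rank"`) since
  the original coding is unstated.
* The intercept-trend grouping unit is genotype-by-year (the repeated
  measures are months within that unit); replication effects are
  year-specific labels and independent of the intercept/trend pair.
* Q columns sum to one and collide with the intercept, so the last
  cluster column is dropped; in the field model the environments form a
  full indicator set with no separate intercept (an equivalent
  parameterization).
* Multi-allelic sites are coded most-frequent-non-reference vs reference;
  gametes carrying any other allele are missing for that site's test
  (the model estimates a single allelic effect).
* Heterozygous testcross calls containing no parent allele cannot arise
  from the design; they are flagged, counted and set missing rather than
  guessed.
* Missingness is handled per test as complete-case analysis; haplotypes
  below the frequency filter set their carriers missing for that gene,
  and the reported missingness fraction makes the information loss
  visible (genes may lose most genotypes, as rare-haplotype-rich genes do
  in the study).
* All haplotype contrasts are reported even when the overall LRT is not
  significant, with an `overall_significant` flag carrying the gate; the
  published tables contain such rows, so suppressing them would lose
  information.
* Ties in haplotype frequency are broken by string order, making labels
  deterministic.

# Problem sizes used by the test suite

The acceptance checks run the full statistical machinery at reduced
problem sizes chosen to finish comfortably on one CPU: calibration of the
single-site scan uses a three-population cohort of 150 genotypes, 40
sites and 40 phenotype replicates (1600 site-tests) on the field
platform; parameter recovery uses 120 genotypes and 40 replicates of the
controlled platform; LRT calibration uses 120-200 replicates of
two-haplotype genes; and the end-to-end reproducibility check runs the
complete pipeline twice on a 95-genotype, 28-site scenario.  The full
default scenario (201 genotypes, 170 sites, all three platforms, all
gene pairs) is exercised by `runPipeline()` / the `ryeassoc demo`
subcommand and completes in roughly 13 minutes on one CPU.

# Known limitations

* Wald P values default to the normal reference; with thousands of
  observations per platform the difference from a t reference is
  negligible, but for very small designs choose `pReference = "tresid"`.
* The $\chi^2$ reference for variance-component LRTs is conservative by
  construction; calibrated boundary-mixture references are out of scope.
* The engine supports at most one kinship block and 2-dimensional
  correlated random effects (intercept + trend), which is exactly what
  the three platforms need — it is not a general-purpose REML package.
* Fixed-effect ML likelihood-ratio tests use the chi-square reference
  without a denominator-degrees-of-freedom correction, as in the original
  lme4-based analysis.  For gene pairs with many retained haplotypes the
  interaction test can have tens of degrees of freedom against only ~200
  genotypes of effective replication, and is then anticonservative; the
  reported exact P values allow any downstream correction.
* Bounded outcomes are modelled as Gaussian with clipping-rare scenarios,
  mirroring the original analysis; strongly censored data (an
  environment with near-zero survival) would need a different
  observation model.
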