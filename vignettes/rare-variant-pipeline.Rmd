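---
title: "Two-stage rare-variant burden discovery: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage rare-variant burden discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exburden)
```

## The design this package implements

`exburden` implements the analysis of a two-stage rare-variant
case-control exome study of a severe pediatric phenotype: a discovery
stage of whole-exome sequenced cases and population controls (on the
scale of 927 cases versus 4,057 controls), and a targeted-resequencing
replication stage (1,810 versus 2,647). Genes are tested for an excess of
rare, functionally severe alleles in cases; candidates passing a
selection threshold are re-tested in stage 2 and the two stages are
combined at the score-statistic level. Around the gene tests sit the
operational layers that decide what enters them: genotype-, variant- and
sample-level QC, allele-frequency classing against reference panels, and
nested functional masks.

## Models and tests

### The intercept-only score test

All gene-level tests are score tests under a logistic model with no
covariates. The studies this design comes from were deliberately
unadjusted — cases were recruited prepubertally, and the cohorts carry no
shared covariates — so the null model is intercept-only: `ȳ` is the case
fraction and the per-sample burden `b_i = Σ_j w_j g_ij` is tested with

\[
U = \sum_i (y_i - \bar y)\,b_i,\qquad
V = \bar y (1-\bar y) \sum_i (b_i - \bar b)^2,\qquad
U^2/V \sim \chi^2_1 .
\]

Default weights are equal (`w_j = 1`). This choice is deliberate: with
equal weights and one qualifying heterozygote per carrier, the test
statistic depends only on the carrier counts and cohort sizes, and the
printed gene-level p-values of the published tables are reproduced
exactly (e.g. 6 case carriers / 0 controls at 927 / 4,057 gives
p = 2.94e-7). Beta(MAF; 1, 25) weights can be supplied but are not the
default. Missing dosages are mean-imputed within variant for all score
tests (the convention of the SKAT family), while the single-variant
likelihood-ratio test is complete-case (the convention of per-SNP
maximum-likelihood fitting).

### SKAT and SKAT-O

SKAT tests `Q = Σ_j S_j²` with `S_j = Σ_i (y_i - ȳ) w_j g_ij`; under the
null `S ~ N(0, Φ)` with `Φ = ȳ(1-ȳ) W Gc'Gc W`, so `Q` is a mixture
`Σ_k λ_k χ²₁` over the eigenvalues of `Φ`. SKAT-O scans
`Q_ρ = (1-ρ)Q_SKAT + ρQ_burden` over the grid
`{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}` and combines the per-ρ
p-values through the minimum-p construction: conditioning on the burden
component ξ = 1'S (with ξ² = σ²x, x ~ χ²₁, σ² = 1'Φ1), each `Q_ρ`
decomposes as `τ(ρ)x + (1-ρ)κ`, and the omnibus p-value is a
one-dimensional integral over x of the conditional probability that κ
stays below every per-ρ threshold.

Two numerical choices in that integral matter and are this package's own:

* **The conditional law of κ is evaluated exactly.** Given ξ, κ is a
  *noncentral* chi-square mixture in the eigenbasis of the residual
  covariance `Φ_η = Φ - Φ11'Φ/σ²`, and its tail is computed by a
  saddlepoint inversion of the cumulant generating function. The common
  shortcut — a central mixture rescaled to match the unconditional
  variance — is visibly conservative with few variants (empirical type-I
  error near 0.03 at nominal 0.05 in our null calibration); the exact
  conditional law restores calibration (0.0492 observed at 0.05, 6e-4 at
  0.001, over 10,000 null replicates).
* **The outer integral substitutes x = t².** The χ²₁ weight has an
  x^(-1/2) singularity at zero that defeats polynomial quadrature; after
  substitution the integrand is smooth and 128 Gauss–Legendre nodes on
  [0, √40] evaluate it to well below the accuracy of the tails
  themselves. Against a 40,000-draw Monte Carlo of the min-p statistic,
  the omnibus p agrees within ±0.005 absolute.

The per-ρ thresholds at the observed minimum p use the moment-matched
(Liu) quantile — closed-form, and accurate to ~1% where it is used. The
reported omnibus p is clamped to `[min_ρ p_ρ, |grid| · min_ρ p_ρ]`, its
theoretical envelope. Single-point grids reduce exactly: `{1}` returns
the burden p, `{0}` the SKAT p.

### Mixture tail probabilities

`pchisq_mixture()` defaults to a Lugannani–Rice saddlepoint inversion:
~0.2 ms per call, no convergence failures, and uniformly accurate into
the far tail (1–5% relative error against exact equal-weight mixtures
from p = 0.5 down to 1e-10). Direct characteristic-function integration
(Imhof's integral via adaptive quadrature) is available as the
high-accuracy cross-check at moderate p — it is exact to machine
precision where the integral converges, but costs ~100 ms per call and
degrades to absolute-tolerance noise below p ≈ 1e-8 — and Liu moment
matching is the fallback. P-values are floored at 1e-300.

### Meta-analysis

Cross-stage combination assumes homogeneous effects: `U` and `V` add for
the burden masks, and for SKAT-O the per-study score vectors and
covariances pool on the union of variant keys (a variant absent from one
study contributes zero score and zero covariance there; targeted stage-2
panels cover the same genes but not necessarily the same variants). On k
identical studies this is exactly the k-fold stacked-cohort test, which
the suite asserts. Single-variant results combine by inverse-variance
fixed effects on the log-OR.

### Odds-ratio conventions

The reported OR is the case:control minor-allele-frequency ratio
`(a/2n₁)/(b/2n₂)` — the convention that reproduces the published
stage-1 values to two decimals, where the allele-odds convention does
not. When a cell is zero the companion estimate adds 0.5 to every cell
of the allele 2×2 (Haldane); our convention gives 39.47 for a 4/0 cell
at these cohort sizes where the source table prints 39.41 — the ~0.2%
discrepancy is documented rather than forced, since the exact cell
definitions behind the printed adjustment are not recoverable.
Confidence intervals are Woolf (normal on the log odds ratio) on the
(adjusted, if used) table.

## QC cascades

Rules are grouped in profiles mirroring the two sequencing modalities.
Stage 1 (joint-called exomes): genotypes missing at GQ < 30, alternate
read depth < 2, or het allelic balance outside [0.2, 0.8]; variants
dropped at missingness ≥ 20%, HWE χ² p ≤ 1e-8, mean GQ < 30, or < 7x
coverage in < 80% of samples; samples dropped at contamination ≥ 3%, mean
depth < 12, missing rate > 15%, kinship ≥ 0.125 (the higher-missingness
member of each related pair is removed; ties go to the lexicographically
larger id — the source protocol does not say which member it dropped).
Stage 2 (targeted amplicons): genotypes missing at DP < 15, GQ < 20
(SNV) / 60 (indel), het AB outside [0.15, 0.85], moderate AB
([0.15, 0.35] or [0.65, 0.85]) without DP > 25, indel DP > 2000; variants
dropped at group call rate < 90% or case/control call-rate difference
> 2.5%.

The cascade order is genotype → variant → sample → variant: sample
removal changes call rates, so a second variant pass (switchable off)
keeps the call-rate rules true of the final dataset. The cascade is
idempotent, and each removal is attributed to the first rule it violates
in a fixed order, so planted-violation counts are exact. HWE is computed
on all retained samples by default (controls-only is a switch); upstream
site-level filters that require alignment internals (VQSR, strand/rank
hard filters) are consumed as precomputed pass/fail status, not
recomputed.

## Frequency classing and masks

A variant is **very rare** when its allele frequency is below 0.025% in
*every* reference panel (four continental panels plus a population
cohort; a missing panel entry means unobserved, i.e. 0) *and* below
0.025% in at least one analysis group of the cohort; **rare** applies the
same logic at 1%. The group-OR side means an allele absent from controls
always qualifies — the intended behavior for case-private alleles. Masks
then intersect frequency class with functional category; category flags
satisfy LOF ⇒ STRICT ⇒ BROAD by construction, and a missing predictor
verdict counts as not-damaging for both the all-five and at-least-one
rules (switchable; the conservative direction for inclusion). Genes need
two qualifying variants to be tested individually but contribute all
qualifying variants to gene-set aggregation.

## Discovery rules

Stage-1 candidates: genes at OR > 1 and p < 1e-4 (LOF/STRICT burden, or
BROAD SKAT-O), plus single variants at p < 1e-4 with case MAF > control
MAF. For BROAD hits, leave-one-out removal — iteratively deleting the
most significant single variant among those seen more than twice (total
minor-allele count > 2, cases and controls together; ties broken by
genomic coordinate) until the gene p rises above 0.1 — decides between
genotyping the one or two driver variants and resequencing the gene.
Gene results are additionally flagged at exome-wide significance
(p < 2.5e-6, Bonferroni for all genes). LD-based clumping of candidate
variants needs an external LD panel and is out of scope; candidates are
emitted unclumped.

## Gene-set enrichment

The per-gene statistic the original tooling used is not publicly
specified; this package's documented statistic is the ratio of ratios

\[
T = \frac{\text{mean case set-burden}/\text{mean control set-burden}}
         {\text{mean case exome-burden}/\text{mean control exome-burden}},
\]

which implements "controlling for exome-wide differences" by
self-normalization: for the all-genes set T ≡ 1 under every labelling.
Significance is by case/control label permutation with the unbiased
estimator `p = (b+1)/(B+1)` (20,000 permutations in the full design;
drivers use 2,000 at demo scale), Bonferroni-adjusted across the ten
primary sets; seeds are recorded in every result. A zero control
set-burden takes a 0.5 continuity term and a flag. Developmental-delay
stratification reruns the permutation with cases restricted to one
stratum against all controls.

## External-control ratio test

Where external controls exist only as summary counts, cases and controls
are compared on the ratio of very-rare functional (LOF or STRICT) to
very-rare synonymous allele counts, modeling the four totals as
independent Poisson and testing equality of rate ratios with a 1-df LRT —
algebraically the G-test on the 2×2 — with 0.5 continuity cells (and a
flag) when a margin is zero. Synonymous variation acts as the internal
calibration that absorbs capture and depth differences between cohorts.
The test is symmetric in the group labels and calibrates at α = 0.05 in
null simulation.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes: genes carry Poisson numbers of variants (≥ 2); variants draw a
frequency stratum (70% at singleton/doubleton scale, 20% rare at
0.1–0.8%, 10% common — a spectrum dominated by ultra-rare alleles, as in
exome cohorts of this size), a functional class (20% LOF, 55% missense
with a mixed damaging-verdict profile, 25% synonymous), reference-panel
frequencies consistent with the stratum, and per-genotype GQ/DP/AD noise
around a mean depth of 40. Case enrichment is by carrier-probability
tilting: for mask-qualifying (non-common functional) variants of a risk
gene, the case allele frequency is `q₀ · RR`. This retrospective
approximation is adequate exactly where the design operates — carrier
probabilities far below 1 — and is checked by parameter recovery: the
Woolf interval of the estimated OR covers the planted RR ∈ {1, 3, 10} at
the nominal rate. A quarter of cases carry a developmental-delay flag.
QC violations are planted one-per-genotype-cell on otherwise clean slots
and recorded in truth tables, so the QC suite can assert exact
per-rule counts.

What the generator does *not* emulate: linkage disequilibrium (variants
are independent, so LD-dependent steps like clumping cannot be
exercised), population stratification, sequencing-batch structure, and
read-level artifacts beyond the marginal GQ/DP/AB distributions. Passing
tests therefore demonstrate the statistical machinery and the rule
logic, not robustness to confounding that real cohorts may carry.

## Problem sizes

The test suite and drivers choose sizes that keep every run
deterministic and fast while preserving the regimes that matter: null
calibration uses 10,000 replicates of 250/250 cohorts with 3 variants at
MAF 0.5–3%; exhaustive permutation oracles run at 14–16 samples where
all label assignments are enumerable (and the asymptotic p is asserted to
lie between the strict and inclusive permutation tails, the honest
comparison against a coarse discrete law); the end-to-end drivers run a
1/5-scale replica of the two-stage design, rescaling the very-rare MAF
ceiling by the same factor so singleton alleles class as they would at
full size, and relaxing the selection threshold from 1e-4 to 1e-3 to
match the reduced power. Published-number checks run at the true cohort
sizes — they are seconds of work because the contingencies are tiny.

## Known limitations

* The saddlepoint tail is approximate (1–5% relative); analyses needing
  machine-precision tails at moderate p can switch `method =
  "integration"` per call.
* Gene-level ORs use cohort-size allele denominators even for
  multi-variant aggregates; with per-variant missingness the effective
  denominators shrink slightly, which is why replication-stage printed
  ORs are reproduced less exactly than discovery-stage ones.
* The min-p SKAT-O construction treats the per-ρ thresholds with a
  moment-matched quantile; the residual error is well inside the Monte
  Carlo validation band but is not exact.
* Heterogeneous-effect gene meta-analysis (study-specific effect sizes)
  is not implemented; pooling assumes homogeneity.
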