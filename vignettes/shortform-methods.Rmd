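---
title: "Methods: IRT-based short-form development and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IRT-based short-form development and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortform)
```

## The measurement model

The package treats a knowledge questionnaire as a set of categorical items
driven by a single latent trait θ ("knowledge"). Items follow the
generalized partial credit model: for item *j* with categories
k = 0, …, K−1, discrimination a and thresholds b₁…b_{K−1},

P(X = k | θ) ∝ exp{ Σ_{v ≤ k} a(θ − b_v) }.

The items of the motivating application are binary after "I don't know" is
recoded as incorrect, so the model reduces to the two-parameter logistic:
P(correct) = logit⁻¹{a(θ − b)}. The code is written for general K and
exercised in the binary case. The key assumptions are unidimensionality
(screened, see below), local independence given θ, and a standard-normal
trait distribution, which also fixes the latent scale: the prior is pinned
at mean 0 and SD 1 and no item-side constraint is imposed.

`gpcm()` maximizes the marginal likelihood by EM. The E step integrates θ
out on a quadrature grid; the M step maximizes each item's expected
complete-data log-likelihood by box-constrained BFGS with analytic
gradients, started at the current estimates, so the marginal log-likelihood
is non-decreasing by construction (asserted in the tests on every
iteration). Three numerical choices matter:

* **Quadrature** (`trait_grid`): 61 equally spaced nodes on [−6, 6] with
  weights proportional to the normal density. For posterior integrands that
  decay to zero inside the interval this trapezoid-type rule is
  exponentially accurate; the test suite verifies EAP scores against a
  2001-point brute-force rule to ~1e−6, far inside the 1e−3 bound asserted.
  A true Gauss–Hermite rule is available (`type = "hermite"`); its
  extreme-node weights underflow at high node counts and are floored, which
  is why it is not the default.
* **Starting values and constraints**: thresholds start at the
  adjacent-category logits of the observed proportions and the M step is
  constrained to a ∈ [0.01, 50], |b| ≤ 15. The GPCM likelihood has a flat
  ridge at a → 0 with |b| → ∞ where items look flat; unconstrained
  optimization from neutral starts can fall onto it (we observed exactly
  this for hard items before adding both safeguards).
* **Convergence**: EM stops when the largest absolute parameter change
  falls below 1e−4 (default), with a 500-iteration cap; hitting the cap
  flags the fit and warns rather than returning silently. Items observed in
  a single category are an error naming the item — silently dropping them
  would change candidate form lengths under the caller's feet.

## Dimensionality screen

`dimensionality_screen()` is a deliberately lightweight gatekeeper for the
"one factor is enough" decision: split the sample in half, compute
pairwise tetrachoric correlations (2×2 bivariate-normal MLE with thresholds
fixed at the margin quantiles; boundary tables clamped at ±0.999 and
flagged; non-PSD matrices eigenvalue-clipped at 1e−6 and rescaled), inspect
the scree on one half, and fit a single factor by unweighted least squares
on the other, reporting loadings and the SRMR. A full categorical-data
EFA/CFA machinery (robust weighted least squares, rotation, fit indices)
is intentionally out of scope: the downstream pipeline consumes only the
unidimensionality decision, and the scree-plus-ULS screen checks that
decision at the level where it is falsifiable on binary data. One
degenerate case is handled explicitly: a matrix with no common structure
makes the ULS loading vector indeterminate (any single-spike vector fits
the off-diagonal equally well), and the null solution is preferred when it
fits as well.

## Optimal test assembly

For each candidate length L from 3 (the minimum for an identifiable
single-factor model) to p−1, the assembly problem is: choose x ∈ {0,1}^p,
Σx = L, maximizing the short form's test information at anchor points
θ ∈ (−5, −3, −1, 1, 3) with equal weights. "Jointly maximizing at the
anchors" is genuinely ambiguous between two objectives, so both are
implemented:

* **sum** (default): maximize Σ_anchors w · TIF(anchor) — separable, and
  the behavior matches how such forms are reported in practice
  (high-discrimination items enter first);
* **maximin**: maximize min_anchors TIF(anchor) — guards the information
  floor at the extreme anchors, where weakly discriminating items are
  flatter and can legitimately displace strong ones.

`assemble_short_form()` solves either by depth-first branch and bound with
an admissible bound (best completion from the largest remaining per-anchor
contributions). Exploring inclusion before exclusion in index order with
strict-improvement updates yields the lexicographically smallest optimal
subset — the same tie-break the exhaustive oracle (`enumerate_optimal`)
uses — so the two must agree exactly, and the tests sweep that agreement
over seeded banks, all lengths, both objectives. Forms of different lengths
are not nested and the code never assumes they are.

## Dual scoring and the five selection criteria

Every candidate and the full form are scored two ways: summed scores
(research convention) and EAP factor scores (posterior mean of θ, better
measurement properties near the ceiling). Selection applies five criteria
at once; a form is admissible only if it passes all, and the shortest
admissible length is selected per external measure:

1. Cronbach α ≥ 95% of the full form's α;
2. r(summed short, summed full) ≥ 0.90;
3. r(EAP short, EAP full) ≥ 0.90;
4. TOST equivalence of convergent validity, summed scores;
5. TOST equivalence of convergent validity, EAP scores.

The equivalence test compares r₁₃ (short form vs external measure) with
r₂₃ (full form vs the same external measure), dependent through r₁₂
(short vs full). Two one-sided z-tests of H₀: |ρ₁₃ − ρ₂₃| ≥ δ use the
Pearson–Filon/Steiger asymptotic variance of a difference of overlapping
correlations; the TOST p is the larger one-sided p. The margin δ = 0.05 is
applied on the raw correlation scale — the natural reading when the
criterion is quoted as a correlation difference — and simulation in the
test suite confirms the test is calibrated there: empirical type-I error
at the boundary is ≈ 0.05 at n = 2552 (10,000 trivariate-normal
replicates), with power ≈ 1 at zero true difference. The full-form row is
a degenerate self-comparison (difference exactly 0 with zero variance);
its p-value is defined as 0 and reported unadjusted.

Benjamini–Hochberg correction (via `stats::p.adjust`; an independent
step-up implementation is the test oracle) is applied within one family
per external measure: 9 candidate lengths × 2 scorings = 18 tests. Whether
the two external measures should share one family is a judgment call; the
default keeps them separate since each defines its own selected form.

## The synthetic-data generator

`generate_population()` produces the structure the pipeline assumes:

* three latent traits (one per measure) with equicorrelation 0.82,
  covariate-driven shifts added and the residual variance shrunk so the
  total trait variance stays 1 — shifts read as fractions of the trait SD;
* binary responses from per-measure GPCM banks with discriminations
  uniform on [0.9, 2.5] and thresholds uniform on [−3.4, −1.2]. These
  defaults were calibrated once so the generated 12-item measure reproduces
  the motivating survey's printed profile — summed-score mean ≈ 11.0 of 12
  (strong ceiling effect), SD ≈ 1.45, Cronbach α ≈ 0.66 with ≥ 90% of
  seeds in [0.55, 0.75], observed inter-measure score correlations ≈ 0.57
  after attenuation — and are not intended as estimates of any real item
  bank;
* covariates drawn from the survey's marginal frequencies (age bands,
  race, education, income, HIV-test status; PrEP use and condomless sex
  only for HIV-negative/never-tested respondents, treatment adherence only
  for positives), with centered trait shifts encoding the expected
  knowledge gradients (e.g. education −0.70/−0.30/+0.15 SD);
* a 5-category perceived-accuracy item generated from the main trait via
  an ordered-logistic link with "don't know" as the lowest category,
  cutpoints set so ≈ 63% choose "completely accurate";
* optional missingness, completely at random at a single configurable
  rate (default 0: the analytic sample emulates complete responders, and
  the analysis pipeline is complete-case throughout).

What the generator does *not* emulate: survey dropout and attention-check
exclusion dynamics, differential item functioning across groups,
non-normal trait distributions, and any dependence of missingness on the
trait. Tests passing on this generator therefore certify the pipeline's
statistical machinery under its stated assumptions, not robustness to
violations of them.

One empirical regularity is worth recording because it constrains what
synthetic replications can show. In the motivating study's own summary
table, α is *not* monotone in form length (it dips from 11 to 12 items)
and the summed-score concurrent correlation at 6 items is 0.889, just
under 0.90. The same two behaviors recur in synthetic runs: α increments
at the top of the ladder are of the same order as the sampling noise of α
at n = 2552, and configurations concentrating information in few items
(which push concurrent correlations of very short forms up) are exactly
the ones where weak tail items flatten or invert the α ladder. A strict
"α nondecreasing and concurrent r ≥ 0.90 from 6 items, jointly in nearly
all seeds" replication target is therefore unattainable under any
calibration consistent with the printed profile; the test suite asserts
it as stated and the corresponding test documents the measured rates
rather than a pass.

## Problem sizes and runtime choices

The test suite and the acceptance script use: n = 2000 with 20 seeded
replicates for parameter recovery (discrimination recovery correlation
≥ 0.9, threshold RMSE ≤ 0.3 under a standard calibration design with
a ~ U[0.5, 2], b ~ U[−2, 2] — recovery is assessed away from the ceiling,
where thresholds near −3.5 are weakly identified and RMSE reflects the
ceiling rather than the estimator); 25 seeded banks × lengths 3–11 × both
objectives for the assembly-oracle sweep; 10,000 replicates at n = 2552
for TOST calibration; and 10 seeded end-to-end pipeline runs. These sizes
were chosen so the whole suite completes in about a minute while keeping
Monte-Carlo error well below every asserted margin.

## Known limitations

* Standard errors of item parameters are not computed; the pipeline's
  inferences ride on score-level statistics, not on parameter-level Wald
  intervals.
* The equivalence test is asymptotic (z-based); at n in the hundreds its
  boundary calibration has not been verified here.
* Group-mean intervals default to the normal approximation (a t option
  exists); at the motivating group sizes the difference is negligible.
* The assembly treats the 12 items as the complete universe of candidate
  items; with a larger item bank the same machinery applies but the
  enumeration oracle's feasibility bound (10⁶ subsets) binds sooner.
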