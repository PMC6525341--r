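---
title: "Detecting adaptive lineage-specific gene-family expansions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adaptive lineage-specific gene-family expansions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsexpand)
```

## The question and the inference

Two sister clades with contrasting ecologies — in the motivating system, the
largely phytophagous beetle suborder Polyphaga against the largely predaceous
Adephaga, 18 species on a ~250 My ultrametric tree — differ in the sizes of
many gene families. The question `lsexpand` answers is: *for which families
is the difference better explained by selection toward a larger optimal
family size in one clade than by neutral turnover?* The inference proceeds in
three stages, each of which is an exported, separately testable surface.

### Stage 1: birth–death gene gain and loss

Family size evolves by a linear birth–death process: each gene copy
duplicates at rate $\lambda$ and is lost at rate $\mu$ (events/gene/My), with
size 0 absorbing (a family that disappears cannot be reinvented). Over a
branch of length $t$ the single-copy transition law is geometric-type with

$$\alpha = \mu E,\quad \beta = \lambda E,\quad
E = \frac{e^{(\lambda-\mu)t} - 1}{\lambda e^{(\lambda-\mu)t} - \mu},$$

($\alpha=\beta=\lambda t/(1+\lambda t)$ at $\lambda=\mu$), and a parent of
size $s$ produces the $s$-fold convolution — the classical
$P(c\,|\,s,t)=\sum_j \binom{s}{j}\binom{s+c-j-1}{s-1}
\alpha^{s-j}\beta^{c-j}(1-\alpha-\beta)^j$. `bd_transition_matrix()` builds
the truncated kernel by iterated convolution of the single-copy law, which is
exact on the truncated range; the test suite checks it against the direct sum
and against the matrix exponential of the truncated generator.

Per-family likelihoods use Felsenstein pruning over count states
$0..\text{cap}$. The truncation cap is tiered per family — the smallest of
20, 40, 80, … at least twice the family's maximum count — so one huge family
does not inflate every family's state space; by the truncation-stability
property (enlarging the cap beyond twice the maximum changes ln L by
< 1e-8) the tiering is numerically equivalent to a single global cap.

**Root priors.** Two distinct uses must be kept apart:

* For **rate estimation** (`fit_global_rates()`) all families share one
  uniform root prior $U\{1..R\}$. $R$ is moment-matched to the table: the
  prior mean $(R+1)/2$ is set to the mean tip count corrected for net drift,
  $R = 2\,\overline{c}\,e^{-(\hat\lambda-\hat\mu)T} - 1$, iterating the
  correction once. A per-family prior tied to the family's own maximum count
  is *not* used here: the maximum is an upper-tail statistic of the realized
  trajectory, so such a prior systematically lets expansions be re-explained
  as "started large, then lost copies" and inflates $\hat\mu$ by ~40% in
  simulation, while the shared moment-matched prior recovers the generating
  rates within ~12% at the study scale (2000 families, 18 tips).
* For **per-family statistics** (`family_log_likelihood()`,
  `family_p_values()`, `ancestral_counts()`) the conventional per-family
  uniform prior on $1..\max(\text{counts},1)$ is kept: there the prior is a
  conditioning device, not an estimation prior.

The single-rate ($\lambda=\mu$) and distinct-rate modes are compared by a
likelihood-ratio test with one degree of freedom; the LRT requires both fits
to share the same $R$ (enforced), which also guarantees the nesting
inequality.

**Screening p-values.** `family_p_values()` simulates null families from the
fitted rates and the shared root prior, computes the same statistic (the
family's own-prior log-likelihood) for observed and simulated families, and
compares each family against null families of similar size: the null sample
is partitioned by quantiles of its maximum tip count (8 bins of `n_sim`
families each by default), and the family's p-value is the left-tail fraction
within its own bin. Conditioning on a binned statistic keeps the p-values
exactly uniform under the fitted model (verified by a Kolmogorov–Smirnov
check in the suite: statistic ≈ 0.03 on 500 null families) while restoring
the power that a raw, size-confounded statistic loses. The 0.01 screening
threshold is the conventional default of this model class.

**Ancestral counts** are max-product (Viterbi) reconstructions over the same
state space; argmax ties resolve to the smaller count (deterministic, and
conservative about gene content). Branch calls (expansion / contraction /
stasis) feed the per-node tallies that mirror the study's per-node pie
charts.

### Stage 2: five-model regime comparison

For each screened family the per-species count is treated as a continuous
trait on the regime-painted tree. Painting assigns every edge of a clade,
including its stem, the clade's regime; the root carries a label only. The
models and their parameter counts $k$:

| model | mean structure | covariance | k |
|-------|----------------|------------|---|
| BM1  | root state | $\sigma^2 \times$ shared path | 2 |
| BMS  | root state | per-regime $\sigma^2$ | 3 |
| OU1  | one optimum $\theta$ | OU recursion, one $\alpha,\sigma^2$ | 3 |
| OUM  | two optima | as OU1 | 4 |
| OUMV | two optima | per-regime $\sigma^2$ | 5 |

The OU covariance accumulates along each edge as
$v_\text{end} = v_\text{start}e^{-2\alpha\ell} +
\sigma^2(1-e^{-2\alpha\ell})/(2\alpha)$ from a fixed root and decays with
time since the last common ancestor; $\alpha \to 0$ reduces to Brownian
motion (computed via `expm1` so the limit is exact to rounding). Tip
expectations use Hansen weights along each lineage, with the residual root
mass $e^{-\alpha T}$ assigned to the regime of the lineage's most basal edge
(the stationarity convention; with a two-clade painting this is the clade's
own optimum, and weight rows sum to one). The root's own optimum is not a
free parameter, which is what the $k$ column above reflects.

Fitting profiles the optima (or root state) by generalized least squares and
the overall variance scale analytically, leaving a bounded search over
$\log\alpha \in [\log 10^{-5}, \log 10]$ and, for BMS/OUMV, the log variance
ratio in $[-8, 8]$: a 15-point grid plus golden-section refinement in one
dimension, a 7×7 grid plus Nelder–Mead from the five best cells in two.
The likelihood surface is ridge-prone in $(\alpha, \sigma^2)$, which the
profiling removes; fitted likelihoods are checked against dense
multivariate-normal evaluation to 1e-6.

Counts enter as raw integers (the trait the study models); degenerate
constant traits are guarded by a $10^{-12}$ floor on the profiled scale.
AICc $=-2\ln L + 2k + 2k(k+1)/(n-k-1)$ compares the models; with $n = 18$
tips the correction is substantial (an OUM win over BM1 needs
$\Delta \ln L > 4.1$). The alternative is retained when the best H0 AICc
exceeds the best H1 AICc by strictly more than 2; boundary ties go to H0.
AICc is reported as `NA` when $n \le k+1$ and such fits cannot enter
selection.

### Stage 3: enrichment

Positive calls per direction (regime with the larger optimum) are compared
against the background by the study's resampling test: draw the category's
size from the background without replacement, 100,000 times, and report the
fraction of draws with at least the observed number of positives — no
pseudo-count, so an unreached tail is an honest 0 (printed as "< 1/n_draws"
semantics by the caller). BH correction runs across all categories tested
(m = 8 in the study configuration), not only those with nonzero counts. The
analytic hypergeometric tail is implemented alongside purely as an oracle.
The two "global" comparisons use, respectively, the two-sample
equality-of-proportions χ² test (Yates correction on by default, both modes
exposed) and the same resampling test with the whole candidate set as one
category.

## The synthetic-data module

The generators define the study conditions under which the package is
validated:

* `fixture_tree()` — deterministic 18-species tree, two clades of nine,
  250 My deep, painted `Adephaga`/`Polyphaga` with root label `root`. Node
  ages are synthesized (the source figure prints none) with similar age
  distributions in the two suborders.
* `simulate_count_table()` — birth–death counts at the study's rate scale
  (defaults λ = 0.002, μ = 0.0018 events/gene/My, 2000 families, root sizes
  uniform on 1..10). Sampling uses the same transition law the inference
  evaluates — self-consistency is the point of the recovery tests — and an
  independent event-by-event (Gillespie) simulator cross-checks the law.
* `simulate_trait()` — exact BM/OU branch transitions, replicated and
  seeded; sample covariances are checked against `model_covariance()`.
* `plant_categories()` — Bernoulli positives for a background (default rate
  0.009, the study's background order of magnitude) and candidate categories
  at the study's sizes (91 families in 8 categories).

Planted adaptive expansions for the end-to-end recovery check use OUM counts
with $\alpha = 0.03$/My (decay half-life ≈ 23 My on a 250 My tree),
$\sigma^2 = 0.5$, and optima 2 vs ≈ 16 gene copies — a roughly eightfold
optimum ratio, at the strong end of what the motivating study's positive
families show. The separation is deliberately clear because the planted
families must pass both the gain/loss screen and the regime test; the
module-level direction-recovery property separately exercises the regime
stage alone at the tighter 3-standard-deviation separation.

What the generators do *not* emulate: transcriptome isoform collapse or
duplication inflation (only the optional tip-error smear $\varepsilon$, off
by default, gestures at observation error), annotation noise in candidate
selection, and non-ultrametric trees. Passing tests therefore demonstrate
the statistical machinery under the model's own assumptions, not robustness
to those artifacts.

## Numerical and design choices

* Ultrametricity tolerance 1e-6 relative, inclusive at the boundary;
  deviations are measured against the median tip depth so the offending
  tips, not the majority, are named.
* Rate bounds $[10^{-8}, 1]$ events/gene/My in log space; L-BFGS-B from
  deterministic multi-starts seeded by the single-rate optimum; rates so
  extreme that the truncated likelihood underflows return a finite penalty
  so the bounded search recovers.
* Pruning rescales each family's conditional-likelihood column per edge,
  accumulating log scale factors, so 250 My trees with outlier families do
  not underflow.
* All stochastic stages take explicit integer seeds and restore the caller's
  RNG state; a pipeline run is byte-reproducible from `(inputs, config,
  seed)`.
* Problem sizes in the shipped tests (2000 families for rate recovery, 500
  null families × 1000 simulations per size bin for calibration, 200
  replicates for direction recovery, 800 + 40 families end-to-end) were
  chosen as the smallest sizes at which the studied effects are comfortably
  resolved.

## Known limitations

* The birth–death model has no within-family innovation (state 0 absorbing)
  and no branch-specific rates; families gained after the clades' split are
  excluded by design by the shared-family filter.
* The error model is a fixed symmetric smear, not the calibrated
  distribution a full error-estimation pass would produce.
* Regime paintings beyond two clades plus a root label fit and simulate, but
  selection directions are only defined for the two-regime contrast.
* The resampling enrichment inherits Monte Carlo granularity 1/`n_draws`;
  analytic tails are available when exactness matters.

## A complete run

```{r, eval = FALSE}
tree <- fixture_tree()
counts <- simulate_count_table(tree, n_families = 2000, seed = 1)
report <- run_pipeline(counts, tree, attr(tree, "regime_map"), seed = 1)
glance(report)
autoplot(report, "node_changes")
write_results(report, "results/")
```
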