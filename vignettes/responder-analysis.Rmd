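---
title: "Identifying responders to robot-assisted gait training: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying responders to robot-assisted gait training: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragtcausal)
```

## The analysis problem

A cohort of patients with severe hemiplegia after a first supratentorial
stroke undergoes four weeks of gait training with a single-legged
assistance robot. The outcome of interest is binary: walking with
supervision or better at four weeks, defined as a score of at least 5 on
the 7-level walking-independence scale (GAA). Candidate explanatory
variables are demographics (age, sex), stroke characteristics (type,
affected side), days from stroke onset to training initiation, the
baseline walking score, five FIM cognitive items (1–7 each), and seven
SIAS items covering lower-limb motor function (0–5), sensation (0–3) and
trunk function (0–3).

These variables are not causally independent of one another — trunk
control influences the baseline walking score, tactile sensation
influences joint position sense, cognitive items share a common driver —
so a flat regression of outcome on everything confounds direct effects
with mediated ones. The pipeline therefore runs causal discovery first,
uses the discovered graph to select the variables with *direct* edges into
the outcome, and only then quantifies those associations with regression
models.

## Causal discovery: DirectLiNGAM

The discovery model is a linear structural equation model with
non-Gaussian, mutually independent noise and no unobserved confounders:
`x = B x + e`, with `B` permutable to strict lower-triangular form
(acyclicity). Under these assumptions the causal order is identifiable:
for a dependent pair, regressing effect on cause leaves a residual
independent of the cause, while the reverse regression does not, and the
asymmetry is detectable whenever the noise is non-Gaussian.

The ordering loop scores each remaining candidate `i` by
`T(i) = Σ_{j≠i} min(0, M(i→j))²`, where

`M(i→j) = H(x_j) + H(r_{i|j}) − H(x_i) − H(r_{j|i})`

is the log-likelihood ratio comparing the model `i → j` against `j → i`
(`r_{a|b}` is the standardized least-squares residual of `a` on `b`).
Only negative evidence is accumulated, so the most exogenous variable has
the smallest score; it is appended to the order, regressed out of the
remaining columns, and the loop repeats. Differential entropy `H` uses
the standard maximum-entropy approximation

`H(u) ≈ H(ν) − k₁ (E[log cosh u] − γ)² − k₂ (E[u e^{−u²/2}])²`

with `H(ν) = (1 + log 2π)/2`, `k₁ = 79.047`, `k₂ = 7.4129`,
`γ = 0.37457`, the constants used by published implementations — chosen
here deliberately so results are comparable against an independent
reference implementation. Ties in the exogeneity score fall to the lowest
column index, making the estimate fully deterministic. Columns are
standardized internally, so the recovered order is invariant to positive
rescaling of any variable. Direct effects are then ordinary least-squares
coefficients of each variable on its predecessors in the order; no
pruning is applied at this stage (an option exists), because weak-edge
suppression is the ensemble's job.

Numerical notes: the ordering loop is compiled (it runs inside the
bootstrap), the residual scale is computed in closed form
(`sd = √(1−ρ²)` for standardized pairs), and a pair with `|ρ| → 1` or a
zero-variance column raises an error rather than returning a degenerate
order; inside the bootstrap such an iteration is recorded as failed and
skipped. On Gaussian data the direction measure is uninformative; the
contract is only that *some* valid permutation is returned.

## Bootstrap stabilization

A single structure estimate on 126 patients would be fragile, so the
graph is an ensemble: `n_boot = 1000` resamples of the rows (with
replacement, same n), one structure fit per resample, per-iteration
effects with `|effect| ≤ 0.05` zeroed. Per edge the ensemble records the
mean effect (averaged over *all* iterations, zeros included — an
`average = "retained"` mode divides by retaining iterations only, since
the convention is genuinely ambiguous), the retention frequency, and the
sign-stability: the fraction of iterations in which the edge survived
thresholding with the sign of its ensemble mean. Sign-stability can never
exceed retention.

The final graph keeps edges with `|mean| > 0.05`, resolves each
bidirectional pair by keeping the direction with the larger absolute mean
(exact ties fall to the lexicographically smaller source–target pair,
with a warning), and repairs cycles by repeatedly locating a directed
cycle and deleting its weakest edge. "Weakest within the detected cycle",
not globally: that is the minimal perturbation consistent with iterative
weakest-edge removal. Cycle detection is a depth-first search over
sorted nodes and sorted neighbors, so repair is deterministic; the
result is independently asserted acyclic (igraph) on every run. The
reporting table applies both stability floors — `|mean| > 0.05` and
sign-stability `≥ 0.20` — and tags edges with `|mean| > 0.20` as solid,
others dashed.

Bootstrap iteration `b` draws its seed from the pair (root seed, `b`)
through a labelled hash, so runs are reproducible, iterations are
independent, and adding a stage never perturbs another stage's draws.

## Variable coding

Each ordinal or continuous variable is dichotomized at its sample median
(quartiles and medians by linear interpolation, quantile type 7). The
default split codes 1 strictly above the median. Two scale-boundary cases
need care:

* floor medians (ankle dorsiflexion has median 0 on 0–5): `≥ median`
  would code everyone 1, so strict `>` is the right default;
* ceiling medians (trunk verticality has median 3 on 0–3): strict `>`
  codes everyone 0, so the split falls back to `≥ median` for that
  column.

The direction actually used is recorded per column in the coding log, and
a column degenerate in both directions (a constant variable) is dropped
with a warning. Whether the median-valued patients belong to the high or
low group is not derivable from the summary statistics the analysis
emulates; both directions are exposed, and the per-column fallback keeps
every non-constant variable in the analysis. The baseline walking score
enters the models dichotomized like every other ordinal variable.

## The synthetic cohort generator

The real cohort is not public, so the generator stands in for it. It
emulates three things and nothing more:

1. **The screening cascade** — a 250-record roster built so the ordered
   filters exclude exactly 11/15/59/5/7/10/4/4/9 records and admit 126,
   with first-failure attribution; record order is shuffled by seed.
2. **Baseline marginals** — each ordinal variable gets a fixed level
   distribution chosen once to reproduce the published overall medians
   and quartiles (e.g. trunk verticality probabilities 0.08/0.12/0.28/0.52
   over 0–3 give median 3, IQR [2, 3]; ankle dorsiflexion mass 0.80 at 0
   pins the floor). Age is Normal(61.2, 11.8²); days to training uses a
   piecewise-linear quantile function anchored at (34.0, 42.5, 54.8) with
   simulator-chosen tails at 15 and 90 days, values a subacute
   rehabilitation cohort could plausibly span. Nominal variables are
   assigned by exact stratified counts (37/126 female, 47/126 infarction,
   54/126 left-sided at n = 126), matching the published proportions
   exactly at the study size.
3. **A planted causal structure** — baseline latents are drawn from a
   linear non-Gaussian SEM over a sparse DAG (tactile → position sense,
   hip → knee → ankle, comprehension → other cognitive items, trunk →
   abdominal and → baseline walking score; weights 0.3–0.5, fixed once —
   the study's recovered graph is reported without numeric edge weights,
   so these are free simulator parameters). Latents map onto instrument scales by
   rank-based quantile binning, a monotone transform that preserves the
   dependence structure while matching the marginals. The binary outcome
   is then drawn from a logistic structural equation over the
   median-dichotomized parents, with nine planted log-odds: the three
   headline effects at their published sizes (trunk verticality
   log 7.79, joint position sense log 3.37, days-to-training log 0.19)
   and six weaker effects (log 1.5–1.8). Unless an intercept is given,
   it is calibrated so expected prevalence matches the published
   responder fraction (66/126).

Default noise is uniform on `[−√3·s, √3·s]`: bounded, strongly
sub-Gaussian, the customary choice for testing LiNGAM identifiability.
Laplace, centered-exponential and Gaussian noise are available; the
Gaussian case exists to demonstrate non-identifiability downstream.

What the generator does *not* emulate: the real joint distribution beyond
these marginals and the planted graph, measurement error in the
instruments, or any time structure. Passing tests therefore demonstrate
that the pipeline recovers structures *of this kind* at these sample
sizes — not that the published estimates are correct.

## Confirmation models

Logistic regression is fit by iteratively reweighted least squares
(relative deviance tolerance 1e-10, 100 iterations max) with Wald
standard errors, `exp(β ± 1.96·SE)` intervals, and two-sided Wald p
values at the 0.05 threshold. Separation is flagged heuristically when a
coefficient magnitude exceeds 15; the fit is returned with a warning
rather than suppressed.

The L1-penalized fit standardizes columns, builds a 100-point grid
log-spaced four decades down from the smallest all-zero penalty, and
picks λ* by five-fold cross-validated binomial deviance on seeded
stratified folds. The default is the one-standard-error rule — the
largest penalty within one SE of the deviance minimum. The minimizing
penalty itself is exposed (`rule = "min"`), but in a variable-screening
analysis it systematically drags noise variables into the active set: on
planted 3-signal/6-noise cohorts at n = 5000 the min rule kept one to
five noise coefficients nonzero per run, while the one-SE rule recovered
exactly the three planted signals; sparsity is the point of this stage,
so one-SE is the default. Penalized coefficients have no standard
closed-form intervals; the reported 95% bounds are percentile bootstrap
(500 resamples, refit at fixed λ*) and are labelled as such. Zeroed
coefficients are reported as OR 1 with no interval.

## Problem sizes used in the checks

The test suite exercises order recovery on 5-node dense lower-triangular
systems at n = 5000 (50 seeds), reference-implementation agreement at
n = 2000 (20 seeds), cycle repair on 1,000 randomized digraphs, Wald
coverage on 200 cohorts of n = 500, and the full pipeline on planted
cohorts of n = 5000 with 200 bootstrap iterations (10 seeds). The
200-iteration ensemble is a deliberate scale-down of the 1,000-iteration
default for repeated seeded runs; at n = 5000 the retained-edge sets are
already stable at 200 iterations, and the default remains 1,000.

## Known limitations

* The discovery stage is applied to dichotomized (binary) variables plus
  a binary outcome, exactly as in the study design it follows. Binary
  data violate the linear-SEM assumptions; this is a documented
  methodological compromise of that design, partially mitigated by the
  bootstrap ensemble and by confirming selected variables with regression
  models. The package follows the design rather than resolving the
  compromise.
* Median dichotomization discards within-scale information; skewed splits
  (e.g. 80% zeros in ankle dorsiflexion) carry little signal and their
  edges are correspondingly unstable.
* The mixed-data extension of the discovery model (for which the
  stability-reporting criteria here were originally formulated) is out of
  scope; only its reporting wrapper — mean weight and sign-stability
  floors — is implemented, applied to a pluggable learner.
* Bootstrap percentile intervals at fixed λ* understate the uncertainty
  of the penalty choice itself.
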