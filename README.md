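# ragtcausal

Causal responder analysis for robot-assisted gait training (RAGT) cohorts.

## The problem

After a severe supratentorial stroke, some non-ambulatory patients regain
the ability to walk with supervision after a 4-week course of single-legged
robot-assisted gait training, and some do not. Which baseline
characteristics separate responders from non-responders? The clinical
variables involved (lower-limb motor items, sensory items, trunk function,
cognitive items, time from onset to training) are causally entangled, so a
plain regression screen conflates direct and mediated effects.

`ragtcausal` implements the full analysis pipeline for this question:

1. **Eligibility screening** — an ordered exclusion cascade
   (non-supratentorial lesion → recurrent stroke → SIAS lower-limb motor
   total > 5 → walking score > 4 → subarachnoid hemorrhage → neurological
   comorbidity → declined → incomplete assessment → < 10 sessions), each
   patient tallied under the first criterion failed.
2. **Variable coding** — the binary outcome is walking with supervision or
   better (4-week GAA ≥ 5); ordinal/continuous baseline variables are
   dichotomized at their sample median, nominal variables dummy-coded.
3. **Causal discovery** — DirectLiNGAM: for data generated by a linear
   non-Gaussian acyclic structural equation model `x = Bx + e`, the causal
   order is estimated by iteratively extracting the most exogenous
   variable. Exogeneity of candidate `i` is scored by
   `T(i) = Σ_j min(0, M(i→j))²`, where
   `M(i→j) = H(x_j) + H(r_i|j) − H(x_i) − H(r_j|i)`
   is the log-likelihood ratio of the two pairwise causal directions and
   `H` is the maximum-entropy approximation of differential entropy.
   Direct effects are then estimated by least squares along the order.
4. **Bootstrap stabilization** — the learner is refit on 1,000 resamples;
   per-iteration effects with |effect| ≤ 0.05 are zeroed; effects are
   averaged across iterations; bidirectional edge pairs keep the stronger
   direction; remaining cycles are repaired by iteratively deleting the
   weakest edge in a detected cycle; per-edge retention frequency and
   sign-stability (fraction of resamples with the sign of the ensemble
   mean) are reported, with reporting floors |mean| > 0.05 and
   sign-stability ≥ 0.20.
5. **Confirmation** — parents of the outcome node enter (a) a
   maximum-likelihood logistic regression with Wald 95% CIs and (b) an
   L1-penalized logistic regression with five-fold cross-validated penalty
   and percentile-bootstrap intervals.

Because the underlying patient-level data are not public, the package
ships a synthetic-cohort generator with a planted causal graph and planted
outcome odds ratios (trunk verticality 7.79, joint position sense 3.37,
late training start 0.19), so every stage is testable end to end.

## Worked example

```r
library(ragtcausal)

cfg <- pipeline_config(
  sim_spec = cohort_sim_spec(n_patients = 5000, seed = 101),
  n_boot = 200, n_boot_ci = 0, seed = 101)
report <- run_pipeline(cfg)
report$selected_parents
forest_table(report$logistic)
```

Output (seed 101):

```
[1] "sias_trunk_verticality" "days_to_ragt"           "sias_position_sense"
[4] "gaa_baseline"           "fim_memory"             "sias_knee_extension"
[7] "sias_abdominal"

                    term        or    ci_low   ci_high             p
1 sias_trunk_verticality 6.9100327 5.9500868 8.0248496 1.478217e-141
2           days_to_ragt 0.1929678 0.1671654 0.2227527 9.060873e-112
3    sias_position_sense 3.2331105 2.8016390 3.7310315  5.137781e-58
4           gaa_baseline 2.0364512 1.6591927 2.4994887  1.018149e-11
5             fim_memory 1.7237566 1.5034002 1.9764111  6.058074e-15
6    sias_knee_extension 1.7341442 1.5121491 1.9887299  3.353552e-15
7         sias_abdominal 1.5635267 1.3589870 1.7988515  4.154934e-10
```

The discovery stage finds the variables with *direct* causal edges into
the walking outcome; the logistic stage quantifies their associations as
odds ratios. Here the three planted headline effects are recovered close
to their generating values (6.91 vs 7.79 for trunk verticality, 0.193 vs
0.19 for days to training initiation, 3.23 vs 3.37 for joint position
sense); the remaining parents are the weaker planted effects.

A screening cascade and a baseline table come from the same package:

```r
scr <- apply_screening(read.csv(system.file(
  "extdata", "screening_fixture.csv", package = "ragtcausal")))
scr$tally          # 11 15 59 5 7 10 4 4 9
nrow(scr$included) # 126
```

## Repository layout

- `R/`, `src/` — implementation (the DirectLiNGAM ordering loop is compiled)
- `inst/extdata/` — frozen text fixtures (screening roster, synthetic
  cohort, default pipeline configuration); regenerate with
  `tools/make_fixtures.R`
- `vignettes/responder-analysis.Rmd` — the methods vignette
- `inst/cli/ragtcausal.R` — thin command-line wrapper over the pipeline
- `tests/testthat/` — unit, property and acceptance suites
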