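# Default pipeline configuration: the retrospective single-center
# responder-analysis design. Point cohort_csv at a cohort table to run on
# real data; otherwise the simulator is used programmatically.
outcome_name: walk_supervision
direction: greater       # high group strictly above the median
n_boot: 1000             # bootstrap iterations for graph stabilization
edge_threshold: 0.05     # retain per-iteration effects with |effect| > 0.05
stability_min: 0.20      # sign-stability floor for the reporting table
folds: 5                 # cross-validation folds for the LASSO penalty
lasso_rule: 1se          # one-standard-error rule on CV binomial deviance
n_boot_ci: 500           # bootstrap resamples for LASSO intervals
seed: 1
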