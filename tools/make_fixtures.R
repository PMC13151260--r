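# Regenerates the frozen fixtures under inst/extdata/ from the package's
# own generators. Run from the repository root after installing the package:
#   Rscript tools/make_fixtures.R
library(ragtcausal)

scr <- generate_screening_fixture(seed = 20180201)
write.csv(scr, "inst/extdata/screening_fixture.csv", row.names = FALSE,
          quote = FALSE)

spec <- cohort_sim_spec(n_patients = 126, seed = 20180201)
cohort <- generate_cohort(spec)
write_cohort_csv(cohort, "inst/extdata/synthetic_cohort_126.csv")
write_spec_json(spec, "inst/extdata/synthetic_cohort_126_spec.json")
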