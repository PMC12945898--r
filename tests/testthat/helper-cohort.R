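# The reference synthetic cohort used by the acceptance suite: 40 subjects,
# 300 trials per condition, both models fitted. Computed once per test run
# and shared between the recovery and association checks.
.cohort_env <- new.env(parent = emptyenv())

cohort_study <- function() {
  if (is.null(.cohort_env$res)) {
    cfg <- study_config(seed = 1, ppc_subjects = 0, n_boot = 0)
    .cohort_env$res <- run_study(cfg, progress = FALSE)
  }
  .cohort_env$res
}
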