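# Small parameter sets and datasets reused across tests; everything is
# generated in code under fixed seeds.

nback_lba_params <- function(...) {
  args <- utils::modifyList(
    list(task = "nback2",
         v_match = c(target = 2.5, lure = 1.5, novel = 2.8),
         v_mismatch = c(target = 0.8, lure = 1.2, novel = 0.4),
         B = 0.9, A = 0.4, sv_mismatch = 0.9, t0 = 0.25, p_gf = 0.05),
    list(...)
  )
  do.call(lba_params, args)
}

nback_ddm_params <- function(...) {
  args <- utils::modifyList(
    list(task = "nback2", v = c(target = 1.8, lure = 0.9, novel = 2.2),
         a = 1.3, z_rel = 0.45, Ter = 0.3, st0 = 0.12, p_gf = 0.04),
    list(...)
  )
  do.call(ddm_params, args)
}

# hand-written 3-trial table (one omission)
toy_trials <- function() {
  validate_trials(tibble::tibble(
    subject = "s1", task = "nback2",
    condition = c("target", "lure", "novel"),
    response = c("target", "nontarget", "omitted"),
    rt = c(0.62, 0.80, NA)
  ))
}

# a subject with given accuracy / omission profile, RTs arbitrary valid
qc_profile_trials <- function(subject, n_correct, n_wrong, n_omit) {
  n_resp <- n_correct + n_wrong
  tibble::tibble(
    subject = subject, task = "nback2",
    condition = rep("target", n_resp + n_omit),
    response = c(rep("target", n_correct), rep("nontarget", n_wrong),
                 rep("omitted", n_omit)),
    rt = c(runif(n_resp, 0.4, 1.5), rep(NA_real_, n_omit))
  )
}
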