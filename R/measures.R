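#' Efficiency and speed of evidence accumulation
#'
#' From accuracy-coded LBA rates, the efficiency of evidence accumulation
#' (EEA) is the average over task conditions of the difference between the
#' matching and mismatching accumulator rates; the speed of evidence
#' accumulation (SEA) is the average over conditions of the mean of the two
#' rates. EEA indexes how selectively task-relevant evidence is accumulated;
#' SEA indexes the overall accumulation rate regardless of evidence quality.
#' Adding a constant to both rates in every condition leaves EEA unchanged
#' and shifts SEA one-to-one.
#'
#' @param params An `lba_params` object, or a list with named vectors
#'   `v_match` and `v_mismatch` over the same conditions.
#' @return Scalar EEA (or SEA), in evidence units per second.
#' @export
#' @examples
#' p <- list(v_match = c(a = 3, b = 2, c = 2.5), v_mismatch = c(a = 1, b = 1, c = 0.5))
#' compute_eea(p)  # 5/3
#' compute_sea(p)  # 5/3
compute_eea <- function(params) {
  v <- .aligned_rates(params)
  mean(v$v_match - v$v_mismatch)
}

#' @rdname compute_eea
#' @export
compute_sea <- function(params) {
  v <- .aligned_rates(params)
  mean((v$v_match + v$v_mismatch) / 2)
}

.aligned_rates <- function(params) {
  if (!all(c("v_match", "v_mismatch") %in% names(params))) {
    abort("params must contain v_match and v_mismatch",
          class = "ea_parameter_error")
  }
  vm <- params$v_match
  vmm <- params$v_mismatch
  if (!is.null(names(vm)) && !is.null(names(vmm))) {
    missing <- union(setdiff(names(vm), names(vmm)),
                     setdiff(names(vmm), names(vm)))
    if (length(missing) > 0) {
      abort(paste0("condition(s) missing a rate: ",
                   paste(missing, collapse = ", ")),
            class = "ea_parameter_error")
    }
    vmm <- vmm[names(vm)]
  } else if (length(vm) != length(vmm)) {
    abort("v_match and v_mismatch must cover the same conditions",
          class = "ea_parameter_error")
  }
  list(v_match = vm, v_mismatch = vmm)
}

#' Condition-averaged DDM drift rate
#'
#' Unweighted mean of the condition-specific drift rates, the DDM analogue
#' of the EEA/SEA condition averaging.
#'
#' @param params A `ddm_params` object, or a list/vector with element `v`.
#' @return Scalar mean drift rate.
#' @export
#' @examples
#' compute_v_mean(list(v = c(1, 2, 3)))  # 2
compute_v_mean <- function(params) {
  v <- if (is.list(params)) params$v else params
  if (is.null(v)) abort("params must contain v", class = "ea_parameter_error")
  mean(v)
}

#' Subject-level derived measures from paired model fits
#'
#' Joins the LBA-derived EEA and SEA with the condition-averaged DDM drift
#' rate per subject, using posterior means (the conventional point summary;
#' medians by `point = "median"`). Because EEA, SEA and the drift average
#' are linear in the parameters, applying them to posterior means equals the
#' posterior mean of the derived quantity.
#'
#' @param lba_fits List of `ea_fit` objects (LBA), one per subject.
#' @param ddm_fits Optional list of `ea_fit` objects (DDM) for the same
#'   subjects.
#' @param point `"mean"` or `"median"` posterior point estimate.
#' @return A tibble with one row per subject: `subject`, `task`, `EEA`,
#'   `SEA`, `v_mean` (if DDM fits given) and convergence flags.
#' @export
subject_measures <- function(lba_fits, ddm_fits = NULL,
                             point = c("mean", "median")) {
  point <- match.arg(point)
  lba_tbl <- purrr::map(lba_fits, function(f) {
    p <- fitted_params(f, point)
    tibble(subject = f$subject, task = f$task,
           EEA = compute_eea(p), SEA = compute_sea(p),
           lba_converged = f$converged)
  }) |> dplyr::bind_rows()
  if (is.null(ddm_fits)) return(lba_tbl)
  ddm_tbl <- purrr::map(ddm_fits, function(f) {
    p <- fitted_params(f, point)
    tibble(subject = f$subject, task = f$task,
           v_mean = compute_v_mean(p), ddm_converged = f$converged)
  }) |> dplyr::bind_rows()
  dplyr::full_join(lba_tbl, ddm_tbl, by = c("subject", "task"))
}
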