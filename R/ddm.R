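#' Diffusion decision model parameters
#'
#' Accuracy-coded DDM: a single noisy evidence total starts at
#' `z = z_rel * a` between a lower boundary at 0 (the mismatching response)
#' and an upper boundary at `a` (the matching response) and drifts with
#' condition-specific mean rate `v[c]` (evidence/s, signed toward the
#' matching boundary). Within-trial noise SD is fixed at `s = 1` as the
#' scaling constant (rescaling both `v` and `a` relative to the legacy
#' s = 0.1 convention). Nondecision time is uniform on
#' `[Ter - st0/2, Ter + st0/2]`; `p_gf` is a go-failure mixture probability.
#' No between-trial drift or start-point variability is included: the
#' parameter set is exactly `v` by condition plus `a`, `z`, `Ter`, `st0`,
#' `p_gf`.
#'
#' @param task Task name (see [task_design()]).
#' @param v Mean drift rate(s): scalar or vector named by condition.
#' @param a Boundary separation, > 0.
#' @param z_rel Relative start point in (0, 1).
#' @param Ter Mean nondecision time (s), with `Ter - st0/2 >= 0`.
#' @param st0 Range of the uniform nondecision-time distribution (s), >= 0.
#' @param p_gf Go-failure probability in `[0, 1]`.
#'
#' @return An object of class `ddm_params`.
#' @export
ddm_params <- function(task, v, a = 1.5, z_rel = 0.5, Ter = 0.3, st0 = 0.1,
                       p_gf = 0.02) {
  design <- task_design(task)
  if (length(v) == 1 && is.null(names(v))) {
    v <- setNames(rep(as.numeric(v), length(design$conditions)),
                  design$conditions)
  }
  if (!all(design$conditions %in% names(v))) {
    abort(paste0("v missing for: ",
                 paste(setdiff(design$conditions, names(v)), collapse = ", ")),
          class = "ea_parameter_error")
  }
  stopifnot(a > 0, z_rel > 0, z_rel < 1, st0 >= 0, p_gf >= 0, p_gf <= 1)
  if (Ter - st0 / 2 < 0) {
    abort("Ter - st0/2 must be >= 0", class = "ea_parameter_error")
  }
  structure(
    list(task = design$task, v = v[design$conditions], a = a, z_rel = z_rel,
         Ter = Ter, st0 = st0, p_gf = p_gf, s = 1),
    class = "ddm_params"
  )
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters (", x$task, ")\n", sep = "")
  cat(" v: ", paste(sprintf("%s=%.3g", names(x$v), x$v), collapse = " "), "\n")
  cat(sprintf(" a=%.3g z_rel=%.3g (z=%.3g) Ter=%.3g st0=%.3g p_gf=%.3g\n",
              x$a, x$z_rel, x$z_rel * x$a, x$Ter, x$st0, x$p_gf))
  invisible(x)
}

#' Flatten / rebuild DDM parameters
#'
#' Serialization to the flat named form `v_target, ..., a, z, t0, st0, p_gf`
#' (the start point serializes as relative `z`).
#'
#' @param params A `ddm_params` object.
#' @return Named numeric vector.
#' @export
ddm_flatten <- function(params) {
  c(setNames(params$v, paste0("v_", names(params$v))),
    a = params$a, z = params$z_rel, t0 = params$Ter, st0 = params$st0,
    p_gf = params$p_gf)
}

#' @rdname ddm_flatten
#' @param x Named numeric vector as produced by [ddm_flatten()].
#' @param task Task name.
#' @export
ddm_unflatten <- function(x, task) {
  design <- task_design(task)
  v <- vapply(design$conditions, function(cc) {
    nm <- paste0("v_", cc)
    if (!nm %in% names(x)) abort(paste0("missing parameter ", nm),
                                 class = "ea_parameter_error")
    unname(x[nm])
  }, numeric(1))
  ddm_params(task, v = v, a = unname(x["a"]), z_rel = unname(x["z"]),
             Ter = unname(x["t0"]), st0 = unname(x["st0"]),
             p_gf = unname(x["p_gf"]))
}

#' Wiener first-passage-time density and CDF
#'
#' Defective density (and distribution function) of the decision time at
#' which the diffusion is absorbed at the named boundary, computed from the
#' infinite-series solutions with automatic switching between the small-time
#' and large-time representations (absolute series tolerance 1e-10).
#'
#' @param t Decision time(s), seconds.
#' @param a Boundary separation.
#' @param z_rel Relative start point in (0, 1).
#' @param v Drift rate toward the upper boundary.
#' @param boundary `"upper"` or `"lower"`.
#' @param method `"auto"` (default), `"small"` or `"large"`: which series
#'   representation to use.
#' @return Numeric vector of defective densities (or probabilities).
#' @export
#' @examples
#' # symmetric, zero-drift diffusion: each boundary absorbs half the mass
#' ddm_absorption_prob(a = 1, z_rel = 0.5, v = 0, boundary = "upper")
wiener_fpt_density <- function(t, a, z_rel, v, boundary = c("upper", "lower"),
                               method = c("auto", "small", "large")) {
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  stopifnot(a > 0, z_rel > 0, z_rel < 1)
  wfpt_density_cpp(as.numeric(t), a, z_rel, v, boundary == "upper",
                   match(method, c("auto", "small", "large")) - 1L)
}

#' @rdname wiener_fpt_density
#' @export
wiener_fpt_cdf <- function(t, a, z_rel, v, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  stopifnot(a > 0, z_rel > 0, z_rel < 1)
  wfpt_cdf_cpp(as.numeric(t), a, z_rel, v, boundary == "upper")
}

#' Closed-form absorption probability at a boundary
#'
#' `P(upper) = (1 - exp(-2 v z)) / (1 - exp(-2 v a))` with `z = z_rel * a`
#' (and `z_rel` for `v = 0`); absorption is certain, so the two boundary
#' probabilities sum to one.
#'
#' @inheritParams wiener_fpt_density
#' @return Probability in `[0, 1]`.
#' @export
ddm_absorption_prob <- function(a, z_rel, v, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  p_up <- absorb_upper_cpp(a, z_rel, v)
  if (boundary == "upper") p_up else 1 - p_up
}

#' Gauss-Legendre nodes and weights on \[-1, 1\]
#'
#' Golub-Welsch eigenvalue construction; used to integrate over the uniform
#' nondecision-time interval.
#'
#' @param n Number of nodes.
#' @return List with `nodes` and `weights` (weights sum to 2).
#' @export
gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}

#' Likelihood contribution of a single trial under the DDM
#'
#' Responded trials: `(1 - p_gf)` times the Wiener density at the boundary
#' matching the response, averaged over the uniform nondecision-time
#' distribution by fixed-order Gauss-Legendre quadrature (`st0 = 0` reduces
#' exactly to the density at `rt - Ter`). Omitted trials:
#' `p_gf + (1 - p_gf) * P(decision time + t0 > window)`.
#'
#' @param rt Response time (s), or `NA` for an omission.
#' @param response Response label, or `"omitted"`.
#' @param params A `ddm_params` object.
#' @param condition Condition label.
#' @param window Response window (s); defaults to the task's.
#' @param gl_order Quadrature order for the nondecision-time integral.
#' @return The (defective) likelihood contribution, >= 0.
#' @export
ddm_trial_density <- function(rt, response, params, condition, window = NULL,
                              gl_order = 11) {
  design <- task_design(params$task)
  if (is.null(window)) window <- design$window
  gl <- gauss_legendre(gl_order)
  if (params$st0 < 1e-10) {
    t0s <- params$Ter
    wts <- 1
  } else {
    t0s <- params$Ter + params$st0 * gl$nodes / 2
    wts <- gl$weights / 2
  }
  vc <- params$v[[condition]]
  if (response == omission_label()) {
    tau <- window - t0s
    crossed <- ifelse(tau > 0,
                      wiener_fpt_cdf(pmax(tau, 0), params$a, params$z_rel, vc, "upper") +
                        wiener_fpt_cdf(pmax(tau, 0), params$a, params$z_rel, vc, "lower"),
                      0)
    surv <- sum(wts * pmax(1 - crossed, 0))
    return(params$p_gf + (1 - params$p_gf) * surv)
  }
  boundary <- if (response == design$correct[[condition]]) "upper" else "lower"
  tt <- rt - t0s
  dens <- sum(wts * ifelse(tt > 0,
                           wiener_fpt_density(pmax(tt, 1e-12), params$a,
                                              params$z_rel, vc, boundary), 0))
  (1 - params$p_gf) * dens
}

#' Total DDM log-likelihood of a subject's trials
#'
#' Sum over trials of the log of [ddm_trial_density()]; `-Inf` when any
#' responded trial has zero density (e.g. `rt <= Ter - st0/2`).
#'
#' @param trials Trial tibble for a single subject and task.
#' @param params A `ddm_params` object covering every condition present.
#' @param window Response window (s); defaults to the task's.
#' @param gl_order Quadrature order for the nondecision-time integral.
#' @return The total log-likelihood (scalar).
#' @export
ddm_loglik <- function(trials, params, window = NULL, gl_order = 11) {
  design <- task_design(params$task)
  if (is.null(window)) window <- design$window
  missing_cond <- setdiff(unique(trials$condition), design$conditions)
  if (length(missing_cond) > 0) {
    abort(paste0("conditions not covered by parameters: ",
                 paste(missing_cond, collapse = ", ")),
          class = "ea_configuration_error")
  }
  if (nrow(trials) == 0) return(0)
  prep <- .ddm_prepare(trials, params$task)
  gl <- gauss_legendre(gl_order)
  ddm_loglik_cpp(prep$rt, prep$is_upper, prep$cond, prep$n_omit,
                 unname(params$v), params$a, params$z_rel, params$Ter,
                 params$st0, params$p_gf, window, gl$nodes, gl$weights)
}

.ddm_prepare <- function(trials, task) {
  design <- task_design(task)
  omitted <- trials$response == omission_label()
  cond_idx <- match(trials$condition, design$conditions)
  is_upper <- as.integer(trials$response ==
                           unname(design$correct[trials$condition]))
  list(
    rt = trials$rt[!omitted],
    is_upper = is_upper[!omitted],
    cond = cond_idx[!omitted] - 1L,
    n_omit = tabulate(cond_idx[omitted], nbins = length(design$conditions))
  )
}

#' Raw Euler-Maruyama first-passage simulation
#'
#' Low-level access to the path simulator: `n` first passages of the
#' diffusion between 0 and `a` starting at `z_rel * a` with drift `v`, no
#' nondecision time or go-failure layer. Used as the brute-force oracle for
#' the analytic first-passage distribution.
#'
#' @param n Number of paths.
#' @param v Drift rate.
#' @param a Boundary separation.
#' @param z_rel Relative start point.
#' @param dt Euler step (s).
#' @param t_cap Time cap (s); capped paths get `boundary = NA`.
#' @param seed Integer seed for the internal generator.
#' @return A tibble with `time` (decision time, s) and `boundary`
#'   (`"upper"`, `"lower"`, or `NA` if capped).
#' @export
ddm_euler_paths <- function(n, v, a, z_rel, dt = 1e-4, t_cap = 10, seed = 1) {
  stopifnot(a > 0, z_rel > 0, z_rel < 1, dt > 0)
  sim <- ddm_euler_cpp(as.integer(n), v, a, z_rel * a, dt, t_cap, seed)
  tibble(
    time = sim$time,
    boundary = dplyr::case_match(sim$boundary, 1L ~ "upper", 0L ~ "lower",
                                 .default = NA_character_)
  )
}

#' Simulate DDM trials by Euler-Maruyama discretization
#'
#' Paths start at `z = z_rel * a` and take steps
#' `dx = v dt + sqrt(dt) N(0, 1)` until a boundary is crossed or the 10 s
#' time cap is reached (capped paths are recorded as omissions and counted in
#' the `capped` attribute). The recorded RT adds a nondecision time drawn
#' uniformly from `[Ter - st0/2, Ter + st0/2]`; go failures and
#' response-window censoring produce further omissions.
#'
#' @param params A `ddm_params` object.
#' @param design Named integer vector: trials per condition.
#' @param window Response window (s); defaults to the task's.
#' @param seed Integer seed; same seed, same dataset.
#' @param dt Euler step (s), default 1e-3.
#' @param t_cap Path time cap (s).
#' @param subject Subject identifier for the output table.
#' @return A trial tibble; attribute `capped` counts paths that hit the cap.
#' @export
ddm_simulate <- function(params, design, window = NULL, seed = NULL,
                         dt = 1e-3, t_cap = 10, subject = "s1") {
  td <- task_design(params$task)
  if (is.null(window)) window <- td$window
  if (is.null(names(design))) {
    stopifnot(length(design) == length(td$conditions))
    names(design) <- td$conditions
  }
  stopifnot(all(design >= 1), dt > 0)
  if (!is.null(seed)) set.seed(seed)
  n_capped <- 0L
  out <- purrr::map(names(design), function(cc) {
    n <- design[[cc]]
    path_seed <- sample.int(.Machine$integer.max, 1)
    sim <- ddm_euler_cpp(n, params$v[[cc]], params$a,
                         params$z_rel * params$a, dt, t_cap, path_seed)
    t0 <- runif(n, params$Ter - params$st0 / 2, params$Ter + params$st0 / 2)
    gf <- runif(n) < params$p_gf
    rt <- sim$time + t0
    capped <- sim$boundary < 0
    n_capped <<- n_capped + sum(capped)
    omit <- gf | capped | rt >= window
    match_resp <- td$correct[[cc]]
    mis_resp <- setdiff(td$responses, match_resp)[1]
    resp <- ifelse(sim$boundary == 1, match_resp, mis_resp)
    tibble(
      subject = subject, task = params$task, condition = cc,
      response = ifelse(omit, omission_label(), resp),
      rt = ifelse(omit, NA_real_, rt)
    )
  })
  res <- validate_trials(dplyr::bind_rows(out), window = window)
  attr(res, "capped") <- n_capped
  res
}
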