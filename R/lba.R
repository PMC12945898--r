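#' Linear ballistic accumulator parameters
#'
#' Constructs the accuracy-coded LBA parameter set for a task. Each condition
#' has a matching and a mismatching accumulator with normally distributed
#' trial-to-trial rates (`sv_match` is fixed to 1 as the scaling parameter),
#' start points drawn uniformly on `[0, A]`, and response thresholds
#' `b = A + B` where the gap `B` may vary by response option (it does in the
#' numerosity design: `B_many`, `B_few`; the n-back design uses a single `B`).
#' A go-failure probability `p_gf` mixes in stimulus-independent omissions.
#'
#' @param task Task name (see [task_design()]).
#' @param v_match,v_mismatch Mean accumulation rates (evidence/s) of the
#'   matching and mismatching accumulators: scalars or vectors named by
#'   condition.
#' @param B Threshold gap above the start-point range: scalar or vector named
#'   by response option; must be > 0.
#' @param A Start-point range (>= 0).
#' @param sv_mismatch Rate SD of the mismatching accumulator (> 0), shared
#'   across conditions.
#' @param t0 Nondecision time in seconds (>= 0).
#' @param p_gf Go-failure probability in `[0, 1]`.
#' @param sv_match Rate SD of the matching accumulator; fixed at 1.
#'
#' @return An object of class `lba_params`.
#' @export
#' @examples
#' p <- lba_params("nback2", v_match = c(target = 3, lure = 2, novel = 2.5),
#'                 v_mismatch = 1)
#' p$v_match
lba_params <- function(task, v_match, v_mismatch, B = 1, A = 0.5,
                       sv_mismatch = 1, t0 = 0.3, p_gf = 0.02, sv_match = 1) {
  design <- task_design(task)
  expand <- function(x, levels, what) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- setNames(rep(as.numeric(x), length(levels)), levels)
    }
    if (!all(levels %in% names(x))) {
      abort(paste0(what, " missing for: ",
                   paste(setdiff(levels, names(x)), collapse = ", ")),
            class = "ea_parameter_error")
    }
    x[levels]
  }
  v_match <- expand(v_match, design$conditions, "v_match")
  v_mismatch <- expand(v_mismatch, design$conditions, "v_mismatch")
  B <- expand(B, design$responses, "B")
  stopifnot(A >= 0, t0 >= 0, p_gf >= 0, p_gf <= 1)
  if (sv_mismatch <= 0) abort("sv_mismatch must be > 0", class = "ea_parameter_error")
  if (any(B <= 0)) abort("B must be > 0", class = "ea_parameter_error")
  structure(
    list(task = design$task, v_match = v_match, v_mismatch = v_mismatch,
         B = B, A = A, sv_match = sv_match, sv_mismatch = sv_mismatch,
         t0 = t0, p_gf = p_gf),
    class = "lba_params"
  )
}

#' @export
print.lba_params <- function(x, ...) {
  cat("LBA parameters (", x$task, ")\n", sep = "")
  cat(" v_match:    ", paste(sprintf("%s=%.3g", names(x$v_match), x$v_match),
                             collapse = " "), "\n")
  cat(" v_mismatch: ", paste(sprintf("%s=%.3g", names(x$v_mismatch), x$v_mismatch),
                             collapse = " "), "\n")
  cat(sprintf(" B: %s  A=%.3g sv_mismatch=%.3g t0=%.3g p_gf=%.3g\n",
              paste(sprintf("%s=%.3g", names(x$B), x$B), collapse = " "),
              x$A, x$sv_mismatch, x$t0, x$p_gf))
  invisible(x)
}

#' Flatten LBA parameters to a named numeric vector
#'
#' Serialization used in config and result files; names follow the
#' conventional symbols, e.g. `v_target_match`, `B_many`, `sv_mismatch`.
#' Response-invariant `B` serializes as a single `B`.
#'
#' @param params An `lba_params` object.
#' @return Named numeric vector.
#' @export
lba_flatten <- function(params) {
  v1 <- setNames(params$v_match, paste0("v_", names(params$v_match), "_match"))
  v2 <- setNames(params$v_mismatch,
                 paste0("v_", names(params$v_mismatch), "_mismatch"))
  Bv <- if (length(unique(params$B)) == 1 && params$task != "numerosity") {
    c(B = unname(params$B[1]))
  } else {
    setNames(params$B, paste0("B_", names(params$B)))
  }
  c(v1, v2, Bv, A = params$A, sv_mismatch = params$sv_mismatch,
    t0 = params$t0, p_gf = params$p_gf)
}

#' Rebuild LBA parameters from a flat named vector
#'
#' @param x Named numeric vector as produced by [lba_flatten()].
#' @param task Task name.
#' @return An `lba_params` object.
#' @export
lba_unflatten <- function(x, task) {
  design <- task_design(task)
  get1 <- function(nm) {
    if (!nm %in% names(x)) abort(paste0("missing parameter ", nm),
                                 class = "ea_parameter_error")
    unname(x[nm])
  }
  vm <- vapply(design$conditions, function(cc) get1(paste0("v_", cc, "_match")),
               numeric(1))
  vmm <- vapply(design$conditions, function(cc) get1(paste0("v_", cc, "_mismatch")),
                numeric(1))
  B <- if ("B" %in% names(x)) {
    get1("B")
  } else {
    vapply(design$responses, function(r) get1(paste0("B_", r)), numeric(1))
  }
  lba_params(task, v_match = vm, v_mismatch = vmm, B = B, A = get1("A"),
             sv_mismatch = get1("sv_mismatch"), t0 = get1("t0"),
             p_gf = get1("p_gf"))
}

#' Single-accumulator LBA finishing-time density and CDF
#'
#' Density and distribution function of the time at which one linear
#' ballistic accumulator -- start point uniform on `[0, A]`, rate drawn once
#' per trial from `Normal(v, sv)` with negative draws allowed (the
#' accumulator then never finishes) -- reaches the threshold `b`. Both are
#' defective: `lba_node_cdf(Inf) = P(rate > 0)`. The `A -> 0` limit is
#' handled by an analytically simplified branch.
#'
#' @param t Decision time(s) in seconds, > 0.
#' @param b Threshold (evidence units), `b >= A`.
#' @param A Start-point range, >= 0.
#' @param v Mean rate.
#' @param sv Rate SD, > 0.
#' @return Numeric vector of densities (or probabilities).
#' @export
lba_node_density <- function(t, b, A, v, sv) {
  if (sv <= 0) abort("sv must be > 0", class = "ea_parameter_error")
  if (b < A) abort("threshold b must be >= A", class = "ea_parameter_error")
  out <- numeric(length(t))
  pos <- which(t > 0)
  tt <- t[pos]
  if (A < 1e-6) {
    out[pos] <- (b / tt^2) * dnorm((b / tt - v) / sv) / sv
  } else {
    ts <- tt * sv
    z1 <- (b - A - tt * v) / ts
    z2 <- (b - tt * v) / ts
    out[pos] <- pmax(0, (-v * pnorm(z1) + sv * dnorm(z1) +
                           v * pnorm(z2) - sv * dnorm(z2)) / A)
  }
  out
}

#' @rdname lba_node_density
#' @export
lba_node_cdf <- function(t, b, A, v, sv) {
  if (sv <= 0) abort("sv must be > 0", class = "ea_parameter_error")
  if (b < A) abort("threshold b must be >= A", class = "ea_parameter_error")
  out <- numeric(length(t))
  inf <- which(is.infinite(t) & t > 0)
  out[inf] <- pnorm(v / sv)
  pos <- which(t > 0 & is.finite(t))
  tt <- t[pos]
  if (A < 1e-6) {
    out[pos] <- pnorm((v - b / tt) / sv)
  } else {
    ts <- tt * sv
    z1 <- (b - A - tt * v) / ts
    z2 <- (b - tt * v) / ts
    out[pos] <- 1 + ((b - A - tt * v) / A) * pnorm(z1) -
      ((b - tt * v) / A) * pnorm(z2) + (ts / A) * (dnorm(z1) - dnorm(z2))
  }
  pmin(pmax(out, 0), 1)
}

# accumulator lookup tables for one condition: matching accumulator first
.lba_accumulators <- function(params, condition) {
  design <- task_design(params$task)
  match_resp <- design$correct[[condition]]
  mismatch_resp <- setdiff(design$responses, match_resp)[1]
  list(
    responses = c(match_resp, mismatch_resp),
    v = c(params$v_match[[condition]], params$v_mismatch[[condition]]),
    sv = c(params$sv_match, params$sv_mismatch),
    b = params$A + c(params$B[[match_resp]], params$B[[mismatch_resp]])
  )
}

#' Defective density of a response winning the LBA race
#'
#' Density that the accumulator for response `r` reaches threshold first at
#' decision time `t`: `f_r(t) * prod_{j != r} (1 - F_j(t))`. Integrating over
#' `t` gives the probability of response `r` among trials on which any
#' accumulator finishes.
#'
#' @param t Decision time(s) in seconds (observed RT minus `t0`).
#' @param response Response option label.
#' @param params An `lba_params` object.
#' @param condition Condition label.
#' @return Numeric vector of defective densities.
#' @export
lba_defective_density <- function(t, response, params, condition) {
  acc <- .lba_accumulators(params, condition)
  k <- match(response, acc$responses)
  if (is.na(k)) abort(paste0("unknown response ", response),
                      class = "ea_parameter_error")
  dens <- lba_node_density(t, acc$b[k], params$A, acc$v[k], acc$sv[k])
  j <- setdiff(1:2, k)
  dens * (1 - lba_node_cdf(t, acc$b[j], params$A, acc$v[j], acc$sv[j]))
}

#' Probability that no LBA accumulator ever finishes
#'
#' With untruncated normal rates, an accumulator whose sampled rate is
#' non-positive never reaches threshold; the race produces no response when
#' that happens to all accumulators.
#'
#' @inheritParams lba_defective_density
#' @return Probability in `[0, 1]`.
#' @export
lba_no_finish_prob <- function(params, condition) {
  acc <- .lba_accumulators(params, condition)
  prod(pnorm(-acc$v / acc$sv))
}

#' Probability of a recorded omission under the LBA
#'
#' Mixture of go failure (probability `p_gf`) and -- on go trials -- the race
#' either never finishing or finishing after the response window:
#' `p_gf + (1 - p_gf) * P(min finish time + t0 > window)`, where the
#' never-finish mass is included in the survival term.
#'
#' @param params An `lba_params` object.
#' @param condition Condition label.
#' @param window Response window in seconds.
#' @return Probability in `[0, 1]`.
#' @export
lba_omission_prob <- function(params, condition, window) {
  if (window <= params$t0) {
    warn("response window does not exceed t0; omission is certain on go trials")
    return(params$p_gf + (1 - params$p_gf) * 1)
  }
  acc <- .lba_accumulators(params, condition)
  tau <- window - params$t0
  surv <- prod(1 - vapply(1:2, function(k) {
    lba_node_cdf(tau, acc$b[k], params$A, acc$v[k], acc$sv[k])
  }, numeric(1)))
  params$p_gf + (1 - params$p_gf) * surv
}

#' Total LBA log-likelihood of a subject's trials
#'
#' Responded trials contribute
#' `log[(1 - p_gf) * f_r(rt - t0) * (1 - F_other(rt - t0))]`; omitted trials
#' contribute `log` of [lba_omission_prob()]. Responded trials with
#' `rt <= t0` have zero density and drive the total to `-Inf`.
#'
#' @param trials Trial tibble for a single subject and task.
#' @param params An `lba_params` object covering every condition present.
#' @param window Response window in seconds; defaults to the task's.
#' @return The total log-likelihood (scalar).
#' @export
lba_loglik <- function(trials, params, window = NULL) {
  design <- task_design(params$task)
  if (is.null(window)) window <- design$window
  missing_cond <- setdiff(unique(trials$condition), design$conditions)
  if (length(missing_cond) > 0) {
    abort(paste0("conditions not covered by parameters: ",
                 paste(missing_cond, collapse = ", ")),
          class = "ea_configuration_error")
  }
  if (nrow(trials) == 0) return(0)
  prep <- .lba_prepare(trials, params$task)
  .lba_loglik_prepared(prep, params, window)
}

# precompute integer indices so the likelihood can be re-evaluated cheaply
.lba_prepare <- function(trials, task) {
  design <- task_design(task)
  omitted <- trials$response == omission_label()
  cond_idx <- match(trials$condition, design$conditions)
  resp_idx <- match(trials$response, design$responses)          # NA for omissions
  match_resp_idx <- match(design$correct[design$conditions], design$responses)
  win_is_match <- resp_idx == match_resp_idx[cond_idx]
  list(
    design = design,
    rt = trials$rt[!omitted],
    cond0 = cond_idx[!omitted] - 1L,
    win_is_match = as.integer(win_is_match[!omitted]),
    match_resp_idx = match_resp_idx,
    n_omit = tabulate(cond_idx[omitted], nbins = length(design$conditions))
  )
}

.lba_loglik_prepared <- function(prep, params, window) {
  design <- prep$design
  Bv <- unname(params$B[design$responses])
  b_match <- params$A + Bv[prep$match_resp_idx]    # per condition
  b_mismatch <- params$A + Bv[3L - prep$match_resp_idx]
  lba_loglik_full_cpp(prep$rt, prep$win_is_match, prep$cond0, prep$n_omit,
                      unname(params$v_match), unname(params$v_mismatch),
                      b_match, b_mismatch, params$A, params$sv_match,
                      params$sv_mismatch, params$t0, params$p_gf, window)
}

#' Simulate LBA trials
#'
#' Exact simulator matching the likelihood: per trial and accumulator, start
#' point ~ Uniform(0, A) and rate ~ Normal(v, sv); the first accumulator to
#' reach threshold determines the response, `RT = finish time + t0`. Trials
#' are recorded as omitted on go failure (probability `p_gf`), when no
#' accumulator has a positive rate, or when the RT falls outside the response
#' window.
#'
#' @param params An `lba_params` object.
#' @param design Named integer vector: trials per condition.
#' @param window Response window (s); defaults to the task's.
#' @param seed Integer seed; same seed, same dataset.
#' @param subject Subject identifier for the output table.
#' @return A trial tibble in the canonical schema.
#' @export
lba_simulate <- function(params, design, window = NULL, seed = NULL,
                         subject = "s1") {
  td <- task_design(params$task)
  if (is.null(window)) window <- td$window
  if (is.null(names(design))) {
    stopifnot(length(design) == length(td$conditions))
    names(design) <- td$conditions
  }
  stopifnot(all(design >= 1))
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map(names(design), function(cc) {
    n <- design[[cc]]
    acc <- .lba_accumulators(params, cc)
    t1 <- .lba_finish_times(n, acc$b[1], params$A, acc$v[1], acc$sv[1])
    t2 <- .lba_finish_times(n, acc$b[2], params$A, acc$v[2], acc$sv[2])
    dec <- pmin(t1, t2)
    winner <- ifelse(t1 <= t2, acc$responses[1], acc$responses[2])
    rt <- dec + params$t0
    gf <- runif(n) < params$p_gf
    omit <- gf | !is.finite(rt) | rt >= window
    tibble(
      subject = subject, task = params$task, condition = cc,
      response = ifelse(omit, omission_label(), winner),
      rt = ifelse(omit, NA_real_, rt)
    )
  })
  validate_trials(dplyr::bind_rows(out), window = window)
}

.lba_finish_times <- function(n, b, A, v, sv) {
  start <- runif(n, 0, A)
  rate <- rnorm(n, v, sv)
  ifelse(rate > 0, (b - start) / rate, Inf)
}
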