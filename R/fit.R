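#' Fitting configuration
#'
#' DMC-style defaults for individual Bayesian estimation: `3 * n_params`
#' chains, `gamma = 2.38 / sqrt(2 d)`, uniform jitter `1e-3`, migration with
#' probability 0.05 during burn-in only, burn-in of 500 iterations, then
#' 500-iteration sampling blocks until the maximum univariate R-hat (computed
#' on the second halves of the retained chains) falls below 1.10 or the
#' iteration cap is reached.
#'
#' @param burn_in Burn-in iterations (discarded).
#' @param block Iterations per sampling block.
#' @param max_iter Cap on post-burn-in iterations.
#' @param n_chains_per_param Chains as a multiple of the parameter count.
#' @param gamma Difference scaling factor (`NULL` = `2.38 / sqrt(2 d)`).
#' @param jitter_eps Proposal jitter half-width.
#' @param migration_prob Migration probability during burn-in.
#' @param rhat_threshold Convergence threshold on max univariate R-hat.
#' @param gl_order Gauss-Legendre order for the DDM nondecision integral.
#' @param init_oversample Prior-draw oversampling factor for chain
#'   initialization (see [demcmc_sample()]).
#' @param outlier_reset After burn-in, reset chains whose log posterior lies
#'   more than `outlier_reset` interquartile ranges below the lower quartile
#'   of the chain population to the state of a randomly chosen healthy chain
#'   (a standard guard against stuck outlier chains in differential-evolution
#'   samplers); `Inf` disables.
#' @return A list of class `ea_fit_config`.
#' @export
fit_config <- function(burn_in = 500, block = 500, max_iter = 10000,
                       n_chains_per_param = 3, gamma = NULL,
                       jitter_eps = 1e-3, migration_prob = 0.05,
                       rhat_threshold = 1.10, gl_order = 11,
                       init_oversample = 10, outlier_reset = 2) {
  structure(
    list(burn_in = burn_in, block = block, max_iter = max_iter,
         n_chains_per_param = n_chains_per_param, gamma = gamma,
         jitter_eps = jitter_eps, migration_prob = migration_prob,
         rhat_threshold = rhat_threshold, gl_order = gl_order,
         init_oversample = init_oversample, outlier_reset = outlier_reset),
    class = "ea_fit_config"
  )
}

# log-likelihood closure over a prepared dataset, on the natural scale
.make_loglik <- function(trials, model, task, window, gl_order = 11) {
  design <- task_design(task)
  if (is.null(window)) window <- design$window
  if (model == "lba") {
    prep <- .lba_prepare(trials, task)
    vm_names <- paste0("v_", design$conditions, "_match")
    vmm_names <- paste0("v_", design$conditions, "_mismatch")
    b_names <- if (design$task == "numerosity") {
      paste0("B_", design$responses)
    } else {
      rep("B", length(design$responses))
    }
    function(natural) {
      Bv <- unname(natural[b_names])
      A <- natural[["A"]]
      b_match <- A + Bv[prep$match_resp_idx]
      b_mismatch <- A + Bv[3L - prep$match_resp_idx]
      lba_loglik_full_cpp(prep$rt, prep$win_is_match, prep$cond0, prep$n_omit,
                          unname(natural[vm_names]), unname(natural[vmm_names]),
                          b_match, b_mismatch, A, 1,
                          natural[["sv_mismatch"]], natural[["t0"]],
                          natural[["p_gf"]], window)
    }
  } else {
    prep <- .ddm_prepare(trials, task)
    gl <- gauss_legendre(gl_order)
    nc <- length(design$conditions)
    v_names <- paste0("v_", design$conditions)
    function(natural) {
      Ter <- natural[["t0"]]
      st0 <- natural[["st0"]]
      if (Ter - st0 / 2 < 0) return(-Inf)
      ddm_loglik_cpp(prep$rt, prep$is_upper, prep$cond, prep$n_omit,
                     unname(natural[v_names]), natural[["a"]], natural[["z"]],
                     Ter, st0, natural[["p_gf"]], window, gl$nodes, gl$weights)
    }
  }
}

#' Fit one subject's data by DE-MCMC
#'
#' Individual Bayesian estimation of the LBA or DDM for a single subject:
#' chains are initialized from the prior, burned in with migration, then
#' sampled in blocks until the maximum univariate R-hat over parameters drops
#' below the threshold (1.10 by default) or the iteration cap is reached.
#' Non-convergence is reported through the `converged` flag, not an error.
#'
#' @param trials Trial tibble for a single subject and task (should have
#'   passed [apply_qc()]).
#' @param model `"lba"` or `"ddm"`.
#' @param prior A `prior_spec`; defaults to [default_priors()] for the model
#'   and task.
#' @param config An [fit_config()] list.
#' @param seed Integer seed.
#' @param window Response window (s); defaults to the task's.
#'
#' @return An object of class `ea_fit`: posterior samples (natural scale,
#'   post-burn-in), per-parameter R-hat, `converged`, acceptance rate and a
#'   posterior summary table (means, medians, SD, 95% credible intervals).
#' @export
fit_subject <- function(trials, model = c("lba", "ddm"), prior = NULL,
                        config = fit_config(), seed = NULL, window = NULL) {
  model <- match.arg(model)
  task <- trials$task[1]
  stopifnot(length(unique(trials$task)) == 1,
            length(unique(trials$subject)) == 1)
  if (is.null(prior)) prior <- default_priors(model, task)
  if (!is.null(seed)) set.seed(seed)
  loglik <- .make_loglik(trials, model, task, window, config$gl_order)
  cp <- .compile_prior(prior)
  log_post <- function(theta) {
    lp <- cp$logdensity(theta)
    if (!is.finite(lp)) return(-Inf)
    lp + loglik(cp$to_natural(theta))
  }
  d <- length(prior)
  n_chains <- config$n_chains_per_param * d
  burn <- demcmc_sample(log_post, prior, n_chains = n_chains,
                        n_iter = config$burn_in, gamma = config$gamma,
                        jitter_eps = config$jitter_eps,
                        migration_prob = config$migration_prob,
                        init_oversample = config$init_oversample)
  state <- burn$final
  # reset stuck outlier chains to healthy states, then re-equilibrate with a
  # short second burn so the reset chains decorrelate before sampling
  if (is.finite(config$outlier_reset)) {
    lp_fin <- burn$final_lp
    iqr <- diff(quantile(lp_fin, c(0.25, 0.75)))
    cut <- median(lp_fin) - max(config$outlier_reset * iqr, 8)
    bad <- which(lp_fin < cut)
    if (length(bad) > 0 && length(bad) < n_chains) {
      good <- setdiff(seq_len(n_chains), bad)
      state[bad, ] <- state[sample(good, length(bad), replace = TRUE), ,
                            drop = FALSE]
      reburn <- demcmc_sample(log_post, prior, n_chains = n_chains,
                              n_iter = max(50, config$burn_in %/% 4),
                              gamma = config$gamma,
                              jitter_eps = config$jitter_eps,
                              migration_prob = config$migration_prob,
                              init = state)
      state <- reburn$final
    }
  }
  kept <- NULL
  kept_lp <- NULL
  converged <- FALSE
  iters <- 0
  acc <- numeric(0)
  while (iters < config$max_iter) {
    run <- demcmc_sample(log_post, prior, n_chains = n_chains,
                         n_iter = config$block, gamma = config$gamma,
                         jitter_eps = config$jitter_eps,
                         migration_prob = 0, init = state)
    state <- run$final
    kept <- if (is.null(kept)) run$theta else
      abind_iter(kept, run$theta)
    kept_lp <- rbind(kept_lp, run$lp)
    acc <- c(acc, run$acceptance_rate)
    iters <- iters + config$block
    rh <- rhat(kept)
    if (all(is.finite(rh)) && max(rh) < config$rhat_threshold) {
      converged <- TRUE
      break
    }
  }
  natural <- kept
  for (k in seq_len(dim(kept)[3])) {
    nm <- dimnames(kept)[[3]][k]
    pr <- prior[[nm]]
    natural[, , k] <- switch(pr$transform,
      identity = kept[, , k],
      log = exp(kept[, , k]),
      probit = pr$lower + (pr$upper - pr$lower) * pnorm(kept[, , k])
    )
  }
  flat <- apply(natural, 3, as.vector)
  summary <- tibble(
    term = colnames(flat),
    estimate = colMeans(flat),
    median = apply(flat, 2, median),
    sd = apply(flat, 2, sd),
    conf.low = apply(flat, 2, quantile, 0.025),
    conf.high = apply(flat, 2, quantile, 0.975),
    rhat = unname(rhat(kept)[colnames(flat)])
  )
  structure(
    list(model = model, task = task, subject = trials$subject[1],
         prior = prior, theta = kept, natural = natural, lp = kept_lp,
         rhat = rhat(kept), converged = converged,
         acceptance_rate = mean(acc), n_iter = iters,
         n_trials = nrow(trials), summary = summary, config = config),
    class = "ea_fit"
  )
}

# bind two iteration x chain x param arrays along iterations
abind_iter <- function(a, b) {
  out <- array(NA_real_, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]),
               dimnames = dimnames(a))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' @export
print.ea_fit <- function(x, ...) {
  cat(sprintf("%s fit for subject %s (%s): %d trials, %d iterations, %s\n",
              toupper(x$model), x$subject, x$task, x$n_trials, x$n_iter,
              if (x$converged) sprintf("converged (max R-hat %.3f)", max(x$rhat))
              else sprintf("NOT converged (max R-hat %.3f)", max(x$rhat))))
  print(x$summary)
  invisible(x)
}

#' Tidy posterior summaries of a model fit
#'
#' @param x An `ea_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean (`estimate`),
#'   `median`, `sd`, 95% credible interval and `rhat`.
#' @export
tidy.ea_fit <- function(x, ...) x$summary

#' One-row fit overview
#'
#' @param x An `ea_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: model, subject, task, trial and iteration
#'   counts, max R-hat, convergence flag, acceptance rate.
#' @export
glance.ea_fit <- function(x, ...) {
  tibble(
    model = x$model, subject = x$subject, task = x$task,
    n_trials = x$n_trials, n_iter = x$n_iter, n_chains = dim(x$theta)[2],
    max_rhat = max(x$rhat), converged = x$converged,
    acceptance_rate = x$acceptance_rate
  )
}

#' Posterior-mean parameters of a fit
#'
#' @param fit An `ea_fit` object.
#' @param point `"mean"` (conventional) or `"median"`.
#' @return An `lba_params` or `ddm_params` object built from the posterior
#'   point estimates.
#' @export
fitted_params <- function(fit, point = c("mean", "median")) {
  point <- match.arg(point)
  est <- setNames(
    if (point == "mean") fit$summary$estimate else fit$summary$median,
    fit$summary$term
  )
  if (fit$model == "lba") lba_unflatten(est, fit$task)
  else ddm_unflatten(est, fit$task)
}
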