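#' Prior specifications for model parameters
#'
#' Each parameter gets a proper prior on its natural scale and a transform
#' defining the unconstrained sampling scale: `identity` (real-valued
#' parameters), `log` (positive parameters), or `probit` (parameters bounded
#' on an interval `[lo, hi]`, sampled as `lo + (hi - lo) * pnorm(theta)`).
#' Under the probit transform a uniform prior on `[lo, hi]` corresponds
#' exactly to a standard-normal prior on the sampling scale.
#'
#' The defaults are broad, weakly informative settings covering published
#' DDM/LBA parameter ranges: rates `N(1, 3)` on the real line; `N(1, 2)`
#' truncated to positives for `a`, `A`, `B` and `sv_mismatch`; `t0`/`Ter`
#' uniform on `[0.05, 1]` s; `st0` uniform on `[0, 0.5]` s; `p_gf` uniform
#' on `[0, 0.2]` via probit; `z_rel` uniform on `[0.1, 0.9]` via probit.
#'
#' @param model `"lba"` or `"ddm"`.
#' @param task Task name (see [task_design()]).
#' @return A `prior_spec` object: a named list of per-parameter entries
#'   `list(dist, transform, ...)`.
#' @export
#' @examples
#' names(default_priors("lba", "nback2"))
default_priors <- function(model = c("lba", "ddm"), task) {
  model <- match.arg(model)
  design <- task_design(task)
  tnorm_pos <- list(dist = "tnorm", mean = 1, sd = 2, lower = 0, upper = Inf,
                    transform = "log")
  rate <- list(dist = "norm", mean = 1, sd = 3, transform = "identity")
  punif <- function(lo, hi) list(dist = "unif", lower = lo, upper = hi,
                                 transform = "probit")
  if (model == "lba") {
    p <- c(
      setNames(rep(list(rate), length(design$conditions)),
               paste0("v_", design$conditions, "_match")),
      setNames(rep(list(rate), length(design$conditions)),
               paste0("v_", design$conditions, "_mismatch"))
    )
    b_names <- if (design$task == "numerosity") {
      paste0("B_", design$responses)
    } else "B"
    p <- c(p, setNames(rep(list(tnorm_pos), length(b_names)), b_names))
    p$A <- tnorm_pos
    p$sv_mismatch <- tnorm_pos
    p$t0 <- punif(0.05, 1)
    p$p_gf <- punif(0, 0.2)
  } else {
    p <- setNames(rep(list(rate), length(design$conditions)),
                  paste0("v_", design$conditions))
    p$a <- tnorm_pos
    p$z <- punif(0.1, 0.9)
    p$t0 <- punif(0.05, 1)
    p$st0 <- punif(0, 0.5)
    p$p_gf <- punif(0, 0.2)
  }
  structure(p, class = "prior_spec")
}

#' Map sampling-scale values to the natural scale
#'
#' @param theta Named numeric vector on the sampling scale.
#' @param prior A `prior_spec` object.
#' @return Named numeric vector on the natural scale.
#' @export
prior_to_natural <- function(theta, prior) {
  out <- theta
  for (nm in names(prior)) {
    pr <- prior[[nm]]
    out[nm] <- switch(pr$transform,
      identity = theta[nm],
      log = exp(theta[nm]),
      probit = pr$lower + (pr$upper - pr$lower) * pnorm(theta[nm])
    )
  }
  out
}

#' Log prior density on the sampling scale
#'
#' Natural-scale prior density plus the log-Jacobian of the transform; for
#' probit-uniform parameters this collapses to a standard normal density.
#'
#' @inheritParams prior_to_natural
#' @return Scalar log density (`-Inf` outside the support).
#' @export
prior_logdensity <- function(theta, prior) {
  lp <- 0
  for (nm in names(prior)) {
    pr <- prior[[nm]]
    th <- theta[[nm]]
    lp <- lp + switch(pr$transform,
      identity = {
        if (pr$dist == "norm") {
          dnorm(th, pr$mean, pr$sd, log = TRUE)
        } else {  # bounded uniform sampled directly
          if (th < pr$lower || th > pr$upper) -Inf else -log(pr$upper - pr$lower)
        }
      },
      log = {
        x <- exp(th)
        # truncated normal on (lower, upper), plus Jacobian dx/dtheta = x
        dnorm(x, pr$mean, pr$sd, log = TRUE) -
          log(pnorm(pr$upper, pr$mean, pr$sd) - pnorm(pr$lower, pr$mean, pr$sd)) +
          th
      },
      probit = dnorm(th, log = TRUE)  # uniform on [lo, hi] by construction
    )
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

# Precompiled vectorized versions of prior_logdensity / prior_to_natural,
# used in the sampling hot loop. Parameters are grouped by transform so each
# evaluation is a handful of vectorized calls.
.compile_prior <- function(prior) {
  nms <- names(prior)
  tr <- vapply(prior, function(p) p$transform, character(1))
  id <- which(tr == "identity")
  lg <- which(tr == "log")
  pb <- which(tr == "probit")
  id_norm <- id[vapply(prior[id], function(p) p$dist == "norm", logical(1))]
  id_unif <- setdiff(id, id_norm)
  g <- list(
    nms = nms,
    id_norm = id_norm,
    id_norm_mean = vapply(prior[id_norm], function(p) p$mean, numeric(1)),
    id_norm_sd = vapply(prior[id_norm], function(p) p$sd, numeric(1)),
    id_unif = id_unif,
    id_unif_lo = vapply(prior[id_unif], function(p) p$lower, numeric(1)),
    id_unif_hi = vapply(prior[id_unif], function(p) p$upper, numeric(1)),
    lg = lg,
    lg_mean = vapply(prior[lg], function(p) p$mean, numeric(1)),
    lg_sd = vapply(prior[lg], function(p) p$sd, numeric(1)),
    lg_lognorm = vapply(prior[lg], function(p) {
      log(pnorm(p$upper, p$mean, p$sd) - pnorm(p$lower, p$mean, p$sd))
    }, numeric(1)),
    pb = pb,
    pb_lo = vapply(prior[pb], function(p) p$lower, numeric(1)),
    pb_hi = vapply(prior[pb], function(p) p$upper, numeric(1))
  )
  g$logdensity <- function(theta) {
    lp <- 0
    if (length(g$id_norm)) {
      lp <- lp + sum(dnorm(theta[g$id_norm], g$id_norm_mean, g$id_norm_sd,
                           log = TRUE))
    }
    if (length(g$id_unif)) {
      x <- theta[g$id_unif]
      if (any(x < g$id_unif_lo | x > g$id_unif_hi)) return(-Inf)
      lp <- lp - sum(log(g$id_unif_hi - g$id_unif_lo))
    }
    if (length(g$lg)) {
      th <- theta[g$lg]
      lp <- lp + sum(dnorm(exp(th), g$lg_mean, g$lg_sd, log = TRUE) -
                       g$lg_lognorm + th)
    }
    if (length(g$pb)) {
      lp <- lp + sum(dnorm(theta[g$pb], log = TRUE))
    }
    lp
  }
  g$to_natural <- function(theta) {
    out <- theta
    if (length(g$lg)) out[g$lg] <- exp(theta[g$lg])
    if (length(g$pb)) {
      out[g$pb] <- g$pb_lo + (g$pb_hi - g$pb_lo) * pnorm(theta[g$pb])
    }
    out
  }
  g
}

#' Draw initial values from the prior (sampling scale)
#'
#' @param n Number of draws.
#' @param prior A `prior_spec` object.
#' @return Matrix `n x n_params` on the sampling scale.
#' @export
prior_draw <- function(n, prior) {
  draws <- vapply(names(prior), function(nm) {
    pr <- prior[[nm]]
    switch(pr$transform,
      identity = rnorm(n, pr$mean, pr$sd),
      log = {
        u <- runif(n, pnorm(pr$lower, pr$mean, pr$sd),
                   pnorm(pr$upper, pr$mean, pr$sd))
        log(qnorm(u, pr$mean, pr$sd))
      },
      probit = rnorm(n)
    )
  }, numeric(n))
  matrix(draws, nrow = n, dimnames = list(NULL, names(prior)))
}
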