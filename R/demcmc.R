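#' Differential-evolution MCMC
#'
#' Samples a target density with a population of chains whose Metropolis
#' proposals are scaled differences between two other randomly chosen
#' chains: `proposal = current + gamma * (chain_a - chain_b) + U(-eps, eps)`.
#' With probability `migration_prob` per iteration a ring-migration step
#' instead proposes that each chain in a random subset adopt (a jittered copy
#' of) its predecessor's state, each swap accepted by a Metropolis ratio.
#' Runs are fully reproducible under `seed`.
#'
#' @param log_posterior Function taking a named numeric vector (sampling
#'   scale) and returning a scalar log density.
#' @param prior A `prior_spec` used to draw initial states (see
#'   [prior_draw()]); alternatively supply `init`, a `n_chains x n_params`
#'   matrix of starting values.
#' @param n_chains Number of chains; at least `2 * n_params + 1` so that
#'   difference proposals span the parameter space.
#' @param n_iter Number of iterations to run (each iteration updates every
#'   chain once).
#' @param gamma Difference scaling factor; default `2.38 / sqrt(2 d)`.
#' @param jitter_eps Half-width of the uniform jitter added to proposals.
#' @param migration_prob Per-iteration probability of a migration step.
#' @param seed Integer seed (optional).
#' @param init Optional starting matrix (overrides prior draws).
#' @param init_cap Maximum redraws per chain to find a finite-posterior start.
#' @param init_oversample When initializing from the prior, draw
#'   `init_oversample * n_chains` candidates and start the chains from the
#'   highest-posterior ones (1 = plain prior draws). Initialization does not
#'   affect the stationary distribution; oversampling just shortens burn-in.
#' @param thin Keep every `thin`-th iteration.
#'
#' @return An object of class `demcmc`: list with `theta` (array
#'   iterations x chains x parameters), `lp` (iterations x chains),
#'   `acceptance_rate`, and the settings.
#' @export
#' @examples
#' lp <- function(th) sum(dnorm(th, log = TRUE))
#' prior <- structure(list(x = list(dist = "norm", mean = 0, sd = 2,
#'                                  transform = "identity")),
#'                    class = "prior_spec")
#' fit <- demcmc_sample(lp, prior, n_chains = 8, n_iter = 200, seed = 1)
#' dim(fit$theta)
demcmc_sample <- function(log_posterior, prior = NULL, n_chains, n_iter,
                          gamma = NULL, jitter_eps = 1e-3,
                          migration_prob = 0, seed = NULL, init = NULL,
                          init_cap = 1000, init_oversample = 1, thin = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    if (is.null(prior)) abort("supply either `prior` or `init`")
    if (init_oversample > 1) {
      cand <- prior_draw(ceiling(init_oversample * n_chains), prior)
      lp_cand <- apply(cand, 1, log_posterior)
      init <- cand[order(lp_cand, decreasing = TRUE)[seq_len(n_chains)], ,
                   drop = FALSE]
    } else {
      init <- prior_draw(n_chains, prior)
    }
  }
  par_names <- colnames(init)
  d <- ncol(init)
  if (n_chains < 2 * d) {
    abort(sprintf("n_chains (%d) must be at least 2 * n_params (%d)",
                  n_chains, 2 * d), class = "ea_configuration_error")
  }
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * d)
  if (gamma == 0 && jitter_eps == 0) {
    warn("gamma = 0 and jitter_eps = 0: proposals are identical to current states")
  }
  current <- init
  lp_cur <- apply(current, 1, log_posterior)
  # re-draw chains that start at zero posterior mass
  for (i in which(!is.finite(lp_cur))) {
    tries <- 0
    while (!is.finite(lp_cur[i]) && tries < init_cap) {
      tries <- tries + 1
      if (is.null(prior)) break
      current[i, ] <- prior_draw(1, prior)
      lp_cur[i] <- log_posterior(current[i, ])
    }
    if (!is.finite(lp_cur[i])) {
      abort(paste0("could not initialize chain ", i,
                   " at finite posterior density (parameters: ",
                   paste(par_names, collapse = ", "), ")"),
            class = "ea_initialization_error")
    }
  }
  n_keep <- n_iter %/% thin
  theta <- array(NA_real_, dim = c(n_keep, n_chains, d),
                 dimnames = list(NULL, NULL, par_names))
  lp_store <- matrix(NA_real_, n_keep, n_chains)
  n_acc <- 0L
  n_prop <- 0L
  for (it in seq_len(n_iter)) {
    if (migration_prob > 0 && runif(1) < migration_prob) {
      k <- sample.int(n_chains, 1)
      ring <- sample.int(n_chains, k)
      prev <- ring[c(k, seq_len(k - 1))]
      snap <- current[prev, , drop = FALSE]
      for (j in seq_len(k)) {
        ci <- ring[j]
        prop <- snap[j, ] + runif(d, -jitter_eps, jitter_eps)
        lp_new <- log_posterior(prop)
        n_prop <- n_prop + 1L
        if (is.finite(lp_new) && log(runif(1)) < lp_new - lp_cur[ci]) {
          current[ci, ] <- prop
          lp_cur[ci] <- lp_new
          n_acc <- n_acc + 1L
        }
      }
    } else {
      for (ci in seq_len(n_chains)) {
        ab <- sample.int(n_chains, 2)
        while (ab[1] == ci || ab[2] == ci) ab <- sample.int(n_chains, 2)
        prop <- current[ci, ] +
          gamma * (current[ab[1], ] - current[ab[2], ]) +
          runif(d, -jitter_eps, jitter_eps)
        lp_new <- log_posterior(prop)
        n_prop <- n_prop + 1L
        if (is.finite(lp_new) && log(runif(1)) < lp_new - lp_cur[ci]) {
          current[ci, ] <- prop
          lp_cur[ci] <- lp_new
          n_acc <- n_acc + 1L
        }
      }
    }
    if (it %% thin == 0) {
      theta[it %/% thin, , ] <- current
      lp_store[it %/% thin, ] <- lp_cur
    }
  }
  structure(
    list(theta = theta, lp = lp_store,
         acceptance_rate = if (n_prop > 0) n_acc / n_prop else NA_real_,
         n_chains = n_chains, n_iter = n_iter, gamma = gamma,
         jitter_eps = jitter_eps, migration_prob = migration_prob,
         final = current, final_lp = lp_cur),
    class = "demcmc"
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Univariate R-hat from between- and within-chain variances:
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)` with `B = n * var(chain means)`
#' and `W = mean(chain variances)`, computed on the samples as given (the
#' fitting routine passes the second halves of its chains). Zero
#' within-chain variance is undefined and returns `NA` (treated as
#' non-converged).
#'
#' @param samples Matrix of samples, iterations x chains (>= 2 chains).
#' @return Scalar R-hat estimate.
#' @export
#' @examples
#' gelman_rubin(cbind(c(1, 2, 3), c(1, 2, 3)))  # sqrt(2/3)
gelman_rubin <- function(samples) {
  samples <- as.matrix(samples)
  m <- ncol(samples)
  n <- nrow(samples)
  if (m < 2) abort("at least 2 chains required", class = "ea_configuration_error")
  chain_means <- colMeans(samples)
  W <- mean(apply(samples, 2, var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * var(chain_means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' R-hat per parameter from a `demcmc` run
#'
#' Computed on the second half of each chain.
#'
#' @param samples A `demcmc` object or an iterations x chains x parameters
#'   array.
#' @return Named numeric vector of R-hat values.
#' @export
rhat <- function(samples) {
  theta <- if (inherits(samples, "demcmc")) samples$theta else samples
  n <- dim(theta)[1]
  half <- theta[(n %/% 2 + 1):n, , , drop = FALSE]
  vapply(seq_len(dim(theta)[3]), function(k) gelman_rubin(half[, , k]),
         numeric(1)) |>
    setNames(dimnames(theta)[[3]])
}
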