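# Monte-Carlo oracle: closed-form finishing-time simulation of one
# accumulator (start ~ U(0, A), rate ~ N(v, sv), threshold b)
simulate_node <- function(n, b, A, v, sv) {
  start <- runif(n, 0, A)
  rate <- rnorm(n, v, sv)
  ifelse(rate > 0, (b - start) / rate, Inf)
}

test_that("node cdf matches the A = 0 limit and its known terminal mass", {
  # with A = 0 the finish time is b / rate, so P(finish) = P(rate > 0)
  expect_equal(lba_node_cdf(Inf, b = 1, A = 0, v = 1, sv = 1), pnorm(1))
  expect_equal(lba_node_cdf(1e9, b = 1, A = 0, v = 1, sv = 1), pnorm(1),
               tolerance = 1e-6)
  # A = 0 handled by the limit branch, not division by zero
  expect_true(is.finite(lba_node_density(0.5, b = 1, A = 0, v = 1, sv = 1)))
  expect_error(lba_node_density(0.5, 1, 0.2, 1, sv = 0),
               class = "ea_parameter_error")
})

test_that("node cdf matches the empirical CDF of simulated finish times", {
  set.seed(101)
  b <- 1.2; A <- 0.5; v <- 1.5; sv <- 1
  ft <- simulate_node(1e6, b, A, v, sv)
  ts <- seq(0.05, 6, by = 0.05)
  emp <- vapply(ts, function(t) mean(ft <= t), numeric(1))
  expect_lt(max(abs(emp - lba_node_cdf(ts, b, A, v, sv))), 0.005)
})

test_that("node density integrates to the cdf", {
  b <- 0.9; A <- 0.4; v <- 1.2; sv <- 0.8
  int <- integrate(function(t) lba_node_density(t, b, A, v, sv), 0, 50,
                   abs.tol = 1e-9)$value
  expect_equal(int, lba_node_cdf(50, b, A, v, sv), tolerance = 1e-6)
})

test_that("defective densities and never-finish mass close to total probability 1", {
  p <- nback_lba_params()
  for (cc in c("target", "lure", "novel")) {
    mass <- sum(vapply(task_design("nback2")$responses, function(r) {
      integrate(function(t) lba_defective_density(t, r, p, cc), 0, Inf,
                abs.tol = 1e-9)$value
    }, numeric(1)))
    expect_equal(mass + lba_no_finish_prob(p, cc), 1, tolerance = 1e-4)
  }
})

test_that("identical accumulators split the finishing mass symmetrically", {
  p <- lba_params("nback2", v_match = 1.2, v_mismatch = 1.2, B = 0.8, A = 0.3,
                  sv_mismatch = 1, t0 = 0.2, p_gf = 0)
  masses <- vapply(task_design("nback2")$responses, function(r) {
    integrate(function(t) lba_defective_density(t, r, p, "target"), 0, Inf,
              abs.tol = 1e-9)$value
  }, numeric(1))
  expect_equal(masses[[1]], masses[[2]], tolerance = 1e-6)
  expect_equal(sum(masses), 1 - lba_no_finish_prob(p, "target"),
               tolerance = 1e-6)
})

test_that("win probabilities and omission rates match a 10^6-trial simulation", {
  p <- nback_lba_params()
  sim <- lba_simulate(p, c(target = 4e5, lure = 3e5, novel = 3e5), seed = 77)
  for (cc in c("target", "lure")) {
    sub <- sim[sim$condition == cc, ]
    emp_om <- mean(sub$response == omission_label())
    expect_lt(abs(emp_om - lba_omission_prob(p, cc, 2)), 0.005)
    # win probability among recorded responses vs analytic defective mass
    # restricted to the response window
    match_resp <- matching_response(cc, "nback2")
    ana_match <- integrate(function(t)
      lba_defective_density(t, match_resp, p, cc), 0, 2 - p$t0,
      abs.tol = 1e-9)$value * (1 - p$p_gf)
    expect_lt(abs(mean(sub$response == match_resp) - ana_match), 0.005)
  }
})

test_that("omission probability obeys the go-failure mixture algebra", {
  # boundary: certain go failure
  p1 <- nback_lba_params(p_gf = 1)
  expect_equal(lba_omission_prob(p1, "target", 2), 1)
  # mixture: p_gf + (1 - p_gf) * P(late or never)
  p <- nback_lba_params(p_gf = 0.1)
  p0 <- nback_lba_params(p_gf = 0)
  tail_prob <- lba_omission_prob(p0, "target", 2)
  expect_equal(lba_omission_prob(p, "target", 2),
               0.1 + 0.9 * tail_prob, tolerance = 1e-12)
  # degenerate window: warns and returns the full mixture mass
  expect_warning(out <- lba_omission_prob(p, "target", p$t0 / 2))
  expect_equal(out, 1)
})

test_that("total log-likelihood equals the brute-force per-trial composition", {
  p <- nback_lba_params()
  trials <- lba_simulate(p, c(target = 40, lure = 40, novel = 40), seed = 5)
  ll <- lba_loglik(trials, p)
  oracle <- sum(vapply(seq_len(nrow(trials)), function(i) {
    if (trials$response[i] == omission_label()) {
      log(lba_omission_prob(p, trials$condition[i], 2))
    } else {
      log((1 - p$p_gf) *
            lba_defective_density(trials$rt[i] - p$t0, trials$response[i],
                                  p, trials$condition[i]))
    }
  }, numeric(1)))
  expect_equal(ll, oracle, tolerance = 1e-10)
  # empty dataset
  expect_identical(lba_loglik(trials[0, ], p), 0)
  # single omitted trial
  om <- trials[trials$response == omission_label(), ][1, ]
  expect_equal(lba_loglik(om, p),
               log(lba_omission_prob(p, om$condition, 2)))
  # condition coverage errors
  expect_error(lba_loglik(dplyr::mutate(trials, condition = "many_easy"), p),
               class = "ea_configuration_error")
})

test_that("likelihood at generating parameters beats +/-50% rate perturbations", {
  p <- nback_lba_params(p_gf = 0.02)
  wins_hi <- wins_lo <- logical(20)
  for (r in 1:20) {
    trials <- lba_simulate(p, c(target = 120, lure = 120, novel = 120),
                           seed = 400 + r)
    ll0 <- lba_loglik(trials, p)
    p_hi <- nback_lba_params(p_gf = 0.02, v_match = p$v_match * 1.5)
    p_lo <- nback_lba_params(p_gf = 0.02, v_match = p$v_match * 0.5)
    wins_hi[r] <- ll0 > lba_loglik(trials, p_hi)
    wins_lo[r] <- ll0 > lba_loglik(trials, p_lo)
  }
  expect_gt(mean(wins_hi), 0.5)
  expect_gt(mean(wins_lo), 0.5)
})

test_that("joint rescaling of rates and evidence units preserves win probabilities", {
  p <- nback_lba_params(p_gf = 0)
  k <- 1.7
  p_scaled <- lba_params(
    "nback2", v_match = p$v_match * k, v_mismatch = p$v_mismatch * k,
    B = p$B * k, A = p$A * k, sv_mismatch = p$sv_mismatch * k,
    t0 = p$t0, p_gf = 0, sv_match = p$sv_match * k
  )
  for (cc in c("target", "lure")) {
    w1 <- integrate(function(t)
      lba_defective_density(t, matching_response(cc, "nback2"), p, cc),
      0, Inf, abs.tol = 1e-9)$value
    w2 <- integrate(function(t)
      lba_defective_density(t, matching_response(cc, "nback2"), p_scaled, cc),
      0, Inf, abs.tol = 1e-9)$value
    expect_equal(w1, w2, tolerance = 1e-6)
    # finish times (b - start)/rate are unchanged when all evidence units
    # scale together, so the whole finishing-time distribution is invariant
    acc <- evaccum:::.lba_accumulators(p, cc)
    acc2 <- evaccum:::.lba_accumulators(p_scaled, cc)
    ts <- c(0.3, 0.6, 1.2)
    expect_equal(lba_node_cdf(ts, acc$b[1], p$A, acc$v[1], acc$sv[1]),
                 lba_node_cdf(ts, acc2$b[1], p_scaled$A, acc2$v[1],
                              acc2$sv[1]),
                 tolerance = 1e-10)
  }
})

test_that("simulator is deterministic under seed and respects the window", {
  p <- nback_lba_params()
  s1 <- lba_simulate(p, c(target = 50, lure = 50, novel = 50), seed = 9)
  s2 <- lba_simulate(p, c(target = 50, lure = 50, novel = 50), seed = 9)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(is.na(s1$rt) | s1$rt < 2))
  expect_true(all(is.na(s1$rt) | s1$rt > p$t0))
})

test_that("simulated RT quantiles match inversion of the analytic defective CDF", {
  p <- nback_lba_params(p_gf = 0)
  cc <- "target"
  r <- matching_response(cc, "nback2")
  sim <- lba_simulate(p, c(target = 1e5, lure = 1, novel = 1), seed = 31,
                      window = 1e6)
  rts <- sim$rt[sim$condition == cc & sim$response == r]
  mass <- integrate(function(t) lba_defective_density(t, r, p, cc), 0, Inf,
                    abs.tol = 1e-10)$value
  cdf_cond <- function(t) {
    integrate(function(s) lba_defective_density(s, r, p, cc), 0, t,
              abs.tol = 1e-10)$value / mass
  }
  for (q in c(.1, .3, .5, .7, .9)) {
    t_ana <- stats::uniroot(function(t) cdf_cond(t) - q, c(0.05, 20),
                            tol = 1e-6)$root + p$t0
    expect_equal(unname(quantile(rts, q)), t_ana, tolerance = 0.01)
  }
})

test_that("parameter vectors round-trip through the flat serialization", {
  p <- nback_lba_params()
  expect_equal(lba_unflatten(lba_flatten(p), "nback2"), p)
  pn <- lba_params("numerosity", v_match = 2.4, v_mismatch = 1.1,
                   B = c(many = 0.8, few = 1.1), A = 0.3)
  expect_equal(lba_unflatten(lba_flatten(pn), "numerosity"), pn)
  expect_named(lba_flatten(pn),
               c(paste0("v_", task_design("numerosity")$conditions, "_match"),
                 paste0("v_", task_design("numerosity")$conditions, "_mismatch"),
                 "B_many", "B_few", "A", "sv_mismatch", "t0", "p_gf"))
})
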