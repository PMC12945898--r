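test_that("zero-drift symmetric diffusion splits absorption mass in half", {
  expect_equal(ddm_absorption_prob(1, 0.5, 0, "upper"), 0.5)
  expect_equal(ddm_absorption_prob(1, 0.5, 0, "lower"), 0.5)
  int_up <- integrate(function(t) wiener_fpt_density(t, 1, 0.5, 0, "upper"),
                      0, Inf, abs.tol = 1e-12)$value
  expect_equal(int_up, 0.5, tolerance = 1e-8)
})

test_that("integrated defective density matches the closed-form absorption probability", {
  grid <- expand.grid(a = c(0.8, 1.4), w = c(0.3, 0.5, 0.7),
                      v = c(-1, 0.5, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    for (b in c("upper", "lower")) {
      int <- integrate(function(t) wiener_fpt_density(t, g$a, g$w, g$v, b),
                       0, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
      expect_equal(int, ddm_absorption_prob(g$a, g$w, g$v, b),
                   tolerance = 1e-6)
    }
  }
})

test_that("the two boundary masses integrate to one", {
  for (v in c(-0.5, 1.5)) {
    tot <- integrate(function(t) wiener_fpt_density(t, 1.2, 0.4, v, "upper"),
                     0, Inf, abs.tol = 1e-10)$value +
      integrate(function(t) wiener_fpt_density(t, 1.2, 0.4, v, "lower"),
                0, Inf, abs.tol = 1e-10)$value
    expect_equal(tot, 1, tolerance = 1e-4)
  }
})

test_that("small-time and large-time series agree across the switching region", {
  u <- seq(0.05, 2.5, by = 0.05)
  for (w in c(0.3, 0.5, 0.7)) {
    for (b in c("upper", "lower")) {
      s <- wiener_fpt_density(u, 1.3, w, 1.1, b, method = "small")
      l <- wiener_fpt_density(u, 1.3, w, 1.1, b, method = "large")
      expect_lt(max(abs(s - l)), 1e-8)
    }
  }
})

test_that("defective CDF agrees with quadrature of the density", {
  for (t in c(0.2, 0.6, 1.5, 4)) {
    int <- integrate(function(s) wiener_fpt_density(s, 1.4, 0.4, 1.2, "upper"),
                     0, t, abs.tol = 1e-12)$value
    expect_equal(wiener_fpt_cdf(t, 1.4, 0.4, 1.2, "upper"), int,
                 tolerance = 1e-7)
  }
})

test_that("upper-boundary probability is nondecreasing in drift", {
  vs <- seq(-2, 3, by = 0.25)
  ps <- vapply(vs, function(v) ddm_absorption_prob(1.1, 0.45, v, "upper"),
               numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("first-passage distribution matches fine-grained Euler paths (sup-CDF)", {
  # unit-scale version of the path-oracle check; the acceptance suite runs
  # the full 10^6-path comparison
  a <- 1; z_rel <- 0.5; v <- 2
  sim <- evaccum:::ddm_euler_cpp(3e5L, v, a, z_rel * a, 1e-4, 10, 424242)
  ts <- seq(0.02, 3, by = 0.02)
  for (b in c(1, 0)) {
    ana <- wiener_fpt_cdf(ts, a, z_rel, v, if (b == 1) "upper" else "lower")
    emp <- vapply(ts, function(t) mean(sim$time <= t & sim$boundary == b),
                  numeric(1))
    expect_lt(max(abs(ana - emp)), 0.01)
  }
})

test_that("Euler accuracy matches the closed-form absorption probability", {
  sim <- ddm_euler_paths(3e5, v = 1, a = 1.4, z_rel = 0.5, dt = 1e-4, seed = 7)
  expect_lt(abs(mean(sim$boundary == "upper", na.rm = TRUE) -
                  ddm_absorption_prob(1.4, 0.5, 1, "upper")), 0.005)
})

test_that("simulator: determinism, symmetry, and cap bookkeeping", {
  p <- nback_ddm_params()
  s1 <- ddm_simulate(p, c(target = 60, lure = 60, novel = 60), seed = 3)
  s2 <- ddm_simulate(p, c(target = 60, lure = 60, novel = 60), seed = 3)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_true(attr(s1, "capped") >= 0)
  # v = 0, z_rel = 0.5: upper-boundary proportion 0.5 within MC error
  p0 <- ddm_params("nback2", v = 0, a = 1.2, z_rel = 0.5, Ter = 0.2,
                   st0 = 0, p_gf = 0)
  sim <- evaccum:::ddm_euler_cpp(1e5L, 0, 1.2, 0.6, 1e-3, 10, 99)
  expect_lt(abs(mean(sim$boundary == 1) - 0.5), 0.01)
})

test_that("st0 = 0 reduces the trial density to the plain shifted density", {
  p0 <- ddm_params("nback2", v = 1.5, a = 1.2, z_rel = 0.5, Ter = 0.3,
                   st0 = 0, p_gf = 0)
  expect_equal(ddm_trial_density(0.8, "target", p0, "target"),
               wiener_fpt_density(0.5, 1.2, 0.5, 1.5, "upper"))
})

test_that("nondecision quadrature matches a dense trapezoid over t0", {
  p <- ddm_params("nback2", v = 1.5, a = 1.2, z_rel = 0.5, Ter = 0.3,
                  st0 = 0.2, p_gf = 0)
  t0g <- seq(0.2, 0.4, length.out = 10001)
  for (rt in c(0.55, 0.8, 1.4)) {
    dense <- mean(wiener_fpt_density(rt - t0g, 1.2, 0.5, 1.5, "upper"))
    expect_equal(ddm_trial_density(rt, "target", p, "target"), dense,
                 tolerance = 1e-5)
  }
})

test_that("omission probability vanishes as the window grows without go failure", {
  p <- nback_ddm_params(p_gf = 0)
  expect_lt(ddm_trial_density(NA, omission_label(), p, "target",
                              window = 50), 1e-6)
  p1 <- nback_ddm_params(p_gf = 1)
  expect_equal(ddm_trial_density(NA, omission_label(), p1, "target"), 1)
})

test_that("DDM log-likelihood equals the brute-force per-trial composition", {
  p <- nback_ddm_params()
  trials <- ddm_simulate(p, c(target = 40, lure = 40, novel = 40), seed = 6)
  ll <- ddm_loglik(trials, p)
  oracle <- sum(log(mapply(function(rt, resp, cond) {
    ddm_trial_density(rt, resp, p, cond)
  }, trials$rt, trials$response, trials$condition)))
  expect_equal(ll, oracle, tolerance = 1e-8)
  expect_identical(ddm_loglik(trials[0, ], p), 0)
  # single correct trial with st0 = 0
  p0 <- nback_ddm_params(st0 = 0)
  tr1 <- trials[which(trials$response != omission_label())[1], ]
  expect_equal(ddm_loglik(tr1, p0),
               log((1 - p0$p_gf) *
                     wiener_fpt_density(
                       tr1$rt - p0$Ter, p0$a, p0$z_rel, p0$v[[tr1$condition]],
                       if (tr1$response == matching_response(tr1$condition, "nback2"))
                         "upper" else "lower")))
})

test_that("DDM parameters round-trip through the flat serialization", {
  p <- nback_ddm_params()
  expect_equal(ddm_unflatten(ddm_flatten(p), "nback2"), p)
  expect_error(ddm_params("nback2", v = 1, Ter = 0.1, st0 = 0.5),
               class = "ea_parameter_error")
})
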