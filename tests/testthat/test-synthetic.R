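test_that("latent EEA/SEA map to rates by the exact inverse of the definitions", {
  spec <- population_spec(n_subjects = 1, trials_per_condition = 5)
  # no offsets: v_match = SEA + EEA/2, v_mismatch = SEA - EEA/2
  spec$offsets_match[] <- 0
  spec$offsets_mismatch[] <- 0
  pop <- generate_population(spec, seed = 3)
  p <- pop$params[[1]]
  expect_equal(unname(p$v_match),
               rep(pop$SEA_true + pop$EEA_true / 2, 3))
  expect_equal(unname(p$v_mismatch),
               rep(pop$SEA_true - pop$EEA_true / 2, 3))
  # derived measures recover the latents exactly (round trip)
  expect_equal(compute_eea(p), pop$EEA_true)
  expect_equal(compute_sea(p), pop$SEA_true)
})

test_that("zero-sum condition offsets leave the derived measures at their latents", {
  spec <- population_spec(n_subjects = 3, trials_per_condition = 5)
  pop <- generate_population(spec, seed = 4)
  for (i in 1:3) {
    expect_equal(compute_eea(pop$params[[i]]), pop$EEA_true[i])
    expect_equal(compute_sea(pop$params[[i]]), pop$SEA_true[i])
  }
})

test_that("independent latent traits stay uncorrelated in large samples", {
  spec <- population_spec(n_subjects = 1e4, trials_per_condition = 1)
  pop <- generate_population(spec, seed = 5)
  expect_lt(abs(cor(pop$EEA_true, pop$SEA_true)), 0.05)
  # non-positive-definite correlation is a spec error
  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 1.2
  expect_error(population_spec(latent_cor = bad), class = "ea_spec_error")
})

test_that("cohort generation is reproducible under seed", {
  spec <- population_spec(n_subjects = 6, trials_per_condition = 10)
  a <- generate_population(spec, seed = 11)
  b <- generate_population(spec, seed = 11)
  expect_equal(dplyr::select(a, !params), dplyr::select(b, !params))
  ta <- generate_trials(a, spec, seed = 12)
  tb <- generate_trials(b, spec, seed = 12)
  expect_equal(as.data.frame(ta), as.data.frame(tb))
  ca <- generate_criteria(a, spec, seed = 13)
  cb <- generate_criteria(b, spec, seed = 13)
  expect_equal(ca, cb)
})

test_that("a generous window and no go failure produce almost no omissions", {
  spec <- population_spec(n_subjects = 5, trials_per_condition = 100,
                          window = 6)
  spec$latent_mean[["p_gf_logit"]] <- qlogis(1e-6)
  spec$latent_sd[["p_gf_logit"]] <- 0
  pop <- generate_population(spec, seed = 6)
  trials <- generate_trials(pop, spec, seed = 7)
  expect_lt(mean(trials$response == omission_label()), 0.01)
})

test_that("trial tables carry the nesting factors and canonical schema", {
  spec <- population_spec(n_subjects = 4, trials_per_condition = 8)
  study <- simulate_study(spec)
  expect_true(all(c("subject", "task", "condition", "response", "rt",
                    "family", "site") %in% names(study$trials)))
  expect_equal(dplyr::n_distinct(study$trials$subject), 4)
  expect_equal(nrow(study$trials), 4 * 8 * 3)
  # subjects nested in families nested in sites
  fam_site <- dplyr::distinct(study$population, family, site)
  expect_equal(nrow(fam_site), dplyr::n_distinct(study$population$family))
})

test_that("criterion scores load on EEA with the designed variance share", {
  spec <- population_spec(n_subjects = 2000, trials_per_condition = 1,
                          criterion_loadings = c(crit = 0.45))
  pop <- generate_population(spec, seed = 8)
  crit <- generate_criteria(pop, spec, seed = 9)
  r2 <- pearson_r(crit$crit, pop$EEA_true)$r^2
  expect_gt(r2, 0.15)
  expect_lt(r2, 0.25)
  # null loading gives a null correlation
  spec0 <- population_spec(n_subjects = 2000, trials_per_condition = 1,
                           criterion_loadings = c(crit = 0))
  pop0 <- generate_population(spec0, seed = 10)
  crit0 <- generate_criteria(pop0, spec0, seed = 11)
  expect_lt(abs(pearson_r(crit0$crit, pop0$EEA_true)$r), 0.05)
  # SEA stays out of the criteria by construction
  expect_lt(abs(pearson_r(crit$crit, pop$SEA_true)$r), 0.05)
})

test_that("raising SEA at fixed EEA speeds responses without moving accuracy", {
  eea <- 1.5
  seas <- seq(1.4, 2.6, by = 0.3)
  stats <- purrr::map(seas, function(sea) {
    p <- lba_params("nback2", v_match = sea + eea / 2,
                    v_mismatch = sea - eea / 2, B = 1, A = 0.5,
                    sv_mismatch = 1, t0 = 0.3, p_gf = 0)
    sim <- lba_simulate(p, c(target = 20000, lure = 1, novel = 1),
                        seed = round(100 + sea * 10))
    sub <- mark_correct(sim[sim$condition == "target" &
                              sim$response != omission_label(), ])
    tibble::tibble(sea = sea, mean_rt = mean(sub$rt),
                   accuracy = mean(sub$correct))
  }) |> dplyr::bind_rows()
  # mean RT decreases monotonically in SEA
  expect_true(all(diff(stats$mean_rt) < 0))
  # accuracy moves by less than 2 percentage points across the sweep
  expect_lt(diff(range(stats$accuracy)), 0.02)
})

test_that("raising EEA at fixed SEA raises accuracy monotonically", {
  sea <- 2
  eeas <- seq(0.6, 2.2, by = 0.4)
  acc <- purrr::map_dbl(eeas, function(eea) {
    p <- lba_params("nback2", v_match = sea + eea / 2,
                    v_mismatch = sea - eea / 2, B = 1, A = 0.5,
                    sv_mismatch = 1, t0 = 0.3, p_gf = 0)
    sim <- lba_simulate(p, c(target = 20000, lure = 1, novel = 1),
                        seed = round(200 + eea * 10))
    sub <- mark_correct(sim[sim$condition == "target" &
                              sim$response != omission_label(), ])
    mean(sub$correct)
  })
  expect_true(all(diff(acc) > 0))
})
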