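test_that("round-trip write-then-read reproduces trials and parses omissions", {
  trials <- toy_trials()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(trials))
  expect_equal(sum(back$response == omission_label()), 1)
  expect_equal(nrow(back), 3)
})

test_that("schema mapping renames columns and missing columns are schema errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    subj = "a", task = "nback2", condition = "target",
    resp = "target", resp_time = 0.5
  ), path)
  back <- read_trials(path, schema = c(subject = "subj", response = "resp",
                                       rt = "resp_time"))
  expect_equal(back$subject, "a")
  expect_error(read_trials(path), class = "ea_schema_error")
})

test_that("validation errors name the offending rows", {
  bad_rt <- tibble::tibble(subject = "a", task = "nback2",
                           condition = c("target", "lure"),
                           response = c("target", "nontarget"),
                           rt = c(0.5, -0.5))
  expect_error(validate_trials(bad_rt), "row.*2", class = "ea_validation_error")
  ms <- tibble::tibble(subject = "a", task = "numerosity",
                       condition = "many_easy", response = "many", rt = 650)
  expect_error(validate_trials(ms), "millisecond", class = "ea_validation_error")
  wrong_cond <- tibble::tibble(subject = "a", task = "numerosity",
                               condition = "target", response = "many", rt = 0.5)
  expect_error(validate_trials(wrong_cond), class = "ea_validation_error")
})

test_that("QC applies the 55% accuracy floor and 25% omission ceiling", {
  set.seed(1)
  trials <- dplyr::bind_rows(
    qc_profile_trials("low_acc", 54, 46, 0),    # accuracy .54 -> out
    qc_profile_trials("high_om", 56, 14, 30),   # omission .30 -> out
    qc_profile_trials("good", 80, 15, 5),       # retained
    qc_profile_trials("silent", 0, 0, 10)       # no responses -> out
  )
  qc <- apply_qc(trials)
  dec <- qc$decisions
  expect_equal(dec$retained[match(c("low_acc", "high_om", "good", "silent"),
                                  dec$subject)],
               c(FALSE, FALSE, TRUE, FALSE))
  expect_match(dec$reason[dec$subject == "low_acc"], "accuracy")
  expect_match(dec$reason[dec$subject == "high_om"], "omission")
  expect_match(dec$reason[dec$subject == "silent"], "no responses")
  # retained and excluded partition the input
  expect_equal(nrow(qc$retained) + nrow(qc$excluded), nrow(trials))
  expect_equal(nrow(dplyr::semi_join(qc$retained, qc$excluded,
                                     by = c("subject", "task"))), 0)
  # idempotent on the retained set
  qc2 <- apply_qc(qc$retained)
  expect_true(all(qc2$decisions$retained))
  expect_equal(nrow(qc2$retained), nrow(qc$retained))
})

test_that("boundary QC cases sit on the right side of the thresholds", {
  set.seed(2)
  # exactly at floor/ceiling is retained (rules are strict inequalities)
  at_floor <- qc_profile_trials("at_floor", 55, 45, 0)
  at_ceiling <- qc_profile_trials("at_ceiling", 75, 0, 25)
  dec <- apply_qc(dplyr::bind_rows(at_floor, at_ceiling))$decisions
  expect_true(all(dec$retained))
})

test_that("summaries: proportions include omissions and sum to one", {
  set.seed(3)
  trials <- lba_simulate(nback_lba_params(), c(target = 80, lure = 80, novel = 80),
                         seed = 11)
  smry <- summarize_trials(trials)
  sums <- smry |>
    dplyr::summarise(total = sum(prop), .by = condition)
  expect_equal(sums$total, rep(1, nrow(sums)))
})

test_that("RT quantiles use linear interpolation between order statistics", {
  trials <- validate_trials(tibble::tibble(
    subject = "s", task = "numerosity", condition = "many_easy",
    response = "many", rt = (1:10) / 10
  ))
  smry <- summarize_trials(trials)
  row <- smry[smry$response == "many", ]
  # oracle: sort-and-interpolate on 1..10 scaled by 1/10
  expect_equal(row$q50, 0.55)
  expect_equal(row$q10, quantile((1:10) / 10, 0.1, type = 7, names = FALSE))
  # random-sample agreement with the sort-and-interpolate oracle
  set.seed(4)
  x <- runif(37, 0.2, 2.5)
  tr2 <- validate_trials(tibble::tibble(
    subject = "s", task = "numerosity", condition = "few_hard",
    response = "few", rt = x
  ))
  s2 <- summarize_trials(tr2)
  expect_equal(unlist(s2[s2$response == "few", c("q10", "q30", "q50", "q70", "q90")],
                      use.names = FALSE),
               quantile(x, c(.1, .3, .5, .7, .9), type = 7, names = FALSE))
})

test_that("degenerate cells: all-omitted condition and empty cells are flagged", {
  trials <- validate_trials(tibble::tibble(
    subject = "s", task = "nback2",
    condition = rep("lure", 4),
    response = rep("omitted", 4),
    rt = rep(NA_real_, 4)
  ))
  smry <- summarize_trials(trials)
  om <- smry[smry$response == omission_label(), ]
  expect_equal(om$prop, 1)
  expect_true(all(is.na(om$q50)))
  # response cells exist with zero counts, flagged
  resp_cells <- smry[smry$response != omission_label(), ]
  expect_true(all(resp_cells$n == 0))
  expect_true(all(resp_cells$flagged))
})
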