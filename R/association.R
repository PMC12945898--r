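#' Pearson correlation with sample size
#'
#' Product-moment correlation of two finite vectors (complete cases only).
#' Zero variance in either variable leaves the estimate undefined (`NA`).
#'
#' @param x,y Numeric vectors of equal length, n >= 3 complete pairs.
#' @return A one-row tibble with `r` and `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs",
                           class = "ea_configuration_error")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble(r = NA_real_, n = length(x)))
  }
  tibble(r = stats::cor(x, y), n = length(x))
}

#' Random-intercept mixed model
#'
#' REML fit of `outcome ~ predictors + (1 | g)` for each grouping factor,
#' via `lme4::lmer`. Grouping factors with fewer than two observed levels
#' are dropped; with no usable grouping factor the model degenerates to
#' ordinary least squares (`lm`), whose coefficients it then matches.
#' Singular fits (a variance component estimated at zero) are flagged, not
#' errors.
#'
#' @param data Data frame with one row per subject.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of fixed-effect column names.
#' @param groups Character vector of grouping-factor column names (possibly
#'   empty).
#' @return An object of class `ea_mixed`: the fitted model plus metadata
#'   (`singular`, `groups_used`, `marginal_r2`).
#' @export
fit_random_intercept_model <- function(data, outcome, predictors,
                                       groups = character()) {
  usable <- groups[vapply(groups, function(g) {
    length(unique(data[[g]])) >= 2
  }, logical(1))]
  fixed <- paste(c("1", predictors), collapse = " + ")
  if (length(usable) > 0) {
    form <- stats::as.formula(paste0(
      outcome, " ~ ", fixed, " + ",
      paste(sprintf("(1 | %s)", usable), collapse = " + ")
    ))
    fit <- lme4::lmer(form, data = data, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
    singular <- lme4::isSingular(fit)
  } else {
    form <- stats::as.formula(paste0(outcome, " ~ ", fixed))
    fit <- lm(form, data = data)
    singular <- FALSE
  }
  structure(
    list(fit = fit, outcome = outcome, predictors = predictors,
         groups_used = usable, singular = singular, data = data,
         marginal_r2 = marginal_r2(fit)),
    class = "ea_mixed"
  )
}

#' Marginal R-squared of a (mixed) linear model
#'
#' Fixed-effects variance over total variance: `var(X beta-hat) /
#' (var(X beta-hat) + sum of random-intercept variances + residual
#' variance)`. For an `lm` the random-effect term is absent.
#'
#' @param fit A fitted `lmerMod` or `lm`, or an `ea_mixed` wrapper.
#' @return Scalar marginal R-squared in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  if (inherits(fit, "ea_mixed")) fit <- fit$fit
  if (inherits(fit, "merMod")) {
    fixed_pred <- as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit))
    var_fixed <- var(fixed_pred)
    vc <- lme4::VarCorr(fit)
    var_random <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
    var_resid <- sigma(fit)^2
  } else {
    fixed_pred <- predict(fit)
    var_fixed <- var(fixed_pred)
    var_random <- 0
    var_resid <- sigma(fit)^2
  }
  var_fixed / (var_fixed + var_random + var_resid)
}

#' @export
print.ea_mixed <- function(x, ...) {
  cat(sprintf("Mixed model: %s ~ %s%s\n", x$outcome,
              paste(x$predictors, collapse = " + "),
              if (length(x$groups_used) > 0)
                paste0(" + (1 | ", paste(x$groups_used, collapse = ") + (1 | "), ")")
              else " (OLS: no usable grouping factor)"))
  cat(sprintf("Marginal R2 = %.4f%s\n", x$marginal_r2,
              if (x$singular) " [singular fit: a variance component at 0]" else ""))
  invisible(x)
}

#' Tidy fixed effects of a mixed model
#' @param x An `ea_mixed` object.
#' @param ... Unused.
#' @return Tibble of fixed-effect terms and estimates.
#' @export
tidy.ea_mixed <- function(x, ...) {
  co <- if (inherits(x$fit, "merMod")) lme4::fixef(x$fit) else coef(x$fit)
  tibble(term = names(co), estimate = unname(co))
}

#' @export
glance.ea_mixed <- function(x, ...) {
  tibble(marginal_r2 = x$marginal_r2, singular = x$singular,
         n = nrow(x$data), groups = paste(x$groups_used, collapse = ","))
}

#' Semipartial (part) R-squared with bootstrap interval
#'
#' Unique variance explained by a predictor set: the marginal R-squared of
#' the full model minus that of the model with the set removed, floored at
#' zero (refit noise can produce tiny negative differences, which are
#' flagged). The percentile confidence interval resamples top-level groups
#' (the first grouping factor, falling back to subjects when there is none)
#' to respect the nesting structure; set `resample = "subjects"` to resample
#' rows instead.
#'
#' @param data Data frame with one row per subject.
#' @param outcome Outcome column name.
#' @param predictors All fixed-effect predictors of the full model.
#' @param part Subset of `predictors` whose unique contribution is wanted.
#' @param groups Grouping-factor column names for random intercepts.
#' @param n_boot Bootstrap replicates (default 1000); 0 skips the interval.
#' @param seed Integer seed for the bootstrap.
#' @param resample `"groups"` (default) or `"subjects"`.
#' @return A one-row tibble: `part_r2`, `conf.low`, `conf.high`,
#'   `full_r2`, `reduced_r2`, `floored`.
#' @export
part_r2 <- function(data, outcome, predictors, part, groups = character(),
                    n_boot = 1000, seed = NULL, resample = c("groups", "subjects")) {
  resample <- match.arg(resample)
  if (!all(part %in% predictors)) {
    abort("`part` must be a subset of `predictors`",
          class = "ea_configuration_error")
  }
  point <- .part_r2_once(data, outcome, predictors, part, groups)
  lo <- hi <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    unit <- if (resample == "groups" && length(groups) > 0) groups[1] else NULL
    stats_boot <- vapply(seq_len(n_boot), function(b) {
      dat_b <- .resample_data(data, unit)
      # resampled designs can be collinear or singular; such replicates are
      # dropped (errors) or fitted as lme4 reports (messages silenced)
      suppressMessages(tryCatch(
        .part_r2_once(dat_b, outcome, predictors, part, groups)$part_r2,
        error = function(e) NA_real_
      ))
    }, numeric(1))
    qs <- quantile(stats_boot, c(0.025, 0.975), na.rm = TRUE)
    lo <- qs[[1]]
    hi <- qs[[2]]
  }
  tibble(part_r2 = point$part_r2, conf.low = lo, conf.high = hi,
         full_r2 = point$full_r2, reduced_r2 = point$reduced_r2,
         floored = point$floored)
}

.part_r2_once <- function(data, outcome, predictors, part, groups) {
  full <- fit_random_intercept_model(data, outcome, predictors, groups)
  reduced_preds <- setdiff(predictors, part)
  reduced <- fit_random_intercept_model(data, outcome, reduced_preds, groups)
  diff <- full$marginal_r2 - reduced$marginal_r2
  list(part_r2 = max(0, diff), full_r2 = full$marginal_r2,
       reduced_r2 = reduced$marginal_r2, floored = diff < 0)
}

.resample_data <- function(data, unit) {
  if (is.null(unit)) {
    data[sample.int(nrow(data), nrow(data), replace = TRUE), , drop = FALSE]
  } else {
    levels <- unique(data[[unit]])
    picked <- sample(levels, length(levels), replace = TRUE)
    purrr::imap(picked, function(g, i) {
      rows <- data[data[[unit]] == g, , drop = FALSE]
      # relabel so repeated draws of a group stay distinct clusters
      rows[[unit]] <- paste0(rows[[unit]], "_b", i)
      rows
    }) |> dplyr::bind_rows()
  }
}

#' Association table relating derived measures to criterion scores
#'
#' For each criterion column, fits the joint mixed model
#' `criterion ~ EEA + SEA (+ random intercepts)` and reports each
#' predictor's part R-squared with its bootstrap interval, alongside the
#' bivariate correlations -- a compact analogue of a variance-partition
#' table.
#'
#' @param measures Subject-level tibble from [subject_measures()] (columns
#'   `subject`, `EEA`, `SEA`, ...).
#' @param criteria Tibble with `subject` and one column per criterion score,
#'   plus any nesting columns.
#' @param criterion_cols Criterion column names; defaults to all numeric
#'   non-nesting columns of `criteria`.
#' @param groups Nesting column names (e.g. `c("family", "site")`).
#' @param n_boot Bootstrap replicates for the intervals.
#' @param seed Integer seed.
#' @return A tibble with one row per criterion x predictor: `r`, `part_r2`,
#'   `conf.low`, `conf.high`.
#' @export
association_table <- function(measures, criteria, criterion_cols = NULL,
                              groups = c("family", "site"), n_boot = 1000,
                              seed = NULL) {
  dup <- setdiff(intersect(names(measures), names(criteria)), "subject")
  dat <- dplyr::inner_join(measures,
                           dplyr::select(criteria, !dplyr::all_of(dup)),
                           by = "subject")
  groups <- intersect(groups, names(dat))
  if (is.null(criterion_cols)) {
    criterion_cols <- setdiff(
      names(criteria)[vapply(criteria, is.numeric, logical(1))],
      c(groups, "subject")
    )
  }
  predictors <- c("EEA", "SEA")
  purrr::map(criterion_cols, function(cr) {
    purrr::map(predictors, function(p) {
      pr <- part_r2(dat, cr, predictors, p, groups = groups,
                    n_boot = n_boot, seed = seed)
      dplyr::bind_cols(
        tibble(criterion = cr, predictor = p,
               r = pearson_r(dat[[p]], dat[[cr]])$r),
        pr[, c("part_r2", "conf.low", "conf.high")]
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
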