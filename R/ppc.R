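#' Posterior predictive check
#'
#' For `n_draws` random posterior draws, simulates a dataset with the same
#' per-condition trial counts as the observed data, summarizes each with
#' [summarize_trials()], and reports -- per condition, response and
#' statistic (response proportion and RT quantiles at .1/.3/.5/.7/.9) -- the
#' observed value next to the median and 2.5/97.5 percentiles of the
#' predictive distribution.
#'
#' @param trials Observed trial tibble for one subject.
#' @param fit An `ea_fit` for the same data.
#' @param n_draws Number of posterior draws to simulate (default 100).
#' @param seed Integer seed.
#' @param probs Quantile probabilities to compare.
#' @param dt Euler step for DDM simulation.
#' @return A tibble of class `ea_ppc`: `condition`, `response`, `statistic`,
#'   `observed`, `predicted_median`, `lo`, `hi`, `coverage` flag.
#' @export
posterior_predictive <- function(trials, fit, n_draws = 100, seed = NULL,
                                 probs = c(.1, .3, .5, .7, .9), dt = 1e-3) {
  if (!fit$converged) {
    warn("posterior predictive check on a non-converged fit")
  }
  if (!is.null(seed)) set.seed(seed)
  design_counts <- table(trials$condition)
  design <- setNames(as.integer(design_counts), names(design_counts))
  n_total <- prod(dim(fit$natural)[1:2])
  idx <- if (n_draws >= n_total) seq_len(n_total) else
    sample.int(n_total, n_draws)
  flat <- apply(fit$natural, 3, as.vector)
  long_stats <- function(tt) {
    summarize_trials(tt, probs = probs) |>
      tidyr::pivot_longer(dplyr::starts_with("q") | dplyr::all_of("prop"),
                          names_to = "statistic", values_to = "value") |>
      dplyr::select(condition, response, statistic, value)
  }
  sim_one <- function(i, draw_id) {
    est <- setNames(flat[i, ], colnames(flat))
    params <- if (fit$model == "lba") lba_unflatten(est, fit$task)
    else ddm_unflatten(est, fit$task)
    sim <- if (fit$model == "lba") {
      lba_simulate(params, design, subject = fit$subject)
    } else {
      ddm_simulate(params, design, dt = dt, subject = fit$subject)
    }
    dplyr::mutate(long_stats(sim), draw = draw_id)
  }
  preds <- purrr::imap(idx, sim_one) |> dplyr::bind_rows()
  pred_sum <- preds |>
    dplyr::summarise(
      predicted_median = median(value, na.rm = TRUE),
      lo = if (all(is.na(value))) NA_real_ else
        quantile(value, 0.025, na.rm = TRUE),
      hi = if (all(is.na(value))) NA_real_ else
        quantile(value, 0.975, na.rm = TRUE),
      n_draws_defined = sum(!is.na(value)),
      .by = c(condition, response, statistic)
    )
  obs <- long_stats(trials) |> dplyr::rename(observed = value)
  out <- dplyr::full_join(obs, pred_sum,
                          by = c("condition", "response", "statistic")) |>
    dplyr::mutate(
      covered = !is.na(observed) & !is.na(lo) & observed >= lo & observed <= hi
    )
  class(out) <- c("ea_ppc", class(out))
  attr(out, "model") <- fit$model
  attr(out, "subject") <- fit$subject
  out
}

#' Plot a posterior predictive check
#'
#' Cumulative response probability against RT quintile, observed (open
#' points, dashed line) over the model's predictive medians and 95% bands,
#' one panel per condition and response.
#'
#' @param object An `ea_ppc` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ea_ppc <- function(object, ...) {
  qdat <- object |>
    dplyr::filter(grepl("^q", statistic), response != omission_label()) |>
    dplyr::mutate(quintile = as.numeric(sub("^q", "", statistic)) / 100)
  props <- object |>
    dplyr::filter(statistic == "prop") |>
    dplyr::select(condition, response, prop_obs = observed)
  dat <- dplyr::left_join(qdat, props, by = c("condition", "response")) |>
    dplyr::mutate(cum_prob = quintile * prop_obs)
  ggplot2::ggplot(dat, ggplot2::aes(x = observed, y = cum_prob)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = lo, xmax = hi, y = cum_prob),
      height = 0, colour = "grey50"
    ) +
    ggplot2::geom_point(ggplot2::aes(x = predicted_median), size = 2) +
    ggplot2::geom_point(shape = 1, size = 2, colour = "red") +
    ggplot2::facet_grid(condition ~ response) +
    ggplot2::labs(
      x = "RT (s)", y = "cumulative response probability",
      title = sprintf("Posterior predictive check (%s, subject %s)",
                      toupper(attr(object, "model")), attr(object, "subject")),
      subtitle = "open red: observed; solid: predictive median with 95% band"
    ) +
    ggplot2::theme_minimal()
}
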