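#' Scatterplots of the DDM drift average against EEA and SEA
#'
#' One panel per LBA-derived measure, with the Pearson correlation printed
#' in the corner and a linear fit overlaid -- the package's analogue of the
#' standard drift-rate-versus-accumulation-measure figure.
#'
#' @param measures Tibble from [subject_measures()] including `v_mean`.
#' @return A ggplot object.
#' @export
plot_drift_relations <- function(measures) {
  stopifnot(all(c("EEA", "SEA", "v_mean") %in% names(measures)))
  long <- tidyr::pivot_longer(measures, c("EEA", "SEA"),
                              names_to = "measure", values_to = "value")
  labels <- long |>
    dplyr::summarise(r = pearson_r(value, v_mean)$r, .by = measure) |>
    dplyr::mutate(label = sprintf("r = %.2f", r))
  ggplot2::ggplot(long, ggplot2::aes(x = value, y = v_mean)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::geom_text(data = labels, ggplot2::aes(label = label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = "LBA-derived measure (evidence/s)",
                  y = "DDM mean drift rate v") +
    ggplot2::theme_minimal()
}

#' Parameter-recovery scatterplot
#'
#' True versus recovered subject-level measures with the identity line.
#'
#' @param measures Tibble with columns `EEA`, `SEA` and their `_true`
#'   counterparts (as produced by [run_study()]).
#' @return A ggplot object.
#' @export
plot_recovery <- function(measures) {
  long <- dplyr::bind_rows(
    tibble(measure = "EEA", true = measures$EEA_true, recovered = measures$EEA),
    tibble(measure = "SEA", true = measures$SEA_true, recovered = measures$SEA)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = true, y = recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "generating value", y = "posterior-mean estimate") +
    ggplot2::theme_minimal()
}
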