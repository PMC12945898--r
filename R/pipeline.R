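#' Default study configuration
#'
#' Settings for a full pipeline run: the synthetic-cohort spec, QC
#' thresholds, fitting configuration for both models, posterior predictive
#' checks on a subset of subjects, and the association stage. Everything is
#' plain data so it round-trips through YAML.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_subjects,trials_per_condition,task Cohort shape (see
#'   [population_spec()]).
#' @param models Which models to fit.
#' @param burn_in,block,max_iter Fitting effort per subject (see
#'   [fit_config()]).
#' @param ppc_subjects,ppc_draws Posterior predictive checking: number of
#'   subjects (from the start of the cohort) and posterior draws.
#' @param n_boot Bootstrap replicates in the association stage.
#' @param include_nonconverged Keep non-converged subjects in the measures
#'   table (they are flagged either way).
#' @return A nested list of class `ea_study_config`.
#' @export
study_config <- function(seed = 1, n_subjects = 40, trials_per_condition = 300,
                         task = "nback2", models = c("lba", "ddm"),
                         burn_in = 400, block = 400, max_iter = 800,
                         ppc_subjects = 2, ppc_draws = 50, n_boot = 1000,
                         include_nonconverged = TRUE) {
  structure(
    list(
      seed = seed,
      synth = list(n_subjects = n_subjects,
                   trials_per_condition = trials_per_condition, task = task),
      qc = list(accuracy_floor = 0.55, omission_ceiling = 0.25),
      fit = list(models = models, burn_in = burn_in, block = block,
                 max_iter = max_iter),
      ppc = list(subjects = ppc_subjects, draws = ppc_draws),
      associate = list(n_boot = n_boot,
                       include_nonconverged = include_nonconverged)
    ),
    class = "ea_study_config"
  )
}

#' Read a study configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a YAML file with any of the [study_config()]
#'   arguments at top level.
#' @return An `ea_study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "ea_configuration_error")
  }
  do.call(study_config, raw)
}

#' Run the full modelling pipeline on a synthetic study
#'
#' Orchestrates synth -> QC -> per-subject fits (LBA and/or DDM) ->
#' posterior predictive checks -> derived measures -> association analyses.
#' Per-subject fitting seeds derive deterministically from the master seed,
#' so re-running the same configuration reproduces every table. When
#' `out_dir` is given, writes `trials.csv`, `criteria.csv`, `truth.csv`,
#' `qc.csv`, `measures.csv`, `ppc.csv`, `associations.csv` and
#' `manifest.json`.
#'
#' @param config An [study_config()] (or path to a YAML file).
#' @param out_dir Optional output directory.
#' @param progress Print per-stage progress.
#' @return A list with all intermediate and final tables, invisibly when
#'   writing to disk.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      progress = interactive()) {
  if (is.character(config)) config <- read_study_config(config)
  say <- function(...) if (progress) message(sprintf(...))

  spec <- population_spec(
    n_subjects = config$synth$n_subjects,
    task = config$synth$task,
    trials_per_condition = config$synth$trials_per_condition,
    seed = config$seed
  )
  say("generating cohort of %d subjects", spec$n_subjects)
  study <- simulate_study(spec)

  qc <- apply_qc(study$trials,
                 accuracy_floor = config$qc$accuracy_floor,
                 omission_ceiling = config$qc$omission_ceiling)
  say("QC retained %d / %d subjects", sum(qc$decisions$retained),
      nrow(qc$decisions))

  fit_cfg <- fit_config(burn_in = config$fit$burn_in,
                        block = config$fit$block,
                        max_iter = config$fit$max_iter)
  subjects <- unique(qc$retained$subject)
  set.seed(config$seed)
  fit_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, length(subjects) * 2),
    ncol = 2, dimnames = list(subjects, c("lba", "ddm"))
  )
  fits <- purrr::map(config$fit$models, function(model) {
    say("fitting %s to %d subjects", toupper(model), length(subjects))
    purrr::map(subjects, function(s) {
      fit_subject(dplyr::filter(qc$retained, subject == s), model = model,
                  config = fit_cfg, seed = fit_seeds[s, model])
    })
  })
  names(fits) <- config$fit$models

  ppc_tbl <- NULL
  if (config$ppc$subjects > 0) {
    say("posterior predictive checks on %d subjects", config$ppc$subjects)
    ppc_subj <- utils::head(subjects, config$ppc$subjects)
    ppc_tbl <- purrr::map(config$fit$models, function(model) {
      purrr::map(ppc_subj, function(s) {
        f <- fits[[model]][[match(s, subjects)]]
        posterior_predictive(dplyr::filter(qc$retained, subject == s), f,
                             n_draws = config$ppc$draws,
                             seed = fit_seeds[s, model]) |>
          dplyr::mutate(model = model, subject = s)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }

  measures <- subject_measures(fits$lba, fits$ddm)
  if (!config$associate$include_nonconverged) {
    keep <- measures$lba_converged &
      (is.na(measures$ddm_converged) | measures$ddm_converged)
    measures <- measures[keep, , drop = FALSE]
  }
  measures <- dplyr::left_join(
    measures,
    dplyr::select(study$population, subject, family, site,
                  EEA_true, SEA_true),
    by = "subject"
  )

  if (nrow(measures) >= 3) {
    say("association stage")
    assoc <- association_table(
      measures, study$criteria,
      criterion_cols = names(spec$criterion_loadings),
      groups = c("family", "site"),
      n_boot = config$associate$n_boot, seed = config$seed
    )
  } else {
    say("association stage skipped: fewer than 3 subjects in the measures table")
    assoc <- NULL
  }

  result <- list(
    config = config, spec = spec, population = study$population,
    trials = study$trials, criteria = study$criteria, qc = qc,
    fits = fits, ppc = ppc_tbl, measures = measures, associations = assoc
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")),
                       progress = FALSE)
    }
    wr(dplyr::select(study$trials, !dplyr::any_of(c("family", "site"))), "trials")
    wr(study$criteria, "criteria")
    wr(dplyr::select(study$population, !params), "truth")
    wr(qc$decisions, "qc")
    wr(measures, "measures")
    if (!is.null(ppc_tbl)) wr(ppc_tbl, "ppc")
    if (!is.null(assoc)) wr(assoc, "associations")
    manifest <- list(
      package_version = as.character(utils::packageVersion("evaccum")),
      seed = config$seed,
      config = unclass(config),
      config_hash = rlang::hash(unclass(config)),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE),
      n_subjects_retained = length(subjects)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(result))
  }
  result
}
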