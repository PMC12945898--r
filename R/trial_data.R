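#' Read a trial table from delimited text
#'
#' Reads one row per trial with columns `subject`, `task`, `condition`,
#' `response`, `rt` (seconds; empty/NA for omitted trials) plus any extra
#' columns (e.g. nesting factors such as `family`, `site`), validates it
#' against the task designs, and returns a tibble in the canonical schema.
#' Omitted trials carry `response == "omitted"` and `rt = NA`.
#'
#' @param path Path to a CSV (or TSV, by file extension) file with a header.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(subject = "subj_id", rt = "resp_time")`. Unmapped canonical names are
#'   assumed to be present verbatim.
#'
#' @return A validated trial tibble (class `ea_trials`), one row per trial.
#' @seealso [validate_trials()], [write_trials()], [apply_qc()]
#' @export
read_trials <- function(path, schema = NULL) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("Schema refers to columns absent from file: ",
                   paste(missing_src, collapse = ", ")), class = "ea_schema_error")
    }
    raw <- dplyr::rename(raw, !!!rlang::set_names(schema, names(schema)))
  }
  required <- c("subject", "task", "condition", "response", "rt")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")), class = "ea_schema_error")
  }
  if (!is.numeric(raw$rt)) {
    rt_num <- suppressWarnings(as.numeric(raw$rt))
    bad <- which(!is.na(raw$rt) & raw$rt != "" & is.na(rt_num))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric RT values at data row(s): ",
                   paste(utils::head(bad, 10), collapse = ", ")),
            class = "ea_validation_error")
    }
    raw$rt <- rt_num
  }
  trials <- dplyr::mutate(
    raw,
    subject = as.character(subject),
    task = as.character(task),
    condition = as.character(condition),
    response = dplyr::if_else(is.na(response) | response == "",
                              omission_label(), as.character(response))
  )
  validate_trials(trials)
}

#' Validate a trial table
#'
#' Checks the invariants of the canonical trial schema: known tasks,
#' conditions and responses matching each task's design, positive RTs below
#' the response window, and RT present exactly when a response was made.
#' A median RT above 100 is taken as evidence of millisecond units and
#' rejected rather than rescaled.
#'
#' @param trials A data frame in the canonical trial schema.
#' @param window Response window in seconds used for the RT upper-bound
#'   check; defaults to each task's design window. Pass the actual window
#'   when validating data recorded under a nonstandard one.
#' @return The validated tibble with class `ea_trials`, or an error naming the
#'   offending rows.
#' @export
validate_trials <- function(trials, window = NULL) {
  trials <- as_tibble(trials)
  fail <- function(msg, rows) {
    abort(paste0(msg, " at row(s): ",
                 paste(utils::head(rows, 10), collapse = ", "),
                 if (length(rows) > 10) sprintf(" (and %d more)", length(rows) - 10) else ""),
          class = "ea_validation_error")
  }
  known <- c("nback0", "nback2", "nback", "numerosity")
  bad <- which(!trials$task %in% known)
  if (length(bad) > 0) fail("Unknown task", bad)

  med_rt <- median(trials$rt, na.rm = TRUE)
  if (is.finite(med_rt) && med_rt > 100) {
    abort(paste0("Median RT is ", signif(med_rt, 4),
                 ": RTs look like milliseconds; convert to seconds before loading."),
          class = "ea_validation_error")
  }
  bad <- which(!is.na(trials$rt) & trials$rt <= 0)
  if (length(bad) > 0) fail("Non-positive RT", bad)

  omitted <- trials$response == omission_label()
  bad <- which(omitted & !is.na(trials$rt))
  if (length(bad) > 0) fail("Omitted trial with an RT", bad)
  bad <- which(!omitted & is.na(trials$rt))
  if (length(bad) > 0) fail("Responded trial without an RT", bad)

  for (tk in unique(trials$task)) {
    design <- task_design(tk)
    idx <- which(trials$task == tk)
    bad <- idx[!trials$condition[idx] %in% design$conditions]
    if (length(bad) > 0) fail(paste0("Condition not in ", tk, " design"), bad)
    ok_resp <- c(design$responses, omission_label())
    bad <- idx[!trials$response[idx] %in% ok_resp]
    if (length(bad) > 0) fail(paste0("Response not in ", tk, " design"), bad)
    win <- if (is.null(window)) design$window else window
    bad <- idx[!is.na(trials$rt[idx]) & trials$rt[idx] >= win]
    if (length(bad) > 0) fail(paste0("RT at or beyond the ", win,
                                     " s response window"), bad)
  }
  class(trials) <- c("ea_trials", class(trials))
  trials
}

#' Write a trial table to delimited text
#'
#' Inverse of [read_trials()]: round-tripping through `write_trials()` and
#' `read_trials()` reproduces the trials exactly.
#'
#' @param trials A trial tibble.
#' @param path Output path (`.csv` or `.tsv` by extension).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- as_tibble(trials)
  class(out) <- class(tibble())
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Mark trial correctness against the task design
#'
#' @param trials A trial tibble.
#' @return The tibble with a logical `correct` column (`NA` for omissions).
#' @export
mark_correct <- function(trials) {
  dplyr::mutate(
    trials,
    correct = dplyr::if_else(
      response == omission_label(), NA,
      response == matching_response(condition, task[1])
    ),
    .by = task
  )
}

#' Quality-control screening of subjects
#'
#' Excludes subjects whose accuracy over responded trials falls below
#' `accuracy_floor` (default 55%) or whose omission rate over all trials
#' exceeds `omission_ceiling` (default 25%). Accuracy is pooled across
#' conditions; subjects with no responded trials at all are excluded with
#' reason `"no responses"`.
#'
#' @param trials A trial tibble covering one or more subjects.
#' @param accuracy_floor Minimum accuracy (proportion correct of responded
#'   trials) to retain a subject.
#' @param omission_ceiling Maximum proportion of omitted trials to retain a
#'   subject.
#'
#' @return A list of class `ea_qc` with elements `retained` (trial tibble),
#'   `excluded` (trial tibble) and `decisions` (one row per subject x task:
#'   `accuracy`, `omission_rate`, `retained`, `reason`).
#' @export
#' @examples
#' trials <- lba_simulate(
#'   lba_params("nback2", v_match = 3, v_mismatch = 1),
#'   design = c(target = 30, lure = 30, novel = 30), seed = 1
#' )
#' apply_qc(trials)$decisions
apply_qc <- function(trials, accuracy_floor = 0.55, omission_ceiling = 0.25) {
  marked <- mark_correct(trials)
  decisions <- marked |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_responded = sum(response != omission_label()),
      accuracy = ifelse(n_responded > 0,
                        sum(correct, na.rm = TRUE) / n_responded, NA_real_),
      omission_rate = mean(response == omission_label()),
      .by = c(subject, task)
    ) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        n_responded == 0 ~ "no responses",
        accuracy < accuracy_floor ~
          sprintf("accuracy %.3f below floor %.2f", accuracy, accuracy_floor),
        omission_rate > omission_ceiling ~
          sprintf("omission rate %.3f above ceiling %.2f",
                  omission_rate, omission_ceiling),
        .default = NA_character_
      ),
      retained = is.na(reason)
    )
  keep_key <- decisions[decisions$retained, c("subject", "task")]
  retained <- dplyr::semi_join(trials, keep_key, by = c("subject", "task"))
  excluded <- dplyr::anti_join(trials, keep_key, by = c("subject", "task"))
  structure(
    list(retained = retained, excluded = excluded, decisions = decisions),
    class = "ea_qc"
  )
}

#' @export
print.ea_qc <- function(x, ...) {
  cat(sprintf("QC: %d of %d subject-task datasets retained\n",
              sum(x$decisions$retained), nrow(x$decisions)))
  dropped <- x$decisions[!x$decisions$retained, ]
  if (nrow(dropped) > 0) {
    cat("Excluded:\n")
    print(dropped[, c("subject", "task", "accuracy", "omission_rate", "reason")])
  }
  invisible(x)
}

#' Per-condition summary of choice proportions and RT quantiles
#'
#' For each condition (within subject and task when several are present)
#' reports the proportion of each response -- including omissions, so
#' proportions sum to one over all trials in the condition -- and RT
#' quantiles at the requested probabilities for each responded option.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Cells with fewer responded trials than
#' `min_count` are flagged, not dropped.
#'
#' @param trials A trial tibble.
#' @param probs Quantile probabilities (default the RT quintiles
#'   .1, .3, .5, .7, .9).
#' @param min_count Responded-trial count below which a cell is flagged.
#' @return A tibble with one row per subject x task x condition x response:
#'   `n`, `prop`, quantile columns `q10`, `q30`, ... and `flagged`.
#' @export
summarize_trials <- function(trials, probs = c(.1, .3, .5, .7, .9),
                             min_count = 5) {
  qnames <- paste0("q", round(100 * probs))
  cells <- trials |>
    dplyr::mutate(n_condition = dplyr::n(), .by = c(subject, task, condition)) |>
    dplyr::summarise(
      n = dplyr::n(),
      prop = dplyr::n() / n_condition[1],
      qs = list(if (response[1] == omission_label()) {
        rep(NA_real_, length(probs))
      } else {
        unname(quantile(rt, probs = probs, type = 7, names = FALSE))
      }),
      .by = c(subject, task, condition, response)
    ) |>
    tidyr::unnest_wider(qs, names_sep = "_") |>
    rlang::set_names(function(nm) {
      is_q <- grepl("^qs_", nm)
      nm[is_q] <- qnames[as.integer(sub("^qs_", "", nm[is_q]))]
      nm
    }) |>
    dplyr::mutate(flagged = response != omission_label() & n < min_count)
  # make every (condition, response) cell explicit, including empty ones
  grid <- trials |>
    dplyr::distinct(subject, task, condition) |>
    dplyr::reframe(response = c(task_design(task[1])$responses, omission_label()),
                   .by = c(subject, task, condition))
  grid |>
    dplyr::left_join(cells, by = c("subject", "task", "condition", "response")) |>
    dplyr::mutate(
      n = dplyr::coalesce(n, 0L),
      prop = dplyr::coalesce(prop, 0),
      flagged = dplyr::coalesce(flagged, response != omission_label())
    )
}
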