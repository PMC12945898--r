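#' Task designs
#'
#' Metadata for the supported two-choice designs: the n-back recognition task
#' (three trial types -- target, lure, novel -- with a 2 s response window and
#' target/nontarget responses) and the numerosity discrimination task (a 2 x 2
#' stimulus-by-difficulty design with a 3 s window and many/few responses).
#' The `correct` map gives, for each condition, the response that matches the
#' stimulus; accumulator-model parameters are accuracy-coded against it.
#'
#' @param task One of `"nback0"`, `"nback2"`, `"nback"`, `"numerosity"`.
#'
#' @return A list with elements `task`, `window` (seconds), `conditions`,
#'   `responses`, and `correct` (named character: condition -> matching
#'   response).
#' @export
#' @examples
#' task_design("nback2")$correct
task_design <- function(task) {
  task <- match.arg(task, c("nback0", "nback2", "nback", "numerosity"))
  if (task %in% c("nback0", "nback2", "nback")) {
    list(
      task = task,
      window = 2,
      conditions = c("target", "lure", "novel"),
      responses = c("target", "nontarget"),
      correct = c(target = "target", lure = "nontarget", novel = "nontarget")
    )
  } else {
    list(
      task = task,
      window = 3,
      conditions = c("many_easy", "few_easy", "many_hard", "few_hard"),
      responses = c("many", "few"),
      correct = c(
        many_easy = "many", few_easy = "few",
        many_hard = "many", few_hard = "few"
      )
    )
  }
}

#' The matching (correct) response for each trial condition
#'
#' @param condition Character vector of condition labels.
#' @param task Task name passed to [task_design()].
#' @return Character vector of matching responses, same length as `condition`.
#' @export
matching_response <- function(condition, task) {
  design <- task_design(task)
  unname(design$correct[condition])
}

#' The non-matching response for each trial condition
#' @inheritParams matching_response
#' @return Character vector of mismatching responses.
#' @export
mismatching_response <- function(condition, task) {
  design <- task_design(task)
  m <- design$correct[condition]
  other <- vapply(m, function(r) setdiff(design$responses, r)[1], character(1))
  unname(other)
}

#' Omission label used in trial tables
#' @return The string `"omitted"`.
#' @export
omission_label <- function() "omitted"
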