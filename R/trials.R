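#' Trial table schema
#'
#' A trial table holds one row per behavioural trial of a confidence-rated
#' two-alternative forced-choice (2AFC) task. The required columns are:
#'
#' * `subject_id` (character): subject identifier.
#' * `group` (character): group label (e.g. lesion group).
#' * `domain` (character): task domain, e.g. `"perception"` or `"memory"`.
#' * `block` (integer): block number within the session.
#' * `trial_index` (integer): trial number within subject and domain;
#'   must be unique within `(subject_id, domain)`.
#' * `stimulus_side` (`"left"` or `"right"`): side of the correct alternative
#'   (`left` = S1, `right` = S2).
#' * `response_side` (`"left"` or `"right"`): side the observer chose.
#' * `accuracy` (0/1): must equal `stimulus_side == response_side`.
#' * `confidence_raw` (numeric in \[1, 6\]): continuous confidence rating on
#'   the 1 (low) to 6 (high) slider scale.
#' * `condition_tag` (character): free condition label (study time in minutes
#'   for memory blocks; staircase difficulty \eqn{\Delta d} for perception).
#'
#' @name trial-table
NULL

trial_columns <- c(
  "subject_id", "group", "domain", "block", "trial_index",
  "stimulus_side", "response_side", "accuracy", "confidence_raw",
  "condition_tag"
)

#' Validate a trial table
#'
#' Checks a data frame against the trial-table schema (see [trial-table]) and
#' aborts with a message listing every offending row if it does not conform.
#'
#' @param trials A data frame of trials.
#' @return The validated table, invisibly, as a tibble.
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) {
    abort_validation("`trials` must be a data frame")
  }
  missing_cols <- setdiff(trial_columns, names(trials))
  unknown_cols <- setdiff(names(trials), trial_columns)
  if (length(missing_cols) > 0 || length(unknown_cols) > 0) {
    probs <- c(
      if (length(missing_cols)) sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
      if (length(unknown_cols)) sprintf("unknown column(s): %s", paste(unknown_cols, collapse = ", "))
    )
    abort_validation("trial table does not match the expected schema", probs)
  }
  trials <- tibble::as_tibble(trials)
  probs <- character()
  row_of <- function(i) sprintf("row %d: ", i)

  bad <- which(!(trials$stimulus_side %in% .side_levels))
  probs <- c(probs, sprintf("%sstimulus_side must be 'left' or 'right' (got '%s')",
                            row_of(bad), trials$stimulus_side[bad]))
  bad <- which(!(trials$response_side %in% .side_levels))
  probs <- c(probs, sprintf("%sresponse_side must be 'left' or 'right' (got '%s')",
                            row_of(bad), trials$response_side[bad]))
  bad <- which(!(trials$accuracy %in% c(0, 1)))
  probs <- c(probs, sprintf("%saccuracy must be 0 or 1 (got '%s')",
                            row_of(bad), trials$accuracy[bad]))
  ok_sides <- trials$stimulus_side %in% .side_levels &
    trials$response_side %in% .side_levels & trials$accuracy %in% c(0, 1)
  bad <- which(ok_sides &
                 trials$accuracy != as.integer(trials$stimulus_side == trials$response_side))
  probs <- c(probs, sprintf("%saccuracy inconsistent with stimulus_side/response_side", row_of(bad)))
  bad <- which(!is.finite(trials$confidence_raw) |
                 trials$confidence_raw < 1 | trials$confidence_raw > 6)
  probs <- c(probs, sprintf("%sconfidence_raw must lie in [1, 6] (got %s)",
                            row_of(bad), format(trials$confidence_raw[bad])))
  key <- paste(trials$subject_id, trials$domain, trials$trial_index, sep = "\r")
  bad <- which(duplicated(key))
  probs <- c(probs, sprintf("%sduplicate (subject_id, domain, trial_index)", row_of(bad)))

  if (length(probs) > 0) {
    abort_validation("invalid trial table", probs)
  }
  invisible(trials)
}
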