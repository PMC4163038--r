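#' Generative observer model
#'
#' Defines a simulated 2AFC observer with independently controllable decision
#' accuracy and confidence-accuracy coupling. Evidence on each trial is drawn
#' from a Gaussian with unit decision noise (the reference scale):
#' `x ~ N(+/- mu, 1)`, where `mu = evidence_per_dot * delta_d` for the dot
#' task and `mu = qnorm(accuracy)` for a memory block targeting a given
#' accuracy. The type-1 response is the sign of the *decision channel*
#' `x + N(0, decision_extra_noise_sd)`; the confidence report reads the
#' *confidence channel* `x + N(0, confidence_noise_sd)`.
#'
#' * `confidence_noise_sd > 0` degrades the confidence channel relative to
#'   the decision, producing metacognitive efficiency (meta-d'/d') below 1.
#' * `decision_extra_noise_sd > 0` degrades the decision relative to the
#'   confidence channel, producing efficiency above 1 (the confidence report
#'   exploits evidence the decision lost to late noise).
#' * Both zero: the SDT-ideal observer, efficiency 1.
#'
#' The signed confidence evidence (evidence for the chosen side) is mapped to
#' the continuous 1-6 slider by a strictly monotone piecewise-linear read-out
#' anchored at the five `confidence_criteria`: criterion `j` maps to slider
#' position `j + 0.5` (a category boundary), segments between criteria are
#' linear, and the outer segments squash exponentially into the scale ends so
#' the report always lies in \[1, 6\].
#'
#' @param evidence_per_dot Mean evidence per dot of staircase difference
#'   `delta_d`, in decision-noise SD units. The default 0.147 puts the
#'   one-up/two-down staircase equilibrium near `delta_d = 4` dots,
#'   matching the difficulty regime of staircase-controlled dot
#'   discrimination.
#' @param memory_accuracy Named numeric vector of target accuracies per study
#'   time in minutes (names `"0.5"`, `"1"`, `"1.5"`); must be non-decreasing
#'   in study time.
#' @param confidence_noise_sd Independent noise SD on the confidence channel
#'   (>= 0).
#' @param decision_extra_noise_sd Independent noise SD added to the decision
#'   channel (>= 0).
#' @param confidence_criteria Five strictly increasing thresholds on the
#'   signed confidence evidence, anchoring the slider read-out.
#' @param lapse_rate Probability of a uniformly random response, in
#'   \[0, 0.1\].
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(evidence_per_dot = 0.147,
                           memory_accuracy = c("0.5" = 0.67, "1" = 0.73, "1.5" = 0.76),
                           confidence_noise_sd = 0,
                           decision_extra_noise_sd = 0,
                           confidence_criteria = c(-0.5, 0, 0.5, 1.1, 1.9),
                           lapse_rate = 0) {
  stopifnot(
    is.numeric(evidence_per_dot), length(evidence_per_dot) == 1L,
    evidence_per_dot >= 0,
    is.numeric(confidence_noise_sd), confidence_noise_sd >= 0,
    is.numeric(decision_extra_noise_sd), decision_extra_noise_sd >= 0
  )
  if (length(confidence_criteria) != 5L || any(diff(confidence_criteria) <= 0)) {
    stop("`confidence_criteria` must be 5 strictly increasing thresholds")
  }
  if (length(lapse_rate) != 1L || lapse_rate < 0 || lapse_rate > 0.1) {
    stop("`lapse_rate` must lie in [0, 0.1]")
  }
  if (is.null(names(memory_accuracy)) ||
      !all(c("0.5", "1", "1.5") %in% names(memory_accuracy))) {
    stop("`memory_accuracy` must be named with study times '0.5', '1', '1.5'")
  }
  memory_accuracy <- memory_accuracy[c("0.5", "1", "1.5")]
  if (any(memory_accuracy <= 0.5) || any(memory_accuracy >= 1) ||
      any(diff(memory_accuracy) < 0)) {
    stop("`memory_accuracy` must be in (0.5, 1) and non-decreasing in study time")
  }
  structure(
    list(
      evidence_per_dot = evidence_per_dot,
      memory_accuracy = memory_accuracy,
      decision_noise_sd = 1,
      confidence_noise_sd = confidence_noise_sd,
      decision_extra_noise_sd = decision_extra_noise_sd,
      confidence_criteria = confidence_criteria,
      lapse_rate = lapse_rate
    ),
    class = "observer_model"
  )
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf(
    paste0("Generative 2AFC observer: evidence/dot = %.3f, conf noise SD = %.3f, ",
           "extra decision noise SD = %.3f, lapse = %.3f\n"),
    x$evidence_per_dot, x$confidence_noise_sd, x$decision_extra_noise_sd, x$lapse_rate
  ))
  cat("  memory accuracy targets:",
      paste(sprintf("%s min: %.2f", names(x$memory_accuracy), x$memory_accuracy),
            collapse = ", "), "\n")
  invisible(x)
}

# Strictly monotone slider read-out: signed confidence evidence -> [1, 6].
map_confidence <- function(z, criteria) {
  w <- mean(diff(criteria))
  r <- numeric(length(z))
  lo <- z <= criteria[1]
  hi <- z > criteria[5]
  mid <- !lo & !hi
  r[lo] <- 1 + 0.5 * exp((z[lo] - criteria[1]) / w)
  r[hi] <- 6 - 0.5 * exp(-(z[hi] - criteria[5]) / w)
  j <- findInterval(z[mid], criteria)
  r[mid] <- j + 0.5 + (z[mid] - criteria[j]) / (criteria[j + 1] - criteria[j])
  pmin(6, pmax(1, r))
}

#' Staircase state for the dot-discrimination task
#'
#' State of the one-up/two-down staircase on the dot difference
#' `delta_d`: the reference circle always holds `reference_dots` (50) dots
#' and the comparison holds `reference_dots +/- delta_d`, so with
#' `delta_d <= 49` every displayed dot count stays within \[1, 100\].
#'
#' @param delta_d Current dot difference (integer, clamped to
#'   `[min_delta, max_delta]`).
#' @param consecutive_correct Number of consecutive correct responses since
#'   the last difficulty change (0 or 1).
#' @param reference_dots Dots in the reference circle (50).
#' @param min_delta,max_delta Clamp bounds for `delta_d`. The upper default
#'   49 keeps both possible comparison counts (50 + 49, 50 - 49) inside the
#'   1-100 display range.
#' @return An object of class `staircase_state`.
#' @export
staircase_state <- function(delta_d = 15L, consecutive_correct = 0L,
                            reference_dots = 50L, min_delta = 1L, max_delta = 49L) {
  delta_d <- as.integer(delta_d)
  stopifnot(delta_d >= min_delta, delta_d <= max_delta,
            consecutive_correct %in% c(0L, 1L))
  structure(
    list(delta_d = delta_d, consecutive_correct = as.integer(consecutive_correct),
         reference_dots = as.integer(reference_dots),
         min_delta = as.integer(min_delta), max_delta = as.integer(max_delta)),
    class = "staircase_state"
  )
}

#' One-up/two-down staircase update
#'
#' After two consecutive correct responses the dot difference `delta_d`
#' decreases by one dot (harder); after a single incorrect response it
#' increases by one dot (easier). This rule converges on the stimulus level
#' yielding about 70.7% correct. `delta_d` is clamped to the state's bounds.
#'
#' @param state A [staircase_state()].
#' @param last_accuracy 0/1 accuracy of the trial just completed.
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, last_accuracy) {
  stopifnot(inherits(state, "staircase_state"), last_accuracy %in% c(0, 1))
  if (last_accuracy == 1) {
    if (state$consecutive_correct >= 1L) {
      state$delta_d <- max(state$min_delta, state$delta_d - 1L)
      state$consecutive_correct <- 0L
    } else {
      state$consecutive_correct <- 1L
    }
  } else {
    state$delta_d <- min(state$max_delta, state$delta_d + 1L)
    state$consecutive_correct <- 0L
  }
  state
}
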