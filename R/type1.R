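#' Type-1 sensitivity and criterion from 2AFC trials
#'
#' Estimates d' and the type-1 criterion c under the equal-variance Gaussian
#' signal detection model, treating the `"right"` (S2) alternative as the
#' signal: `d' = z(hit) - z(fa)` and `c = -(z(hit) + z(fa)) / 2`, where the
#' hit rate is the probability of a `"right"` response to a `"right"`
#' stimulus and the false-alarm rate the probability of a `"right"` response
#' to a `"left"` stimulus.
#'
#' Extreme proportions are corrected per stimulus class before taking normal
#' quantiles: a rate of 0 is replaced by `1/(2N)` and a rate of 1 by
#' `1 - 1/(2N)`, with `N` the number of trials of that class, so both
#' estimates are always finite.
#'
#' @param trials A data frame with columns `stimulus_side` and
#'   `response_side` (`"left"`/`"right"`); see [trial-table].
#' @return An object of class `type1_summary`: a list with `d_prime`,
#'   `criterion_c`, `hit_rate`, `fa_rate` (corrected rates) and `n_trials`.
#' @examples
#' trials <- tibble::tibble(
#'   stimulus_side = rep(c("left", "right"), each = 50),
#'   response_side = sample(c("left", "right"), 100, replace = TRUE)
#' )
#' compute_type1(trials)
#' @export
compute_type1 <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("`trials` is empty: need at least one trial per stimulus class")
  }
  stim <- trials$stimulus_side
  resp <- trials$response_side
  for (cls in .side_levels) {
    if (!any(stim == cls)) {
      stop(sprintf("no trials with stimulus_side = '%s'", cls))
    }
  }
  n_s2 <- sum(stim == "right")
  n_s1 <- sum(stim == "left")
  hit <- sum(resp == "right" & stim == "right") / n_s2
  fa <- sum(resp == "right" & stim == "left") / n_s1
  hit <- correct_extreme(hit, n_s2)
  fa <- correct_extreme(fa, n_s1)
  structure(
    list(
      d_prime = qnorm(hit) - qnorm(fa),
      criterion_c = -(qnorm(hit) + qnorm(fa)) / 2,
      hit_rate = hit,
      fa_rate = fa,
      n_trials = length(stim)
    ),
    class = "type1_summary"
  )
}

# 0 -> 1/(2N), 1 -> 1 - 1/(2N); intermediate rates untouched
correct_extreme <- function(rate, n) {
  if (rate == 0) 1 / (2 * n) else if (rate == 1) 1 - 1 / (2 * n) else rate
}

#' @export
print.type1_summary <- function(x, ...) {
  cat(sprintf(
    "Type-1 SDT summary: d' = %.3f, c = %.3f (hit = %.3f, fa = %.3f, n = %d)\n",
    x$d_prime, x$criterion_c, x$hit_rate, x$fa_rate, x$n_trials
  ))
  invisible(x)
}
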