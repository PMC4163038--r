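#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples `values` with replacement `n_resamples` times, computes the
#' statistic (the mean by default) on each resample, and returns the
#' percentile interval of the resulting bootstrap distribution. The default
#' of 100,000 resamples is the conventional setting for subject-level
#' summary statistics in this design.
#'
#' @param values Numeric vector (length >= 2). When resampling subjects,
#'   pass one value per subject: the resampling unit is the subject, not the
#'   trial.
#' @param level Confidence level (default 0.95).
#' @param n_resamples Number of bootstrap resamples (default 100000).
#' @param seed Optional integer seed for reproducibility.
#' @param statistic Function applied to each resample (default `mean`).
#' @return Named numeric vector `c(lower, upper)` with attributes `level` and
#'   `n_resamples`.
#' @export
bootstrap_percentile_ci <- function(values, level = 0.95, n_resamples = 100000L,
                                    seed = NULL, statistic = mean) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("need at least 2 non-missing values to bootstrap")
  }
  stopifnot(level > 0, level < 1, n_resamples >= 1)
  n <- length(values)
  with_seed(seed, {
    fast_mean <- identical(statistic, mean)
    stats <- if (fast_mean) {
      # chunked to bound memory at large resample counts
      chunk <- max(1L, min(n_resamples, as.integer(2e7 / n)))
      out <- numeric(n_resamples)
      done <- 0L
      while (done < n_resamples) {
        b <- min(chunk, n_resamples - done)
        m <- matrix(sample(values, n * b, replace = TRUE), nrow = n)
        out[done + seq_len(b)] <- colMeans(m)
        done <- done + b
      }
      out
    } else {
      vapply(seq_len(n_resamples),
             function(i) statistic(sample(values, n, replace = TRUE)),
             numeric(1))
    }
    alpha <- (1 - level) / 2
    ci <- unname(quantile(stats, c(alpha, 1 - alpha)))
    structure(c(lower = ci[1], upper = ci[2]),
              level = level, n_resamples = n_resamples)
  })
}
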