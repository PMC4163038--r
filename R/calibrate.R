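# Measure the expected fitted efficiency of an observer on a long session.
measure_efficiency <- function(observer, task, n_trials, seed, nbins = 4L) {
  trials <- if (task == "perception") {
    simulate_perception_session(observer, seed = seed, n_trials = n_trials,
                                n_blocks = 1L)
  } else {
    simulate_memory_session(observer, seed = seed,
                            trials_per_block = as.integer(ceiling(n_trials / 4)))
  }
  efficiency_from_trials(trials, nbins = nbins)$efficiency
}

observer_with_noise <- function(observer, sigma, channel) {
  if (channel == "confidence") {
    observer$confidence_noise_sd <- sigma
  } else {
    observer$decision_extra_noise_sd <- sigma
  }
  observer
}

#' Calibrate generative noise to a target metacognitive efficiency
#'
#' Finds the noise level at which the simulated observer's *fitted*
#' meta-d'/d' equals a target efficiency. Targets at or below 1 are reached
#' by adding noise to the confidence channel (efficiency decreases
#' monotonically in `confidence_noise_sd`); targets above 1 by adding noise
#' to the decision channel while confidence reads the cleaner underlying
#' evidence (the standard generative route to super-optimal efficiency).
#' Inversion is by bisection, evaluating the mean fitted efficiency of one
#' long simulated session (`n_trials` trials, default 1e5) at each candidate
#' noise level.
#'
#' @param target_efficiency Target meta-d'/d' in (0, 1.5].
#' @param task `"perception"` (staircased dot task) or `"memory"`.
#' @param observer Template [observer_model()]; its noise fields are
#'   overwritten by the calibration.
#' @param n_trials Trials per calibration simulation (default 1e5).
#' @param seed Integer seed.
#' @param max_iter Bisection iterations (default 14).
#' @return The calibrated noise SD, with attributes `channel`
#'   (`"confidence"` or `"decision"`), `achieved` (fitted efficiency at the
#'   returned value) and `target`.
#' @export
calibrate_confidence_noise <- function(target_efficiency,
                                       task = c("perception", "memory"),
                                       observer = observer_model(),
                                       n_trials = 1e5, seed = 1L,
                                       max_iter = 14L) {
  task <- match.arg(task)
  if (!is.numeric(target_efficiency) || length(target_efficiency) != 1L ||
      target_efficiency <= 0 || target_efficiency > 1.5) {
    stop("`target_efficiency` must lie in (0, 1.5]; larger or non-positive ",
         "efficiencies are outside the supported calibration range")
  }
  channel <- if (target_efficiency <= 1) "confidence" else "decision"
  lo <- 0
  hi <- if (channel == "confidence") 8 else 2
  eff_at <- function(sigma, i) {
    measure_efficiency(observer_with_noise(observer, sigma, channel),
                       task, n_trials, seed = derive_seed(seed, 1000L + i))
  }
  # efficiency is decreasing in confidence noise, increasing in decision noise
  sign_up <- if (channel == "confidence") -1 else 1

  eff_hi <- eff_at(hi, 0L)
  if (sign_up * (eff_hi - target_efficiency) < -0.03) {
    stop(sprintf(
      paste0("target efficiency %.3f is unreachable for the %s channel ",
             "(attains %.3f at noise SD %.1f); supported range is (0, 1.5]"),
      target_efficiency, channel, eff_hi, hi
    ))
  }
  hist_sigma <- numeric(0)
  hist_eff <- numeric(0)
  for (i in seq_len(max_iter)) {
    sigma <- (lo + hi) / 2
    eff <- eff_at(sigma, i)
    hist_sigma <- c(hist_sigma, sigma)
    hist_eff <- c(hist_eff, eff)
    if (sign_up * (eff - target_efficiency) > 0) hi <- sigma else lo <- sigma
  }
  sigma <- (lo + hi) / 2
  # each bisection evaluation is a noisy Monte-Carlo estimate, so the final
  # interval can sit slightly off target; correct with a local linear fit
  # over the late (clustered) bisection points
  late <- utils::tail(order(abs(hist_sigma - sigma)), 8L)
  keep <- utils::head(order(abs(hist_sigma - sigma)), max(4L, length(late) - 2L))
  if (length(unique(hist_sigma[keep])) >= 2) {
    fit <- stats::lm(hist_eff[keep] ~ hist_sigma[keep])
    slope <- stats::coef(fit)[2]
    if (is.finite(slope) && abs(slope) > 1e-3) {
      sigma_new <- (target_efficiency - stats::coef(fit)[1]) / slope
      span <- diff(range(hist_sigma[keep]))
      if (is.finite(sigma_new)) {
        sigma <- min(max(sigma_new, sigma - 2 * span), sigma + 2 * span)
        sigma <- max(sigma, 0)
      }
    }
  }
  achieved <- mean(c(eff_at(sigma, max_iter + 1L), eff_at(sigma, max_iter + 2L)))
  structure(sigma, channel = channel, achieved = achieved,
            target = target_efficiency)
}

# Monotone noise -> efficiency curve for a task, used to draw cohorts with
# per-subject generative efficiencies without re-running the bisection for
# every subject.
efficiency_noise_curve <- function(task, observer, n_trials = 4e4, seed = 1L,
                                   conf_sigmas = c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.75, 4),
                                   dec_sigmas = c(0.25, 0.5, 0.75, 1)) {
  eff_conf <- vapply(seq_along(conf_sigmas), function(i) {
    measure_efficiency(observer_with_noise(observer, conf_sigmas[i], "confidence"),
                       task, n_trials, seed = derive_seed(seed, 2000L + i))
  }, numeric(1))
  eff_dec <- vapply(seq_along(dec_sigmas), function(i) {
    measure_efficiency(observer_with_noise(observer, dec_sigmas[i], "decision"),
                       task, n_trials, seed = derive_seed(seed, 3000L + i))
  }, numeric(1))
  # one axis from strongly degraded (large conf noise) to super-optimal
  # (large decision noise); enforce monotonicity for interpolation
  sigma_axis <- c(-rev(conf_sigmas), dec_sigmas)
  eff_axis <- c(rev(eff_conf), eff_dec)
  eff_axis <- cummax(eff_axis)
  list(sigma_axis = sigma_axis, eff_axis = eff_axis)
}

# Invert the curve: target efficiency -> (confidence_noise_sd,
# decision_extra_noise_sd)
noise_for_efficiency <- function(curve, target) {
  rng <- range(curve$eff_axis)
  target <- pmin(pmax(target, rng[1]), rng[2])
  s <- approx(curve$eff_axis, curve$sigma_axis, xout = target, ties = "ordered")$y
  list(
    confidence_noise_sd = ifelse(s < 0, -s, 0),
    decision_extra_noise_sd = ifelse(s > 0, s, 0)
  )
}
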