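#' Simulate a staircased dot-discrimination session
#'
#' Generates one perception session of 2AFC dot-number judgements with
#' confidence ratings. The reference circle holds 50 dots; the comparison
#' holds `50 +/- delta_d`, with `delta_d` adapted by the one-up/two-down
#' staircase ([staircase_update()]). Each trial draws evidence
#' `x ~ N(stim * evidence_per_dot * delta_d, 1)` (stim = -1 for left, +1 for
#' right), responds with the sign of the decision channel, reports confidence
#' from the confidence channel (see [observer_model()]) and then advances the
#' staircase. A burn-in of `burn_in` staircase trials emulating the practice
#' titration phase is simulated first and discarded, so recorded trials start
#' near the staircase's stationary region.
#'
#' @param observer An [observer_model()].
#' @param seed Integer seed; the session is fully reproducible from it.
#' @param n_trials Number of recorded trials (default 200).
#' @param n_blocks Number of blocks (default 8, i.e. 8 x 25 trials).
#' @param burn_in Discarded staircase practice trials (default 25).
#' @param delta_d_start Staircase starting difference in dots (default 15).
#' @param subject_id,group Labels copied into the trial table.
#' @return A trial table (see [trial-table]) with `domain = "perception"` and
#'   `condition_tag` holding the trial's `delta_d`.
#' @export
simulate_perception_session <- function(observer, seed,
                                        n_trials = 200L, n_blocks = 8L,
                                        burn_in = 25L, delta_d_start = 15L,
                                        subject_id = "sim", group = "sim") {
  stopifnot(inherits(observer, "observer_model"))
  n_trials <- as.integer(n_trials)
  if (n_trials %% n_blocks != 0L) stop("`n_trials` must be a multiple of `n_blocks`")
  with_seed(seed, {
    N <- n_trials + burn_in
    stim <- sample(c(-1, 1), N, replace = TRUE)
    noise <- rnorm(N)
    dec_noise <- if (observer$decision_extra_noise_sd > 0) {
      observer$decision_extra_noise_sd * rnorm(N)
    } else {
      numeric(N)
    }
    conf_noise <- if (observer$confidence_noise_sd > 0) {
      observer$confidence_noise_sd * rnorm(N)
    } else {
      numeric(N)
    }
    lapse <- if (observer$lapse_rate > 0) runif(N) < observer$lapse_rate else logical(N)
    lapse_resp <- sample(c(-1, 1), N, replace = TRUE)

    st <- staircase_state(delta_d = delta_d_start)
    delta_d <- integer(N)
    resp <- numeric(N)
    acc <- integer(N)
    k <- observer$evidence_per_dot
    for (i in seq_len(N)) {
      delta_d[i] <- st$delta_d
      x_dec <- stim[i] * k * st$delta_d + noise[i] + dec_noise[i]
      resp[i] <- if (lapse[i]) lapse_resp[i] else if (x_dec > 0) 1 else -1
      acc[i] <- as.integer(resp[i] == stim[i])
      st <- staircase_update(st, acc[i])
    }
    x_conf <- stim * k * delta_d + noise + conf_noise
    conf <- map_confidence(x_conf * resp, observer$confidence_criteria)

    keep <- seq.int(burn_in + 1L, N)
    tibble::tibble(
      subject_id = subject_id,
      group = group,
      domain = "perception",
      block = rep(seq_len(n_blocks), each = n_trials / n_blocks),
      trial_index = seq_len(n_trials),
      stimulus_side = ifelse(stim[keep] > 0, "right", "left"),
      response_side = ifelse(resp[keep] > 0, "right", "left"),
      accuracy = acc[keep],
      confidence_raw = conf[keep],
      condition_tag = as.character(delta_d[keep])
    )
  })
}

#' Simulate a word-recognition memory session
#'
#' Generates one memory session of 2AFC old/new judgements: four 50-trial
#' blocks whose study times (0.5, 1, 1, and 1.5 minutes; order shuffled per
#' session) control memory strength. Study lists are modelled abstractly:
#' each trial pairs an old-word strength draw `N(mu_t * sqrt(2), 1)` with a
#' new-word draw `N(0, 1)`; their contrast is the trial evidence
#' `x ~ N(stim * mu_t, 1)` with `mu_t = qnorm(accuracy_t)`, so expected
#' accuracy equals the observer's `memory_accuracy` target for that study
#' time and is non-decreasing in study time. Response and confidence use the
#' same decision/confidence channels as the perception task.
#'
#' @param observer An [observer_model()].
#' @param seed Integer seed.
#' @param subject_id,group Labels copied into the trial table.
#' @param trials_per_block Trials per block (default 50).
#' @return A trial table with `domain = "memory"` and `condition_tag` holding
#'   the block's study time in minutes (`"0.5"`, `"1"`, `"1.5"`).
#' @export
simulate_memory_session <- function(observer, seed, subject_id = "sim",
                                    group = "sim", trials_per_block = 50L) {
  stopifnot(inherits(observer, "observer_model"))
  with_seed(seed, {
    study_times <- sample(c("0.5", "1", "1", "1.5"))
    n <- 4L * trials_per_block
    mu <- qnorm(observer$memory_accuracy[rep(study_times, each = trials_per_block)])
    stim <- sample(c(-1, 1), n, replace = TRUE)
    old_strength <- rnorm(n, mean = mu * sqrt(2), sd = 1)
    new_strength <- rnorm(n)
    x <- stim * (old_strength - new_strength) / sqrt(2)
    x_dec <- x + if (observer$decision_extra_noise_sd > 0) {
      observer$decision_extra_noise_sd * rnorm(n)
    } else {
      0
    }
    resp <- ifelse(x_dec > 0, 1, -1)
    if (observer$lapse_rate > 0) {
      lapse <- runif(n) < observer$lapse_rate
      resp[lapse] <- sample(c(-1, 1), sum(lapse), replace = TRUE)
    }
    x_conf <- x + if (observer$confidence_noise_sd > 0) {
      observer$confidence_noise_sd * rnorm(n)
    } else {
      0
    }
    conf <- map_confidence(x_conf * resp, observer$confidence_criteria)
    tibble::tibble(
      subject_id = subject_id,
      group = group,
      domain = "memory",
      block = rep(1:4, each = trials_per_block),
      trial_index = seq_len(n),
      stimulus_side = ifelse(stim > 0, "right", "left"),
      response_side = ifelse(resp > 0, "right", "left"),
      accuracy = as.integer(resp == stim),
      confidence_raw = conf,
      condition_tag = rep(study_times, each = trials_per_block)
    )
  })
}
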