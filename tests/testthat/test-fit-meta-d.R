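# expected (non-integer) type-2 counts computed from first principles for an
# unbiased observer with sensitivity d and type-2 criteria symmetric around 0
expected_counts <- function(d, crit = c(0.5, 1.0, 1.5), n_per_stim = 1e4) {
  K <- length(crit) + 1
  u <- c(0, crit, Inf)
  l <- c(0, -crit, -Inf)
  rows <- matrix(0, 4, K,
                 dimnames = list(c("S1_correct", "S1_incorrect",
                                   "S2_correct", "S2_incorrect"), NULL))
  for (stim in c(-1, 1)) {
    mu <- stim * d / 2
    p_s2 <- pnorm(u[-1] - mu) - pnorm(u[-(K + 1)] - mu)  # joint, resp S2
    p_s1 <- pnorm(l[-(K + 1)] - mu) - pnorm(l[-1] - mu)  # joint, resp S1
    if (stim == 1) {
      rows["S2_correct", ] <- n_per_stim * p_s2
      rows["S1_incorrect", ] <- n_per_stim * p_s1
    } else {
      rows["S2_incorrect", ] <- n_per_stim * p_s2
      rows["S1_correct", ] <- n_per_stim * p_s1
    }
  }
  rows
}

type1_manual <- function(d, c = 0, n = 2e4) {
  structure(list(d_prime = d, criterion_c = c,
                 hit_rate = pnorm(d / 2 - c), fa_rate = pnorm(-d / 2 - c),
                 n_trials = n),
            class = "type1_summary")
}

test_that("fitting model-expected counts recovers the generating meta-d'", {
  tab <- type2_counts(expected_counts(1.5))
  fit <- fit_meta_d(tab, type1_manual(1.5), padding = FALSE)
  expect_equal(fit$meta_d, 1.5, tolerance = 0.01)
  expect_equal(fit$efficiency, 1.0, tolerance = 0.01)
  expect_false(fit$excluded)
  expect_equal(fit$meta_c, 0, tolerance = 1e-6)
})

test_that("the fitted meta-d' matches the profiled grid-search oracle on a fixed table", {
  counts <- rbind(
    S1_correct = c(2, 4, 8, 16),
    S1_incorrect = c(6, 4, 2, 1),
    S2_correct = c(2, 4, 8, 16),
    S2_incorrect = c(6, 4, 2, 1)
  )
  tab <- type2_counts(counts)
  t1 <- compute_type1(counts_to_trials(tab))
  fit <- fit_meta_d(tab, t1)
  oracle <- oracle_grid_meta_d(tab, t1, lo = 0.005, hi = 5)
  expect_lt(abs(fit$meta_d - oracle$meta_d), 0.011)
  expect_gte(fit$log_likelihood, oracle$loglik - 1e-4)
})

test_that("fit matches the grid-search oracle across randomized tables", {
  set.seed(41)
  for (i in 1:10) {
    rt <- random_type2_table(seed = 4100 + i)
    fit <- fit_meta_d(rt$table, rt$type1)
    oracle <- oracle_grid_meta_d(rt$table, rt$type1)
    expect_lt(abs(fit$meta_d - oracle$meta_d), 0.011)
    expect_gte(fit$log_likelihood, oracle$loglik - 1e-3)
  }
})

test_that("type-2 criteria respect the mirror ordering and log-likelihood is valid", {
  rt <- random_type2_table(seed = 4242, conf_noise = 0.5)
  fit <- fit_meta_d(rt$table, rt$type1)
  expect_true(all(diff(fit$type2_criteria["S2", ]) >= 0))
  expect_true(all(diff(fit$type2_criteria["S1", ]) <= 0))
  expect_lte(fit$log_likelihood, 0)
  # log-likelihood equals the multinomial log-likelihood of the padded table
  # at the fitted parameters, recomputed via the independent oracle route
  counts <- rt$table$counts + 1 / (2 * rt$table$nbins)
  cprime <- rt$type1$criterion_c / rt$type1$d_prime
  ll <- oracle_loglik(fit$meta_d, fit$type2_criteria["S1", ],
                      fit$type2_criteria["S2", ], counts, cprime)
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-6)
})

test_that("left/right relabelling leaves meta-d' unchanged", {
  obs <- observer_model(confidence_noise_sd = 0.6)
  s <- simulate_perception_session(obs, seed = 77, n_trials = 400)
  flip <- function(x) ifelse(x == "left", "right", "left")
  s2 <- s
  s2$stimulus_side <- flip(s$stimulus_side)
  s2$response_side <- flip(s$response_side)
  f1 <- efficiency_from_trials(s)
  f2 <- efficiency_from_trials(s2)
  expect_equal(f1$meta_d, f2$meta_d, tolerance = 1e-6)
  expect_equal(abs(f1$criterion_c), abs(f2$criterion_c), tolerance = 1e-10)
})

test_that("efficiency_from_trials equals the four steps run by hand", {
  obs <- observer_model(confidence_noise_sd = 1)
  s <- simulate_perception_session(obs, seed = 88, n_trials = 200)
  composed <- efficiency_from_trials(s, nbins = 4)
  t1 <- compute_type1(s)
  s$confidence_bin <- bin_confidence(s$confidence_raw, 4)
  manual <- fit_meta_d(build_type2_counts(s, 4), t1)
  expect_equal(composed$meta_d, manual$meta_d)
  expect_equal(composed$log_likelihood, manual$log_likelihood)
})

test_that("degrading confidence monotonically lowers fitted efficiency", {
  obs <- observer_model()  # ideal: confidence channel = decision channel
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  means <- numeric(length(fracs))
  set.seed(42)
  n_rep <- 4
  effs <- matrix(NA_real_, n_rep, length(fracs))
  for (r in seq_len(n_rep)) {
    s <- simulate_perception_session(obs, seed = 9000 + r, n_trials = 3000,
                                     n_blocks = 1)
    scramble_order <- sample(nrow(s))
    random_conf <- runif(nrow(s), 1, 6)
    for (j in seq_along(fracs)) {
      sj <- s
      idx <- scramble_order[seq_len(floor(fracs[j] * nrow(s)))]
      sj$confidence_raw[idx] <- random_conf[idx]  # nested replacement sets
      effs[r, j] <- efficiency_from_trials(sj)$efficiency
    }
  }
  means <- colMeans(effs)
  expect_true(all(diff(means) <= 0.02))
  expect_lt(means[length(fracs)], 0.25)
  expect_gt(means[1], 0.85)
})

test_that("shuffling confidence across trials destroys efficiency on average", {
  obs <- observer_model()
  s <- simulate_perception_session(obs, seed = 91, n_trials = 1000, n_blocks = 1)
  base_eff <- efficiency_from_trials(s)$efficiency
  set.seed(43)
  shuffled <- replicate(20, {
    s2 <- s
    s2$confidence_raw <- sample(s2$confidence_raw)
    efficiency_from_trials(s2)$efficiency
  })
  expect_lt(mean(shuffled), base_eff - 0.4)
})

test_that("non-positive d', degenerate tables and negative meta-d' are flagged", {
  # below-chance observer: d' < 0
  s <- tibble::tibble(
    stimulus_side = rep(c("left", "right"), each = 50),
    response_side = c(rep("right", 35), rep("left", 15),
                      rep("left", 35), rep("right", 15))
  )
  s$accuracy <- as.integer(s$stimulus_side == s$response_side)
  s$confidence_raw <- runif(100, 1, 6)
  fit <- efficiency_from_trials(s)
  expect_equal(fit$quality, "type1_nonpositive")
  expect_true(is.na(fit$efficiency))
  expect_true(fit$excluded)

  # all mass in a single cell
  tab <- type2_counts(rbind(S1_correct = c(0, 0, 0, 0), S1_incorrect = c(0, 0, 0, 0),
                            S2_correct = c(0, 0, 0, 50), S2_incorrect = c(0, 0, 0, 0)))
  fit <- fit_meta_d(tab, type1_manual(1))
  expect_equal(fit$quality, "degenerate")
  expect_true(is.na(fit$efficiency))

  # confidence anti-correlated with accuracy: negative meta-d', retained but
  # excluded from log-based analyses
  counts <- rbind(S1_correct = c(16, 8, 4, 2), S1_incorrect = c(1, 2, 4, 6),
                  S2_correct = c(16, 8, 4, 2), S2_incorrect = c(1, 2, 4, 6))
  tab <- type2_counts(counts)
  t1 <- compute_type1(counts_to_trials(tab))
  fit <- fit_meta_d(tab, t1)
  expect_lt(fit$meta_d, 0)
  expect_true(is.na(fit$log_efficiency))
  expect_true(fit$excluded)
})
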