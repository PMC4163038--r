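# Independent reference route to the meta-d' model, used to validate the
# package's maximum-likelihood fit: the response-conditional multinomial
# log-likelihood is recoded here from the model definition (joint interval
# probabilities normalized by the response probability), and meta_d is found
# by a profiled grid search (criteria re-optimized at every grid point with
# a Nelder-Mead simplex) instead of the package's bounded quasi-Newton
# search.

oracle_loglik <- function(meta_d, crit_s1, crit_s2, counts, cprime) {
  mc <- cprime * meta_d
  K <- ncol(counts)
  ll <- 0
  for (stim in c(-1, 1)) {
    mu <- stim * meta_d / 2
    u <- c(mc, crit_s2, Inf)          # ascending S2-side boundaries
    l <- c(mc, crit_s1, -Inf)         # descending S1-side boundaries
    p_s2 <- pnorm(u[-1] - mu) - pnorm(u[-(K + 1)] - mu)
    p_s1 <- pnorm(l[-(K + 1)] - mu) - pnorm(l[-1] - mu)
    p_resp_s2 <- 1 - pnorm(mc - mu)
    p_resp_s1 <- pnorm(mc - mu)
    p_s2 <- pmax(p_s2 / p_resp_s2, 1e-12)
    p_s1 <- pmax(p_s1 / p_resp_s1, 1e-12)
    if (stim == -1) {
      ll <- ll + sum(counts["S1_correct", ] * log(p_s1)) +
        sum(counts["S2_incorrect", ] * log(p_s2))
    } else {
      ll <- ll + sum(counts["S1_incorrect", ] * log(p_s1)) +
        sum(counts["S2_correct", ] * log(p_s2))
    }
  }
  ll
}

# profile out the criteria at fixed meta_d (Nelder-Mead on log-increments)
oracle_profile <- function(meta_d, counts, cprime, start = NULL) {
  K <- ncol(counts)
  start <- start %||% rep(log(0.5), 2 * (K - 1))
  obj <- function(par) {
    mc <- cprime * meta_d
    cs1 <- mc - cumsum(exp(par[seq_len(K - 1)]))
    cs2 <- mc + cumsum(exp(par[K:(2 * (K - 1))]))
    -oracle_loglik(meta_d, cs1, cs2, counts, cprime)
  }
  res <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-9))
  list(loglik = -res$value, par = res$par)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# coarse-to-fine profiled grid search for the ML meta_d
oracle_grid_meta_d <- function(table, type1, pad = TRUE,
                               lo = -2, hi = 5, coarse = 0.1, fine = 0.005) {
  counts <- table$counts
  if (pad) counts <- counts + 1 / (2 * table$nbins)
  cprime <- type1$criterion_c / type1$d_prime
  search <- function(grid, start) {
    best <- NULL
    for (md in grid) {
      pr <- oracle_profile(md, counts, cprime, start)
      start <- pr$par  # warm start along the grid
      if (is.null(best) || pr$loglik > best$loglik) {
        best <- list(meta_d = md, loglik = pr$loglik, par = pr$par)
      }
    }
    best
  }
  b1 <- search(seq(lo, hi, by = coarse), NULL)
  b2 <- search(seq(b1$meta_d - 1.5 * coarse, b1$meta_d + 1.5 * coarse, by = fine),
               b1$par)
  if (b2$loglik >= b1$loglik) b2 else b1
}

# random plausible type-2 count table: simulate a small session from the
# generative observer and tabulate it
random_type2_table <- function(seed, n_trials = 200,
                               conf_noise = NULL, dec_noise = 0) {
  conf_noise <- conf_noise %||% runif(1, 0, 1.5)
  obs <- observer_model(confidence_noise_sd = conf_noise,
                        decision_extra_noise_sd = dec_noise)
  s <- simulate_perception_session(obs, seed = seed, n_trials = n_trials,
                                   n_blocks = 1L)
  s$confidence_bin <- bin_confidence(s$confidence_raw, 4)
  list(table = build_type2_counts(s, 4), type1 = compute_type1(s))
}
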