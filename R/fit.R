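#' Maximum-likelihood meta-d' fit
#'
#' Fits the equal-variance Gaussian meta-d' model to a type-2 count table:
#' the value of type-1 sensitivity that an SDT-ideal metacognitive observer
#' would need in order to produce the observed confidence counts, given the
#' observer's actual response bias. The model places evidence at
#' `N(-meta_d/2, 1)` (S1 stimuli) and `N(+meta_d/2, 1)` (S2), holds the
#' type-1 criterion at the same *relative* position as the empirical one
#' (`meta_c = (c/d') * meta_d`) and maximizes the multinomial likelihood of
#' the confidence bins conditional on the response, jointly over `meta_d` and
#' the `2 * (nbins - 1)` response-conditional type-2 criteria.
#'
#' Numerical strategy: criteria are parameterized as ordered log-spaced
#' increments away from `meta_c` (so the mirror ordering can never be
#' violated), `meta_d` is searched within \[-5, 5\], and the optimizer is
#' restarted from three fixed initial points, keeping the best converged
#' solution. Before fitting, `1 / (2 * nbins)` is added to every cell so that
#' empty cells cannot degenerate the likelihood.
#'
#' @param table A [type2_counts] object.
#' @param type1 The [compute_type1()] summary of the same trials.
#' @param padding Add `1/(2*nbins)` to every cell before fitting
#'   (default `TRUE`).
#' @return An object of class `meta_d_fit` with elements
#'   `meta_d`, `type2_criteria` (2 x `nbins - 1` matrix, rows `S1`/`S2`,
#'   ordered outward from the criterion), `meta_c` (the constrained type-1
#'   criterion `c * meta_d / d'`), `log_likelihood`, `efficiency`
#'   (`meta_d / d_prime`), `log_efficiency` (natural log, `NA` and flagged
#'   `excluded` when efficiency is not positive), `excluded`, `quality`
#'   (`"ok"`, `"bound"`, `"degenerate"` or `"type1_nonpositive"`), plus the
#'   type-1 quantities.
#' @examples
#' counts <- type2_counts(rbind(
#'   S1_correct = c(2, 4, 8, 16), S1_incorrect = c(6, 4, 2, 1),
#'   S2_correct = c(2, 4, 8, 16), S2_incorrect = c(6, 4, 2, 1)
#' ))
#' type1 <- compute_type1(counts_to_trials(counts))
#' fit_meta_d(counts, type1)
#' @export
fit_meta_d <- function(table, type1, padding = TRUE) {
  stopifnot(inherits(table, "type2_counts"), inherits(type1, "type1_summary"))
  K <- table$nbins
  counts <- table$counts
  if (padding) counts <- counts + 1 / (2 * K)

  d <- type1$d_prime
  out <- list(
    meta_d = NA_real_, type2_criteria = NULL, meta_c = NA_real_,
    log_likelihood = NA_real_, efficiency = NA_real_,
    log_efficiency = NA_real_, excluded = TRUE, quality = "ok",
    d_prime = d, criterion_c = type1$criterion_c,
    nbins = K, n_total = table$n_total
  )

  if (!is.finite(d) || d <= 0) {
    out$quality <- "type1_nonpositive"
    return(structure(out, class = "meta_d_fit"))
  }
  if (sum(table$counts > 0) <= 1L) {
    out$quality <- "degenerate"
    return(structure(out, class = "meta_d_fit"))
  }

  cprime <- type1$criterion_c / d
  n_par <- 1L + 2L * (K - 1L)
  obj <- function(par) type2_nll_cpp(par, counts, cprime)

  # three fixed starting points: at the type-1 estimate, at half of it, and
  # at a generic moderate sensitivity
  starts <- list(
    c(min(max(d, -4.9), 4.9), rep(log(0.5), 2L * (K - 1L))),
    c(min(max(d / 2, 0.05), 4.9), rep(log(0.3), 2L * (K - 1L))),
    c(1.5, rep(log(0.8), 2L * (K - 1L)))
  )
  lower <- c(-5, rep(-7, n_par - 1L))
  upper <- c(5, rep(3, n_par - 1L))
  best <- NULL
  diags <- character()
  for (s0 in starts) {
    res <- tryCatch(
      nlminb(s0, obj, lower = lower, upper = upper,
             control = list(rel.tol = 1e-10, abs.tol = 1e-12, iter.max = 500L)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    diags <- c(diags, sprintf("start meta_d=%.2f: convergence=%d (%s)",
                              s0[1], res$convergence, res$message))
    if (!is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) {
    stop(errorCondition(
      paste0("meta-d' optimizer failed to converge from all starts:\n",
             paste(diags, collapse = "\n")),
      class = c("mratio_fit_error", "error")
    ))
  }

  md <- best$par[1]
  mc <- cprime * md
  incr <- exp(best$par[-1])
  t_s1 <- mc - cumsum(incr[seq_len(K - 1L)])
  t_s2 <- mc + cumsum(incr[K:(2L * (K - 1L))])
  out$meta_d <- md
  out$meta_c <- mc
  out$type2_criteria <- rbind(S1 = t_s1, S2 = t_s2)
  colnames(out$type2_criteria) <- paste0("t", seq_len(K - 1L))
  out$log_likelihood <- -best$objective
  out$efficiency <- md / d
  if (abs(md) >= 5 - 1e-3) out$quality <- "bound"
  if (out$efficiency > 0) {
    out$log_efficiency <- log(out$efficiency)
    out$excluded <- FALSE
  }
  structure(out, class = "meta_d_fit")
}

#' @export
print.meta_d_fit <- function(x, ...) {
  cat(sprintf(
    "meta-d' fit: meta_d = %.3f, d' = %.3f, meta-d'/d' = %.3f (logL = %.2f, quality = %s)\n",
    x$meta_d, x$d_prime, x$efficiency, x$log_likelihood, x$quality
  ))
  if (x$excluded) {
    cat("  efficiency not positive (or fit degenerate): excluded from log-based analyses\n")
  }
  invisible(x)
}

#' Expand a type-2 count table into pseudo-trials
#'
#' Reconstructs a trial table (one row per counted trial) from a
#' [type2_counts] object, e.g. to compute the type-1 summary that a count
#' table implies. Requires integer counts.
#'
#' @param table A [type2_counts] object.
#' @return A tibble with `stimulus_side`, `response_side`, `accuracy` and
#'   `confidence_bin`.
#' @export
counts_to_trials <- function(table) {
  stopifnot(inherits(table, "type2_counts"))
  cn <- table$counts
  if (any(cn != round(cn))) stop("counts_to_trials() needs integer counts")
  rows <- expand.grid(row = rownames(cn), bin = seq_len(ncol(cn)),
                      stringsAsFactors = FALSE)
  n <- as.vector(cn[cbind(match(rows$row, rownames(cn)), rows$bin)])
  resp <- ifelse(grepl("^S1", rows$row), "left", "right")
  correct <- grepl("correct$", rows$row) & !grepl("incorrect$", rows$row)
  stim <- ifelse(correct, resp, ifelse(resp == "left", "right", "left"))
  idx <- rep.int(seq_len(nrow(rows)), n)
  tibble::tibble(
    stimulus_side = stim[idx],
    response_side = resp[idx],
    accuracy = as.integer(correct)[idx],
    confidence_bin = rows$bin[idx]
  )
}

#' Per-session metacognitive efficiency
#'
#' Convenience composition for one subject and one task domain: type-1
#' estimation, within-session quantile binning of confidence, type-2 count
#' construction and the meta-d' fit.
#'
#' @param trials Trial table for a single subject and domain (see
#'   [trial-table]; only `stimulus_side`, `response_side`, `accuracy` and
#'   `confidence_raw` are used).
#' @param nbins Number of confidence quantile bins (default 4).
#' @return A `meta_d_fit` (see [fit_meta_d()]).
#' @export
efficiency_from_trials <- function(trials, nbins = 4L) {
  type1 <- compute_type1(trials)
  trials$confidence_bin <- bin_confidence(trials$confidence_raw, nbins)
  table <- build_type2_counts(trials, nbins)
  fit_meta_d(table, type1)
}
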