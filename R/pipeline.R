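#' Fit every subject and domain of a trial table
#'
#' Runs [efficiency_from_trials()] once per subject x domain.
#'
#' @param trials A validated trial table covering one or more subjects.
#' @param nbins Confidence quantile bins (default 4).
#' @return A tibble with one row per subject x domain: `subject_id`,
#'   `group`, `domain`, `n_trials`, `d_prime`, `criterion_c`, `meta_d`,
#'   `efficiency`, `log_efficiency`, `excluded_flag`, `loglik`, `quality`.
#' @export
fit_cohort <- function(trials, nbins = 4L) {
  keys <- unique(trials[, c("subject_id", "group", "domain")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    df <- trials[trials$subject_id == keys$subject_id[i] &
                   trials$domain == keys$domain[i], ]
    fit <- efficiency_from_trials(df, nbins = nbins)
    tibble::tibble(
      subject_id = keys$subject_id[i], group = keys$group[i],
      domain = keys$domain[i], n_trials = nrow(df),
      d_prime = fit$d_prime, criterion_c = fit$criterion_c,
      meta_d = fit$meta_d, efficiency = fit$efficiency,
      log_efficiency = fit$log_efficiency, excluded_flag = fit$excluded,
      loglik = fit$log_likelihood, quality = fit$quality
    )
  })
  dplyr::bind_rows(rows)
}

# Task-performance descriptives per group (and per study time for memory),
# feeding the report.
summarize_performance <- function(trials) {
  trials <- tibble::as_tibble(trials)
  perc <- trials[trials$domain == "perception", ]
  mem <- trials[trials$domain == "memory", ]
  per_subject <- function(df, extra = NULL) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c("group", "subject_id", extra)))) |>
      dplyr::summarise(
        pct_correct = 100 * mean(.data$accuracy),
        confidence = mean(.data$confidence_raw),
        delta_d = mean(suppressWarnings(as.numeric(.data$condition_tag))),
        .groups = "drop"
      )
  }
  list(
    perception = per_subject(perc),
    memory_by_time = if (nrow(mem)) per_subject(mem, "condition_tag") else NULL
  )
}

#' Run the full metacognition analysis
#'
#' End-to-end composition: validation, per-subject meta-d' fits in both
#' domains, the exclusion rule, the domain-general index, subject-resampled
#' bootstrap CIs, group tests and the permutation interaction test, plus a
#' plain-text report of group means and SDs in the conventional layout
#' (per-domain percent correct, confidence, meta-d'/d', staircase
#' difficulty, domain-general index). Deterministic given
#' `config$seed`.
#'
#' @param trials Trial table covering both domains (see [trial-table]).
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `fits.csv`,
#'   `subjects.csv`, `exclusions.csv`, `group_tests.csv`, `report.md` and
#'   `config.yaml` there.
#' @param interaction_groups Optional subset of groups for the interaction
#'   test.
#' @return An object of class `mratio_analysis`: list with `fits`,
#'   `subjects`, `exclusions`, `groups` (a `group_result` or `NULL` when
#'   fewer than two groups are available), `performance`, `report`
#'   (character vector of report lines) and `config`.
#' @export
run_full_analysis <- function(trials, config = run_config(), out_dir = NULL,
                              interaction_groups = NULL) {
  trials <- validate_trials(trials)
  fits <- fit_cohort(trials, nbins = config$nbins)
  excl <- apply_exclusions(fits, log_base = config$log_base)
  groups <- group_tests(excl$subjects, config = config,
                        interaction_groups = interaction_groups)
  performance <- summarize_performance(trials)
  result <- structure(
    list(fits = fits, subjects = excl$subjects, exclusions = excl$exclusions,
         groups = groups, performance = performance, config = config),
    class = "mratio_analysis"
  )
  result$report <- format_report(result)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fit_results(fits, file.path(out_dir, "fits.csv"))
    write.csv(as.data.frame(excl$subjects), file.path(out_dir, "subjects.csv"),
              row.names = FALSE, quote = FALSE, eol = "\n")
    write.csv(as.data.frame(excl$exclusions), file.path(out_dir, "exclusions.csv"),
              row.names = FALSE, quote = TRUE, eol = "\n")
    write.csv(as.data.frame(groups$tests), file.path(out_dir, "group_tests.csv"),
              row.names = FALSE, quote = TRUE, eol = "\n")
    writeLines(result$report, file.path(out_dir, "report.md"))
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  result
}

#' @export
print.mratio_analysis <- function(x, ...) {
  writeLines(x$report)
  invisible(x)
}
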