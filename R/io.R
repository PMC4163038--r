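#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline. Defaults follow the
#' standard settings for this design: 4 confidence quantile bins, 100,000
#' bootstrap resamples, 95% CIs, 10,000 interaction permutations, natural
#' logarithms.
#'
#' @param nbins Confidence quantile bins.
#' @param n_resamples Bootstrap resamples.
#' @param ci_level Bootstrap CI level.
#' @param permutations Interaction-test permutations.
#' @param seed Master seed; every random step derives its own stream from it.
#' @param log_base Base of the log-efficiency transform.
#' @return An object of class `run_config`.
#' @export
run_config <- function(nbins = 4L, n_resamples = 100000L, ci_level = 0.95,
                       permutations = 10000L, seed = 1L, log_base = exp(1)) {
  stopifnot(nbins >= 2, n_resamples >= 1, ci_level > 0, ci_level < 1,
            permutations >= 1)
  structure(
    list(nbins = as.integer(nbins), n_resamples = as.integer(n_resamples),
         ci_level = ci_level, permutations = as.integer(permutations),
         seed = as.integer(seed), log_base = log_base),
    class = "run_config"
  )
}

#' Read or write a configuration file (YAML)
#'
#' @param path File path.
#' @return `read_config()` returns a [run_config()]; `write_config()` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' @param config A [run_config()].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a trial table from a delimited text file
#'
#' Reads a comma-separated, UTF-8, one-header-row trial table and validates
#' it against the schema (see [trial-table]); schema violations are listed
#' with their row numbers.
#'
#' @param path File path.
#' @return A validated trial tibble.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  chr_cols <- c("subject_id", "group", "domain", "stimulus_side",
                "response_side", "condition_tag")
  for (col in intersect(chr_cols, names(raw))) {
    raw[[col]] <- as.character(raw[[col]])
  }
  validate_trials(raw)
}

#' Write a trial table to a delimited text file
#'
#' Comma-separated, UTF-8, LF line endings, full ("round-trip") numeric
#' precision.
#'
#' @param trials A trial table.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_trials <- function(trials, path) {
  df <- as.data.frame(validate_trials(trials))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
            eol = "\n")
  invisible(path)
}

#' Write per-subject fit results
#'
#' One row per subject x domain with type-1 and type-2 estimates, as
#' comma-separated text.
#'
#' @param fits Fit table from [fit_cohort()] or [run_full_analysis()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  write.csv(as.data.frame(fits), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
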