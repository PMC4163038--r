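# Internal helpers: seeding and error conditions.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  code
}

# Deterministically derive a sub-seed (< 2^31) from a master seed and any
# number of integer indices, so that every simulated unit (subject, domain,
# resample) has its own reproducible stream.
derive_seed <- function(seed, ...) {
  m <- 2147483629  # large prime < 2^31
  h <- as.double(seed %% m)
  for (v in c(...)) {
    h <- (h * 48271 + as.double(v) + 1) %% m
  }
  as.integer(h)
}

abort_validation <- function(msg, problems = NULL) {
  if (!is.null(problems)) {
    shown <- head(problems, 20L)
    msg <- paste0(
      msg, "\n", paste0("  - ", shown, collapse = "\n"),
      if (length(problems) > 20L) {
        sprintf("\n  ... and %d more problems", length(problems) - 20L)
      }
    )
  }
  stop(errorCondition(msg, class = c("mratio_validation_error", "error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
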