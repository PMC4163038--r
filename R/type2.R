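#' Type-2 count table
#'
#' Cross-classifies trials by response, accuracy and confidence bin. The
#' resulting 4 x `nbins` table of counts is the sufficient statistic for the
#' meta-d' fit: rows are `S1_correct`, `S1_incorrect`, `S2_correct`,
#' `S2_incorrect` (S1 = `"left"` response, S2 = `"right"` response), columns
#' are confidence bins from lowest to highest.
#'
#' @param trials A data frame with columns `response_side`, `accuracy` and
#'   `confidence_bin` (integer bins from [bin_confidence()]).
#' @param nbins Number of confidence bins; defaults to the maximum bin
#'   present.
#' @return A `type2_counts` object.
#' @seealso [type2_counts()] to build a table directly from counts.
#' @export
build_type2_counts <- function(trials, nbins = NULL) {
  if (!("confidence_bin" %in% names(trials)) || anyNA(trials$confidence_bin)) {
    stop("`trials` must carry a complete `confidence_bin` column; run bin_confidence() first")
  }
  bin <- as.integer(trials$confidence_bin)
  nbins <- as.integer(nbins %||% max(bin))
  if (any(bin < 1L) || any(bin > nbins)) {
    stop(sprintf("`confidence_bin` values must lie in 1..%d", nbins))
  }
  resp <- trials$response_side
  acc <- trials$accuracy
  counts <- rbind(
    S1_correct   = tabulate(bin[resp == "left" & acc == 1], nbins),
    S1_incorrect = tabulate(bin[resp == "left" & acc == 0], nbins),
    S2_correct   = tabulate(bin[resp == "right" & acc == 1], nbins),
    S2_incorrect = tabulate(bin[resp == "right" & acc == 0], nbins)
  )
  type2_counts(counts)
}

#' Construct a type-2 count table from a matrix
#'
#' @param counts A 4 x `nbins` matrix (or something coercible) with rows
#'   `S1_correct`, `S1_incorrect`, `S2_correct`, `S2_incorrect` and columns
#'   ordered from lowest to highest confidence. Non-negative, possibly
#'   non-integer (e.g. model-expected) counts are accepted.
#' @return A `type2_counts` object: list with `counts`, `nbins`, `n_total`.
#' @export
type2_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) {
    stop("`counts` must have 4 rows: S1_correct, S1_incorrect, S2_correct, S2_incorrect")
  }
  if (ncol(counts) < 2L) {
    stop("`counts` must have at least 2 confidence bins")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("all cells of `counts` must be finite and non-negative")
  }
  rownames(counts) <- c("S1_correct", "S1_incorrect", "S2_correct", "S2_incorrect")
  colnames(counts) <- paste0("bin", seq_len(ncol(counts)))
  structure(
    list(counts = counts, nbins = ncol(counts), n_total = sum(counts)),
    class = "type2_counts"
  )
}

#' @export
print.type2_counts <- function(x, ...) {
  cat(sprintf("Type-2 count table (%d bins, %g trials)\n", x$nbins, x$n_total))
  print(x$counts)
  invisible(x)
}
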