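#' Quantile-bin continuous confidence ratings
#'
#' Assigns each rating to one of `nbins` within-subject empirical quantile
#' bins, pooled over responses and blocks. With all-distinct ratings the bin
#' sizes differ by at most one. Ties are handled deterministically: tied
#' ratings share the bin that the first (lowest-ranked) member of the tie
#' group would occupy, i.e. a tie group straddling a quantile boundary is
#' assigned as a whole to the lower bin. The mapping is monotone in the
#' rating.
#'
#' @param confidence_raw Numeric vector of ratings on the 1-6 slider scale.
#' @param nbins Number of quantile bins (default 4, the standard choice for
#'   confidence analyses of this design).
#' @return Integer vector of bin indices in `1:nbins`.
#' @examples
#' bin_confidence(c(1, 2, 3, 4, 5, 5.5, 5.8, 6), nbins = 4)
#' @export
bin_confidence <- function(confidence_raw, nbins = 4L) {
  nbins <- as.integer(nbins)
  if (length(nbins) != 1L || is.na(nbins) || nbins < 2L) {
    stop("`nbins` must be a single integer >= 2")
  }
  n <- length(confidence_raw)
  if (n < nbins) {
    stop(sprintf("need at least `nbins` = %d trials to form quantile bins (got %d)", nbins, n))
  }
  if (anyNA(confidence_raw) ||
      any(confidence_raw < 1 - 1e-9) || any(confidence_raw > 6 + 1e-9)) {
    stop("`confidence_raw` must lie in [1, 6] with no missing values")
  }
  if (length(unique(confidence_raw)) == 1L) {
    warning("constant confidence vector: all trials assigned to bin 1")
    return(rep(1L, n))
  }
  # lowest rank of each tie group -> bin of that rank position
  r <- rank(confidence_raw, ties.method = "min")
  pmin.int(nbins, pmax.int(1L, as.integer(ceiling(r * nbins / n))))
}
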