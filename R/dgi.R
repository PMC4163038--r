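#' Domain-general index
#'
#' `DGI = |log(Mp) - log(Mm)|`: the absolute log-difference between a
#' subject's perceptual efficiency `Mp` (perceptual meta-d'/d') and memory
#' efficiency `Mm`. Zero means identical metacognitive efficiency in both
#' domains; larger values mean a greater cross-domain dissociation. Natural
#' logarithms are used by default; the index is symmetric in its arguments
#' and invariant to which domain is the numerator of the underlying ratios.
#'
#' @param mp,mm Positive efficiencies (vectorized).
#' @param base Logarithm base (default `exp(1)`; the index scales by
#'   `1/log(base)` for any other choice).
#' @return `|log(mp) - log(mm)|`.
#' @examples
#' dgi(0.5, 1.0)  # log(2)
#' @export
dgi <- function(mp, mm, base = exp(1)) {
  if (any(!is.finite(mp)) || any(!is.finite(mm)) || any(mp <= 0) || any(mm <= 0)) {
    stop("dgi() is undefined for non-positive efficiencies; ",
         "such subjects are excluded from log-based analyses")
  }
  abs(log(mp, base = base) - log(mm, base = base))
}
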