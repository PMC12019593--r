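#' Olfactory sensory neuron relay
#'
#' OSN-to-ET connections are simple relays with weight 1: the glomerular
#' layer receives the raw sensor vector unchanged.
#'
#' @param raw Numeric vector of raw sensor responses.
#' @return `raw`, unchanged.
#' @export
osn_relay <- function(raw) {
  stopifnot(is.numeric(raw), all(is.finite(raw)))
  raw
}

#' Divisive (l1) normalization of the ET layer
#'
#' Lateral shunting inhibition among external tufted cells implements
#' `ET(x) = x / ||x||_1`: output proportions equal input proportions and sum
#' to 1 for any nonzero input. This is the concentration-invariance
#' mechanism — scaling the input by any positive constant leaves the output
#' unchanged. The normalization is computed algebraically at its fixed point
#' rather than by simulating the inhibitory dynamics. An all-zero (rinse)
#' input maps to an all-zero output.
#'
#' @param x Nonnegative, finite numeric vector of relayed sensor responses.
#' @return Numeric vector of ET activations summing to 1 (or all zeros).
#' @examples
#' normalize_l1(c(1, 0, 0, 0, 0, 0, 0, 3))  # 0.25, 0, ..., 0.75
#' @export
normalize_l1 <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (any(x < 0)) stop("ET input must be nonnegative.", call. = FALSE)
  s <- sum(x)
  if (s == 0) return(x * 0)
  x / s
}
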