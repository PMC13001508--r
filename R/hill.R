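#' EC10/EC90-based Hill coefficient
#'
#' Quantifies the steepness of a sigmoidal dose-response curve as
#' \deqn{n_H = \log(81) / \log(EC90 / EC10)}
#' where EC10 and EC90 are the input levels producing 10% and 90% of the
#' maximal response after min-max normalization of the curve to \[0, 1\].
#' For an exact Hill function \eqn{x^n / (x^n + K^n)} this recovers the
#' exponent \eqn{n} exactly (EC90/EC10 = 81^{1/n}).
#'
#' The curve must be monotone after normalization; decreasing curves are
#' accepted and flipped (\code{1 - y}) so that EC10 < EC90 on the input
#' axis. EC levels are located by piecewise-linear interpolation of
#' \code{log(xs)} against the normalized response.
#'
#' @param xs Strictly increasing, strictly positive input levels
#'   (concentrations / relative protein levels).
#' @param ys Response values at \code{xs}.
#' @param tol Numerical slack allowed for monotonicity violations of the
#'   normalized curve (default \code{1e-9}).
#' @return The Hill coefficient (a single positive number).
#' @examples
#' x <- 10^seq(-3, 3, length.out = 2001)
#' hill_coefficient_ec(x, x^3 / (x^3 + 1)) # ~ 3
#' @export
hill_coefficient_ec <- function(xs, ys, tol = 1e-9) {
  stopifnot(is.numeric(xs), is.numeric(ys), length(xs) == length(ys))
  if (length(xs) < 3L) stop("need at least 3 points to locate EC10/EC90")
  if (any(!is.finite(xs)) || any(!is.finite(ys))) stop("non-finite input")
  if (any(xs <= 0)) stop("input levels must be strictly positive")
  if (any(diff(xs) <= 0)) stop("input levels must be strictly increasing")
  rng <- max(ys) - min(ys)
  if (rng == 0) stop("flat response: Hill coefficient undefined")
  y <- (ys - min(ys)) / rng
  d <- diff(y)
  if (all(d >= -tol)) {
    # non-decreasing
  } else if (all(d <= tol)) {
    y <- 1 - y
  } else {
    stop("normalized response is not monotone")
  }
  lx <- log(xs)
  ec <- stats::approx(y, lx, xout = c(0.1, 0.9), ties = "ordered")$y
  if (any(is.na(ec))) {
    stop("EC10 or EC90 falls outside the sampled input range")
  }
  log(81) / (ec[2L] - ec[1L])
}
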