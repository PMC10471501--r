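#' Box-Cox transformation with maximum-likelihood lambda
#'
#' `boxcox_lambda()` maximises the Box-Cox profile log-likelihood of a
#' positive sample over lambda in `interval` (ties in a flat profile break
#' toward 1, the identity). `boxcox_transform()` applies
#' \eqn{(x^\lambda - 1)/\lambda} (or \eqn{\ln x} at \eqn{\lambda = 0}).
#'
#' @param x strictly positive values.
#' @param interval search interval for lambda.
#' @param region optional label used in error messages.
#' @return `boxcox_lambda()`: the ML lambda (scalar).
#' @export
boxcox_lambda <- function(x, interval = c(-2, 2), region = NULL) {
  if (any(!is.finite(x) | x <= 0))
    stop_arg(sprintf("Box-Cox requires strictly positive values%s",
                     if (is.null(region)) "" else
                       sprintf(" (region %s)", region)))
  lx <- log(x)
  n <- length(x)
  prof <- function(lam) {
    y <- boxcox_transform(x, lam)
    -n / 2 * log(stats::var(y) * (n - 1) / n) + (lam - 1) * sum(lx)
  }
  opt <- stats::optimize(prof, interval, maximum = TRUE, tol = 1e-6)
  # flat profile (e.g. near-constant data): prefer the identity transform
  if (abs(prof(1) - opt$objective) < 1e-8) 1 else opt$maximum
}

#' @rdname boxcox_lambda
#' @param lambda transformation parameter.
#' @return `boxcox_transform()`: transformed values.
#' @export
boxcox_transform <- function(x, lambda, region = NULL) {
  if (any(!is.finite(x) | x <= 0))
    stop_arg(sprintf("Box-Cox requires strictly positive values%s",
                     if (is.null(region)) "" else
                       sprintf(" (region %s)", region)))
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

# Inverse transform (used by simulate.normative).
boxcox_inverse <- function(y, lambda) {
  if (abs(lambda) < 1e-12) exp(y) else (lambda * y + 1)^(1 / lambda)
}
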