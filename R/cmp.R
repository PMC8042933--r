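## Conway-Maxwell-Poisson (CMP) distribution, mean parameterization, and the
## zero-inflated mixtures used by the fitness models.
##
## The CMP pmf is P(Y = y) = lambda^y / (y!)^nu / Z(lambda, nu) with
## Z(lambda, nu) = sum_{j>=0} lambda^j / (j!)^nu.  nu = 1 recovers the Poisson,
## nu < 1 gives overdispersion, nu > 1 underdispersion.  The mean
## parameterization solves lambda from a target mean mu by Newton iteration so
## that regression coefficients act on the log-mean scale.

# Truncation point for the CMP series: generous for the small counts handled
# here (recruits, grand-offspring); tail terms beyond it are below 1e-12 for
# the parameter ranges the package uses.
cmp_trunc <- function(lambda, nu) {
  mode <- max(lambda)^(1 / nu)
  max(100L, as.integer(ceiling(10 * mode + 50)))
}

#' Log normalizing constant of the Conway-Maxwell-Poisson distribution
#'
#' Computes \eqn{\log Z(\lambda, \nu)} with
#' \eqn{Z(\lambda,\nu) = \sum_{j \ge 0} \lambda^j / (j!)^\nu}, summed in log
#' space and truncated once the tail is negligible.
#'
#' @param lambda Positive rate parameter(s); vectorized.
#' @param nu Positive dispersion parameter (scalar). `nu = 1` gives the
#'   Poisson identity `log Z = lambda`.
#' @param tol Tail tolerance for the series truncation.
#' @return Numeric vector of `log Z` values, one per element of `lambda`.
#' @examples
#' cmp_log_normalizer(2, 1)            # = 2 (Poisson identity)
#' exp(cmp_log_normalizer(2, 2))       # approx 4.2525
#' @export
cmp_log_normalizer <- function(lambda, nu, tol = 1e-12) {
  if (any(lambda <= 0) || length(nu) != 1L || nu <= 0 || tol <= 0)
    stop_bad_arg("cmp_log_normalizer() needs lambda > 0, scalar nu > 0, tol > 0")
  jmax <- cmp_trunc(lambda, nu)
  j <- 0:jmax
  lt <- outer(log(lambda), j) - rep(nu * lgamma(j + 1), each = length(lambda))
  row_logsumexp(lt)
}

# log Z, mean and variance of CMP(lambda, nu) in one pass (vectorized over
# lambda).  Used by the Newton solver and by the fitness likelihoods.
cmp_moments <- function(lambda, nu) {
  jmax <- cmp_trunc(lambda, nu)
  j <- 0:jmax
  lt <- outer(log(lambda), j) - rep(nu * lgamma(j + 1), each = length(lambda))
  mx <- apply(lt, 1L, max)
  w <- exp(lt - mx)
  sw <- rowSums(w)
  m1 <- rowSums(w * rep(j, each = length(lambda))) / sw
  m2 <- rowSums(w * rep(j^2, each = length(lambda))) / sw
  list(logZ = mx + log(sw), mean = m1, var = pmax(m2 - m1^2, 1e-12))
}

#' Solve the CMP rate parameter from a target mean
#'
#' Inverts the mean map of the Conway-Maxwell-Poisson distribution by Newton
#' iteration on \eqn{\log\lambda} (the mean is strictly increasing in
#' \eqn{\lambda}), starting from the asymptotic approximation
#' \eqn{\lambda \approx (\mu + (\nu-1)/(2\nu))^\nu}.
#'
#' @param mu Positive target mean(s); vectorized.
#' @param nu Positive dispersion parameter (scalar).
#' @param tol Convergence tolerance on the mean.
#' @param max_iter Maximum Newton iterations before the failure is signalled.
#' @return Vector of `lambda` values with attribute `"iterations"`.
#' @export
cmp_lambda_from_mu <- function(mu, nu, tol = 1e-10, max_iter = 50L) {
  if (any(mu <= 0) || length(nu) != 1L || nu <= 0)
    stop_bad_arg("cmp_lambda_from_mu() needs mu > 0 and scalar nu > 0")
  if (nu == 1) return(structure(mu, iterations = 0L))
  loglam <- nu * log(pmax(mu + (nu - 1) / (2 * nu), mu / 2, 1e-8))
  for (it in seq_len(max_iter)) {
    mom <- cmp_moments(exp(loglam), nu)
    err <- mom$mean - mu
    if (all(abs(err) <= tol * pmax(1, mu)))
      return(structure(exp(loglam), iterations = it))
    # d mean / d loglam = variance
    step <- err / mom$var
    loglam <- loglam - pmin(pmax(step, -5), 5)
  }
  stop("CMP mean inversion did not converge; extreme mu/nu combination")
}

#' Conway-Maxwell-Poisson probability mass function (mean parameterization)
#'
#' @param y Non-negative integer count(s).
#' @param mu Positive mean(s), recycled against `y`.
#' @param nu Positive dispersion parameter (scalar); `nu = 1` reduces to
#'   `dpois`.
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities) of `y`.
#' @export
cmp_pmf <- function(y, mu, nu, log = FALSE) {
  if (any(y < 0) || any(y != floor(y))) stop_bad_arg("y must be non-negative integers")
  n <- max(length(y), length(mu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  lambda <- cmp_lambda_from_mu(mu, nu)
  lp <- y * base::log(lambda) - nu * lgamma(y + 1) - cmp_log_normalizer(lambda, nu)
  if (log) lp else exp(lp)
}

# pmf in the rate parameterization, kept for testing the normalizer directly.
cmp_pmf_lambda <- function(y, lambda, nu, log = FALSE) {
  lp <- y * base::log(lambda) - nu * lgamma(y + 1) - cmp_log_normalizer(lambda, nu)
  if (log) lp else exp(lp)
}

#' Random deviates from the mean-parameterized CMP distribution
#'
#' @param n Number of draws when `mu` is scalar; otherwise one draw per
#'   element of `mu`.
#' @param mu Positive mean(s).
#' @param nu Positive dispersion parameter (scalar).
#' @return Integer vector of counts, drawn by inversion of the truncated CDF.
#' @export
rcmp <- function(n, mu, nu) {
  mu <- rep_len(mu, n)
  lambda <- cmp_lambda_from_mu(mu, nu)
  jmax <- cmp_trunc(lambda, nu)
  j <- 0:jmax
  lt <- outer(base::log(lambda), j) - rep(nu * lgamma(j + 1), each = n)
  p <- exp(lt - apply(lt, 1L, max))
  cp <- t(apply(p, 1L, cumsum))
  cp <- cp / cp[, ncol(cp)]
  u <- stats::runif(n)
  rowSums(cp < u)
}

#' Zero-inflated probability mass
#'
#' Mixes a point mass at zero with a base count distribution:
#' `P(0) = pi + (1 - pi) * base(0)` and `P(y) = (1 - pi) * base(y)` for
#' `y > 0`.
#'
#' @param y Non-negative integer count(s).
#' @param pi Zero-inflation probability in `[0, 1]`.
#' @param base Either a function `base(y)` returning base probabilities, or a
#'   numeric vector of base probabilities aligned with `y`.
#' @return Mixture probabilities of `y`.
#' @export
zi_pmf <- function(y, pi, base) {
  if (pi < 0 || pi > 1) stop_bad_arg("pi must lie in [0, 1]")
  pb <- if (is.function(base)) base(y) else rep_len(base, length(y))
  ifelse(y == 0, pi + (1 - pi) * pb, (1 - pi) * pb)
}

#' @rdname rcmp
#' @param zi Zero-inflation probability.
#' @export
rzicmp <- function(n, mu, nu, zi) {
  (1 - stats::rbinom(n, 1L, zi)) * rcmp(n, mu, nu)
}

#' Random deviates from a zero-inflated negative binomial
#'
#' @inheritParams rcmp
#' @param size Negative-binomial dispersion (as in [stats::rnbinom()]).
#' @param zi Zero-inflation probability.
#' @export
rzinb <- function(n, mu, size, zi) {
  (1 - stats::rbinom(n, 1L, zi)) * stats::rnbinom(n, mu = rep_len(mu, n), size = size)
}
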