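#' The ex-Gaussian distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the ex-Gaussian (exponentially modified Gaussian) distribution: the
#' sum of a normal variate with mean `mu` and standard deviation `rho` and
#' an independent exponential variate with mean `eta`. It is the standard
#' model for human response-latency distributions, combining a roughly
#' Gaussian core with a long right tail. Its mean is `mu + eta` and its
#' standard deviation `sqrt(rho^2 + eta^2)`.
#'
#' The density is evaluated on the log scale throughout
#' (`-log(eta) + rho^2/(2 eta^2) - (x - mu)/eta + log Phi((x - mu)/rho - rho/eta)`),
#' which stays finite far into both tails where the naive product of an
#' exponential and a Gaussian term overflows.
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param mu Mean of the Gaussian component.
#' @param rho Standard deviation of the Gaussian component (> 0).
#' @param eta Mean of the exponential component (> 0).
#' @param log,log.p Logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail Logical; if `TRUE` (default), probabilities are
#'   `P(X <= x)`.
#' @return `dexgauss` the density, `pexgauss` the distribution function,
#'   `qexgauss` the quantile function, `rexgauss` random draws.
#' @examples
#' dexgauss(500, mu = 350, rho = 34.2, eta = 124)
#' mean(rexgauss(1e4, 350, 34.2, 124))
#' @name exgauss
NULL

#' @rdname exgauss
#' @export
dexgauss <- function(x, mu, rho, eta, log = FALSE) {
  if (any(rho <= 0) || any(eta <= 0)) {
    # invalid parameters: NaN (optimizers probe outside the valid region)
    return(rep(NaN, length(x)))
  }
  lf <- -log(eta) + rho^2 / (2 * eta^2) - (x - mu) / eta +
    stats::pnorm((x - mu) / rho - rho / eta, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname exgauss
#' @export
pexgauss <- function(q, mu, rho, eta, lower.tail = TRUE, log.p = FALSE) {
  if (any(rho <= 0) || any(eta <= 0)) {
    return(rep(NaN, length(q)))
  }
  z <- (q - mu) / rho
  # P(X <= q) = Phi(z) - exp(...) * Phi(z - rho/eta), assembled in log space
  tail_term <- exp(rho^2 / (2 * eta^2) - (q - mu) / eta +
                     stats::pnorm(z - rho / eta, log.p = TRUE))
  p <- stats::pnorm(z) - tail_term
  p <- pmin(pmax(p, 0), 1)
  if (!lower.tail) p <- 1 - p
  if (log.p) log(p) else p
}

#' @rdname exgauss
#' @export
qexgauss <- function(p, mu, rho, eta, lower.tail = TRUE, log.p = FALSE) {
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  stopifnot(all(p >= 0 & p <= 1))
  vapply(p, function(pi) {
    if (pi <= 0) return(-Inf)
    if (pi >= 1) return(Inf)
    lo <- mu - 10 * rho
    hi <- mu + eta + 10 * sqrt(rho^2 + eta^2)
    while (pexgauss(lo, mu, rho, eta) > pi) lo <- lo - 10 * (rho + eta)
    while (pexgauss(hi, mu, rho, eta) < pi) hi <- hi + 10 * (rho + eta)
    stats::uniroot(function(x) pexgauss(x, mu, rho, eta) - pi,
                   c(lo, hi), tol = 1e-8)$root
  }, numeric(1))
}

#' @rdname exgauss
#' @export
rexgauss <- function(n, mu, rho, eta) {
  if (any(rho <= 0) || any(eta <= 0)) {
    stop_input("ex-Gaussian requires rho > 0 and eta > 0")
  }
  stats::rnorm(n, mu, rho) + stats::rexp(n, rate = 1 / eta)
}
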