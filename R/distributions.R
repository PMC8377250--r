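# Duration-distribution families used for all timing behavior: construction,
# sampling, closed-form moments, per-participant maximum-likelihood fitting
# and BIC family selection, and cross-participant parameter summaries.

DIST_FAMILIES <- c("norm", "lnorm", "exgauss")

normalize_family <- function(family) {
  fam <- tolower(as.character(family))
  fam[fam %in% c("exgaus", "exgauss", "exgaussian")] <- "exgauss"
  if (!all(fam %in% DIST_FAMILIES)) {
    stop_input("unknown distribution family '%s' (use norm, lnorm or exgauss)",
               paste(setdiff(fam, DIST_FAMILIES), collapse = ", "))
  }
  fam
}

#' Construct a duration distribution
#'
#' A `duration_dist` is a positive-duration law from one of three families
#' standard for human gaze timing: normal (`norm`), log-normal (`lnorm`) and
#' ex-Gaussian (`exgauss`). It parameterizes every dwell time, reaction time
#' and blink interval in the simulation, and is the object the fitting
#' pipeline estimates from data.
#'
#' Parameter conventions: for `norm` and `exgauss`, `mu` and `rho` are the
#' Gaussian mean and SD in milliseconds and (for `exgauss`) `eta` is the
#' exponential-component mean in milliseconds, so the ex-Gaussian mean is
#' `mu + eta`. For `lnorm`, `mu` and `rho` are the mean and SD of
#' `log(duration)` (log-ms units).
#'
#' @param family One of `"norm"`, `"lnorm"`, `"exgauss"`.
#' @param mu Location parameter (ms for norm/exgauss, log-ms for lnorm).
#' @param rho Scale parameter, `> 0` (ms for norm/exgauss, log-units for
#'   lnorm).
#' @param eta Exponential-component mean in ms; required for `exgauss` and
#'   disallowed otherwise.
#' @return An object of class `duration_dist`.
#' @examples
#' duration_dist("exgauss", 350, 34.2, 124)
#' duration_dist("lnorm", 6.72, 0.46)
#' @seealso [dist_moments()], [sample_duration()], [fit_family()]
#' @export
duration_dist <- function(family, mu, rho, eta = NULL) {
  family <- normalize_family(family)
  stopifnot(length(family) == 1L)
  check_scalar_number(mu, "mu")
  check_scalar_number(rho, "rho")
  if (rho <= 0) stop_input("'rho' must be > 0, got %s", format(rho))
  if (family == "exgauss") {
    if (is.null(eta)) stop_input("family 'exgauss' requires 'eta'")
    check_scalar_number(eta, "eta")
    if (eta <= 0) stop_input("'eta' must be > 0, got %s", format(eta))
  } else if (!is.null(eta)) {
    stop_input("'eta' is only meaningful for family 'exgauss'")
  }
  structure(list(family = family, mu = mu, rho = rho,
                 eta = if (family == "exgauss") eta),
            class = "duration_dist")
}

#' @export
print.duration_dist <- function(x, ...) {
  m <- dist_moments(x)
  cat(sprintf("<duration_dist %s> mu=%g rho=%g%s  (mean %.4g ms, sd %.4g ms)\n",
              x$family, x$mu, x$rho,
              if (!is.null(x$eta)) sprintf(" eta=%g", x$eta) else "",
              m[["mean"]], m[["sd"]]))
  invisible(x)
}

is_duration_dist <- function(x) inherits(x, "duration_dist")

#' Closed-form mean and SD of a duration distribution
#'
#' Returns the analytic moments in milliseconds: `norm` has mean `mu` and SD
#' `rho`; `lnorm` has mean `exp(mu + rho^2/2)` and SD
#' `mean * sqrt(exp(rho^2) - 1)`; `exgauss` has mean `mu + eta` and SD
#' `sqrt(rho^2 + eta^2)`.
#'
#' @param dist A [duration_dist()].
#' @return Named numeric vector `c(mean =, sd =)` in ms.
#' @examples
#' dist_moments(duration_dist("exgauss", 350, 34.2, 124)) # mean 474 ms
#' @export
dist_moments <- function(dist) {
  stopifnot(is_duration_dist(dist))
  switch(dist$family,
    norm = c(mean = dist$mu, sd = dist$rho),
    lnorm = {
      m <- exp(dist$mu + dist$rho^2 / 2)
      c(mean = m, sd = m * sqrt(exp(dist$rho^2) - 1))
    },
    exgauss = c(mean = dist$mu + dist$eta,
                sd = sqrt(dist$rho^2 + dist$eta^2))
  )
}

#' Draw positive durations from a duration distribution
#'
#' Non-positive draws (possible for `norm`, and for `exgauss` when `rho` is
#' large relative to `mu`) are redrawn, so returned durations are strictly
#' positive. For high-CV normal configurations this truncation shifts the
#' realized mean slightly above `mu`; see the methods vignette.
#'
#' @param dist A [duration_dist()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducible draws; the caller's
#'   RNG state is left untouched.
#' @return Numeric vector of `n` strictly positive durations (ms).
#' @export
sample_duration <- function(dist, n, seed = NULL) {
  stopifnot(is_duration_dist(dist))
  check_scalar_number(n, "n", lower = 1)
  n <- as.integer(n)
  with_seed(seed, {
    draw <- switch(dist$family,
      norm = function(k) stats::rnorm(k, dist$mu, dist$rho),
      lnorm = function(k) stats::rlnorm(k, dist$mu, dist$rho),
      exgauss = function(k) rexgauss(k, dist$mu, dist$rho, dist$eta)
    )
    x <- draw(n)
    bad <- which(x <= 0)
    while (length(bad)) {
      x[bad] <- draw(length(bad))
      bad <- bad[x[bad] <= 0]
    }
    x
  })
}

# direct ex-Gaussian MLE on a log-transformed scale (rho, eta > 0 by
# construction); robust fallback for small or near-degenerate samples where
# the bounded quasi-Newton route fails on finite differences
fit_exgauss_direct <- function(x) {
  s <- exgauss_start(x)
  nll <- function(par) {
    v <- -sum(dexgauss(x, par[1], exp(par[2]), exp(par[3]), log = TRUE))
    if (!is.finite(v)) 1e12 else v
  }
  opt <- stats::optim(c(s$mu, log(s$rho), log(s$eta)), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(estimate = c(mu = opt$par[1], rho = exp(opt$par[2]),
                    eta = exp(opt$par[3])),
       loglik = -opt$value)
}

# method-of-moments starting values for the ex-Gaussian optimizer
exgauss_start <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  g <- mean(((x - m) / s)^3)
  eta0 <- s * (max(g, 0.01) / 2)^(1 / 3)
  eta0 <- min(max(eta0, 0.05 * s), m * 0.95)
  rho0 <- sqrt(max(s^2 - eta0^2, (0.1 * s)^2))
  list(mu = m - eta0, rho = rho0, eta = eta0)
}

#' Fit one duration-distribution family by maximum likelihood
#'
#' Fits `norm`, `lnorm` or `exgauss` to a sample of positive durations via
#' [fitdistrplus::fitdist()]. The ex-Gaussian uses the package's own density
#' ([dexgauss()]) with method-of-moments starting values and bounded
#' L-BFGS-B refinement, so fits are deterministic given the data. A
#' degenerate sample (zero variance) is handled explicitly: the location is
#' the common value and the scale collapses to a small lower bound, flagged
#' via `degenerate = TRUE`.
#'
#' @param x Numeric vector of durations (ms), all `> 0` for `lnorm`.
#' @param family One of `"norm"`, `"lnorm"`, `"exgauss"`.
#' @param min_n Minimum sample size accepted for fitting (default 10).
#' @return An object of class `gaze_fit`: list with `family`, `params`
#'   (named vector), `loglik`, `n`, `bic` (`k log n - 2 loglik`), `dist`
#'   (the fitted [duration_dist()]) and `degenerate`.
#' @examples
#' x <- sample_duration(duration_dist("lnorm", 6.72, 0.46), 500, seed = 1)
#' fit_family(x, "lnorm")
#' @export
fit_family <- function(x, family, min_n = 10) {
  family <- normalize_family(family)
  stopifnot(length(family) == 1L)
  x <- as.numeric(x)
  if (anyNA(x)) stop_input("durations contain NA")
  if (length(x) < min_n) {
    stop_input("insufficient data: %d observations, need >= %d",
               length(x), min_n)
  }
  if (family == "lnorm" && any(x <= 0)) {
    stop_input("log-normal fitting requires strictly positive durations")
  }
  k <- if (family == "exgauss") 3L else 2L
  n <- length(x)

  if (stats::sd(x) < 1e-9) {
    # all observations (numerically) identical: scale at its lower bound
    rho_min <- 1e-6
    params <- switch(family,
      norm = c(mu = mean(x), rho = rho_min),
      lnorm = c(mu = mean(log(x)), rho = rho_min),
      exgauss = c(mu = mean(x) - rho_min, rho = rho_min, eta = rho_min))
    ll <- sum(density_at(family, x, params))
    return(new_gaze_fit(family, params, ll, n, k, degenerate = TRUE))
  }

  fit <- switch(family,
    norm = fitdistrplus::fitdist(x, "norm"),
    lnorm = fitdistrplus::fitdist(x, "lnorm"),
    exgauss = tryCatch(
      fitdistrplus::fitdist(
        x, "exgauss", start = exgauss_start(x),
        lower = c(-Inf, 1e-6, 1e-6), optim.method = "L-BFGS-B"),
      error = function(e) fit_exgauss_direct(x)))
  params <- fit$estimate
  names(params) <- switch(family,
    norm = c("mu", "rho"), lnorm = c("mu", "rho"),
    exgauss = c("mu", "rho", "eta"))
  new_gaze_fit(family, params, fit$loglik, n, k, degenerate = FALSE)
}

density_at <- function(family, x, params) {
  switch(family,
    norm = stats::dnorm(x, params[["mu"]], params[["rho"]], log = TRUE),
    lnorm = stats::dlnorm(x, params[["mu"]], params[["rho"]], log = TRUE),
    exgauss = dexgauss(x, params[["mu"]], params[["rho"]], params[["eta"]],
                       log = TRUE))
}

new_gaze_fit <- function(family, params, loglik, n, k, degenerate) {
  dist <- duration_dist(family, params[["mu"]], params[["rho"]],
                        if (family == "exgauss") params[["eta"]])
  structure(list(family = family, params = params, loglik = loglik,
                 n = n, k = k, bic = k * log(n) - 2 * loglik,
                 dist = dist, degenerate = degenerate),
            class = "gaze_fit")
}

#' @export
print.gaze_fit <- function(x, ...) {
  cat(sprintf("<gaze_fit %s> n=%d  %s  loglik=%.2f  BIC=%.2f%s\n",
              x$family, x$n,
              paste(sprintf("%s=%.4g", names(x$params), x$params),
                    collapse = " "),
              x$loglik, x$bic,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Select the best-fitting family across participants by BIC
#'
#' Fits each candidate family separately to every participant's sample and
#' selects the family with the smallest total BIC summed over participants,
#' so that one family is chosen per timing parameter. Participants with
#' fewer than `min_n` observations are dropped from the comparison for all
#' families symmetrically.
#'
#' @param samples Named list: participant id -> numeric vector of durations.
#' @param candidates Families to compare (default all three).
#' @param min_n Minimum per-participant sample size (default 10).
#' @return List with `family` (winner), `fits` (named list of `gaze_fit`
#'   for the winning family, one per retained participant), `total_bic`
#'   (named vector per candidate) and `dropped` (ids excluded by `min_n`).
#' @export
select_family <- function(samples, candidates = DIST_FAMILIES, min_n = 10) {
  candidates <- normalize_family(candidates)
  if (!is.list(samples) || length(samples) == 0L) {
    stop_input("'samples' must be a non-empty list of per-participant durations")
  }
  if (is.null(names(samples))) {
    names(samples) <- paste0("p", seq_along(samples))
  }
  sizes <- vapply(samples, length, integer(1))
  keep <- sizes >= min_n
  if (!any(keep)) {
    stop_input("insufficient data: no participant has >= %d observations", min_n)
  }
  kept <- samples[keep]
  fits <- lapply(candidates, function(fam) {
    lapply(kept, fit_family, family = fam, min_n = min_n)
  })
  names(fits) <- candidates
  total_bic <- vapply(fits, function(fl) {
    sum(vapply(fl, `[[`, numeric(1), "bic"))
  }, numeric(1))
  winner <- candidates[which.min(total_bic)]
  list(family = winner, fits = fits[[winner]], total_bic = total_bic,
       dropped = names(samples)[!keep])
}

#' Summarize per-participant fits of one timing parameter
#'
#' Cross-participant summary for a single timing parameter: the fitted
#' parameter vectors are averaged element-wise, and the estimated mean/SD
#' are the arithmetic means of the per-participant closed-form moments (not
#' the moments of the averaged parameters; for the log-normal the two differ
#' by a Jensen gap, while for the ex-Gaussian the mean is linear in the
#' parameters so they coincide).
#'
#' @param name Label of the timing parameter (e.g. `"t_follow_RJA"`).
#' @param fits List of `gaze_fit` objects, one per participant, all of the
#'   same family.
#' @param observations Optional pooled raw observations for this parameter;
#'   if supplied, `raw_mean`/`raw_sd` are their sample moments.
#' @return Object of class `parameter_summary`: list with `parameter`,
#'   `family`, `n_participants`, `mean_params` (named vector), `est_mean`,
#'   `est_sd`, `raw_mean`, `raw_sd`, `n_obs`, `degenerate` (TRUE if any
#'   contributing fit was degenerate).
#' @export
summarize_parameter <- function(name, fits, observations = NULL) {
  stopifnot(is.character(name), length(name) == 1L, length(fits) >= 1L)
  fams <- unique(vapply(fits, `[[`, character(1), "family"))
  if (length(fams) != 1L) {
    stop_input("fits mix families (%s); summarize one family at a time",
               paste(fams, collapse = ", "))
  }
  pmat <- do.call(rbind, lapply(fits, `[[`, "params"))
  mean_params <- colMeans(pmat)
  moments <- vapply(fits, function(f) dist_moments(f$dist), numeric(2))
  structure(list(
    parameter = name,
    family = fams,
    n_participants = length(fits),
    mean_params = mean_params,
    est_mean = mean(moments["mean", ]),
    est_sd = mean(moments["sd", ]),
    raw_mean = if (!is.null(observations)) mean(observations) else NA_real_,
    raw_sd = if (!is.null(observations)) stats::sd(observations) else NA_real_,
    n_obs = if (!is.null(observations)) length(observations) else NA_integer_,
    degenerate = any(vapply(fits, `[[`, logical(1), "degenerate"))
  ), class = "parameter_summary")
}

#' @export
print.parameter_summary <- function(x, ...) {
  cat(sprintf(
    "<parameter_summary %s> %s over %d participant(s): est mean %.4g ms, est sd %.4g ms%s\n",
    x$parameter, x$family, x$n_participants, x$est_mean, x$est_sd,
    if (x$degenerate) "  [degenerate fits]" else ""))
  invisible(x)
}
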