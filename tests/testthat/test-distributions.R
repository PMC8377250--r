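# Duration-distribution families: moments, sampling, maximum-likelihood
# fitting, BIC family selection and cross-participant summaries.

test_that("closed-form moments match the empirical moments of large samples", {
  cases <- list(
    duration_dist("norm", 2480, 1670),
    duration_dist("lnorm", 6.72, 0.46),
    duration_dist("exgauss", 350, 34.2, 124))
  n <- 1e6
  for (d in cases) {
    m <- dist_moments(d)
    x <- sample_duration(d, n, seed = 7)
    se_mean <- m[["sd"]] / sqrt(n)
    if (d$family == "norm") {
      # positivity truncation shifts high-CV normal draws upward; compare
      # against the truncated-law mean instead of mu
      z <- -d$mu / d$rho
      trunc_mean <- d$mu + d$rho * dnorm(z) / (1 - pnorm(z))
      expect_lt(abs(mean(x) - trunc_mean), 3 * se_mean)
    } else {
      expect_lt(abs(mean(x) - m[["mean"]]), 3 * se_mean)
      expect_lt(abs(sd(x) - m[["sd"]]) / m[["sd"]], 0.01)
    }
  }
})

test_that("degenerate scales collapse sampling to the location", {
  expect_equal(sample_duration(duration_dist("norm", 100, 1e-9), 3, seed = 1),
               rep(100, 3), tolerance = 1e-6)
  expect_equal(sample_duration(duration_dist("lnorm", 0, 1e-9), 5, seed = 1),
               rep(1, 5), tolerance = 1e-6)
})

test_that("sampling is strictly positive and seed-reproducible", {
  d <- duration_dist("norm", 50, 200) # heavy truncation pressure
  x <- sample_duration(d, 5000, seed = 42)
  expect_true(all(x > 0))
  expect_identical(x, sample_duration(d, 5000, seed = 42))
  expect_false(identical(x, sample_duration(d, 5000, seed = 43)))
})

test_that("invalid distribution parameters are rejected", {
  expect_error(duration_dist("norm", 100, 0), "rho")
  expect_error(duration_dist("exgauss", 100, 10), "eta")
  expect_error(duration_dist("lnorm", 6, 0.4, eta = 5), "exgauss")
  expect_error(duration_dist("weibull", 1, 1), "family")
})

test_that("ex-Gaussian density, distribution and quantile functions cohere", {
  mu <- 350; rho <- 34.2; eta <- 124
  # density integrates to the distribution function
  for (q in c(300, 474, 900)) {
    num <- integrate(dexgauss, -Inf, q, mu = mu, rho = rho, eta = eta,
                     rel.tol = 1e-9)$value
    expect_equal(num, pexgauss(q, mu, rho, eta), tolerance = 1e-6)
  }
  # quantile inverts the cdf
  for (p in c(0.05, 0.5, 0.95)) {
    expect_equal(pexgauss(qexgauss(p, mu, rho, eta), mu, rho, eta), p,
                 tolerance = 1e-6)
  }
  # draws match the cdf (pointwise check at a few probes)
  set.seed(1)
  x <- rexgauss(2e5, mu, rho, eta)
  for (q in c(350, 474, 700)) {
    expect_lt(abs(mean(x <= q) - pexgauss(q, mu, rho, eta)), 0.005)
  }
})

test_that("maximum-likelihood fits recover generating parameters at large n", {
  x <- sample_duration(duration_dist("lnorm", 6.72, 0.46), 20000, seed = 5)
  f <- fit_family(x, "lnorm")
  expect_lt(abs(f$params[["mu"]] - 6.72), 0.02)
  expect_lt(abs(f$params[["rho"]] - 0.46), 0.02)
  # independent closed-form MLE oracle for the log-normal
  expect_equal(f$params[["mu"]], mean(log(x)), tolerance = 1e-4)
  expect_equal(f$params[["rho"]],
               sqrt(mean((log(x) - mean(log(x)))^2)), tolerance = 1e-3)

  y <- sample_duration(duration_dist("exgauss", 350, 34.2, 124), 20000,
                       seed = 6)
  g <- fit_family(y, "exgauss")
  expect_lt(abs(g$params[["mu"]] + g$params[["eta"]] - 474), 3)

  z <- sample_duration(duration_dist("norm", 2480, 1670), 5000, seed = 7)
  h <- fit_family(z, "norm")
  expect_equal(h$params[["mu"]], mean(z), tolerance = 1e-2)
})

test_that("BIC follows its definition k*log(n) - 2*loglik", {
  x <- sample_duration(duration_dist("lnorm", 6.5, 0.5), 500, seed = 1)
  f2 <- fit_family(x, "lnorm")
  f3 <- fit_family(x, "exgauss")
  expect_equal(f2$bic, 2 * log(500) - 2 * f2$loglik)
  expect_equal(f3$bic, 3 * log(500) - 2 * f3$loglik)
})

test_that("degenerate samples fit with the scale at its lower bound", {
  f <- fit_family(rep(250, 20), "norm")
  expect_true(f$degenerate)
  expect_equal(f$params[["mu"]], 250)
  expect_lte(f$params[["rho"]], 1e-6)
})

test_that("fitting guards its preconditions", {
  expect_error(fit_family(rnorm(5, 100, 1), "norm"), "insufficient")
  expect_error(fit_family(c(-1, rlnorm(20)), "lnorm"), "positive")
})

test_that("a single candidate family is returned unchanged", {
  samples <- list(a = sample_duration(duration_dist("norm", 500, 50), 50,
                                      seed = 1))
  sel <- select_family(samples, candidates = "norm")
  expect_identical(sel$family, "norm")
  expect_length(sel$fits, 1L)
})

test_that("undersized participants are dropped symmetrically", {
  d <- duration_dist("lnorm", 6.5, 0.4)
  samples <- list(big = sample_duration(d, 200, seed = 1),
                  small = sample_duration(d, 4, seed = 2))
  sel <- select_family(samples)
  expect_identical(sel$dropped, "small")
  expect_length(sel$fits, 1L)
  expect_error(select_family(list(a = 1:3)), "insufficient")
})

test_that("pooled BIC recovers log-normal and ex-Gaussian generators", {
  # 20 replicates x 5 participants x 2000 draws per generating family
  generators <- list(
    lnorm = duration_dist("lnorm", 6.72, 0.46),
    exgauss = duration_dist("exgauss", 350, 34.2, 124))
  for (fam in names(generators)) {
    hits <- vapply(1:20, function(r) {
      samples <- lapply(1:5, function(p) {
        sample_duration(generators[[fam]], 2000,
                        seed = derive_seed(1000 * r + p, match(fam, names(generators))))
      })
      names(samples) <- paste0("p", 1:5)
      select_family(samples)$family == fam
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})

test_that("positivity truncation of a high-CV normal is picked up as skew", {
  # redrawing the ~7% non-positive draws of norm(2480, 1670) leaves a
  # right-skewed truncated normal; BIC correctly attributes that skew to
  # the ex-Gaussian rather than recovering the untruncated normal label
  samples <- lapply(1:5, function(p) {
    sample_duration(duration_dist("norm", 2480, 1670), 2000, seed = 500 + p)
  })
  names(samples) <- paste0("p", 1:5)
  sel <- select_family(samples)
  expect_identical(sel$family, "exgauss")
  # with negligible truncation pressure the same data would be symmetric:
  # the skewness of the truncated draws is clearly positive
  expect_gt(mean(vapply(samples, function(x) {
    mean(((x - mean(x)) / sd(x))^3)
  }, numeric(1))), 0.1)
})

test_that("parameter summaries average element-wise and over moments", {
  f1 <- fit_family(sample_duration(duration_dist("exgauss", 300, 30, 100),
                                   200, seed = 1), "exgauss")
  f2 <- fit_family(sample_duration(duration_dist("exgauss", 400, 40, 148),
                                   200, seed = 2), "exgauss")
  # forced arithmetic on exact parameter values
  f1$params[] <- c(300, 30, 100); f1$dist <- duration_dist("exgauss", 300, 30, 100)
  f2$params[] <- c(400, 40, 148); f2$dist <- duration_dist("exgauss", 400, 40, 148)
  sm <- summarize_parameter("t_follow_RJA", list(f1, f2))
  expect_equal(unname(sm$mean_params), c(350, 35, 124))
  expect_equal(sm$est_mean, (400 + 548) / 2)
  # single participant: the summary is that participant's fit
  sm1 <- summarize_parameter("t_follow_RJA", list(f1))
  expect_equal(sm1$est_mean, 400)
  expect_equal(unname(sm1$mean_params), c(300, 30, 100))
})

test_that("summaries refuse mixed families", {
  fe <- fit_family(sample_duration(duration_dist("exgauss", 300, 30, 100),
                                   50, seed = 1), "exgauss")
  fl <- fit_family(sample_duration(duration_dist("lnorm", 6, 0.4), 50,
                                   seed = 2), "lnorm")
  expect_error(summarize_parameter("x", list(fe, fl)), "famil")
})

test_that("ex-Gaussian mean is linear in the parameters; log-normal is not", {
  mk <- function(family, ...) {
    d <- duration_dist(family, ...)
    params <- c(mu = d$mu, rho = d$rho)
    if (family == "exgauss") params <- c(params, eta = d$eta)
    structure(list(family = family, params = params, loglik = 0, n = 10,
                   k = length(params), bic = 0, dist = d, degenerate = FALSE),
              class = "gaze_fit")
  }
  # exgauss: mean of averaged parameters == average of means, exactly
  fe <- list(mk("exgauss", 300, 30, 100), mk("exgauss", 500, 60, 200))
  sm <- summarize_parameter("t_follow_RJA", fe)
  avg_dist <- duration_dist("exgauss", sm$mean_params[["mu"]],
                            sm$mean_params[["rho"]], sm$mean_params[["eta"]])
  expect_equal(dist_moments(avg_dist)[["mean"]], sm$est_mean, tolerance = 1e-9)
  # lnorm: Jensen gap makes the two differ
  fl <- list(mk("lnorm", 6.0, 0.3), mk("lnorm", 7.4, 0.9))
  sml <- summarize_parameter("t_agent_INT", fl)
  avg_l <- duration_dist("lnorm", sml$mean_params[["mu"]],
                         sml$mean_params[["rho"]])
  expect_gt(abs(dist_moments(avg_l)[["mean"]] - sml$est_mean), 1)
})

test_that("parameter recovery holds across a simulated cohort", {
  gen <- duration_dist("exgauss", 350, 34.2, 124)
  fits <- lapply(1:30, function(p) {
    fit_family(sample_duration(gen, 200, seed = 100 + p), "exgauss")
  })
  sm <- summarize_parameter("t_follow_RJA", fits)
  expect_lt(abs(sm$est_mean - 474), 10)
})
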