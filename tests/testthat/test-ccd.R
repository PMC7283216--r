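test_that("CCD design has the expected size and geometry", {
  ts <- toy_series(4)
  y <- ts$values - mean(ts$values)
  pr <- hyper_priors()
  mode3 <- find_mode(ts$times, y, pr)
  grid3 <- build_ccd(mode3, function(w)
    pgpde:::log_joint_w(w, ts$times, y, pr))
  expect_equal(nrow(grid3$W), 1 + 6 + 8)     # mode + stars + full 2^3
  expect_equal(grid3$d, 3)
  mode1 <- find_mode(ts$times, y, pr,
                     fixed = list(signal_variance = 1, noise_variance = 0.1))
  grid1 <- build_ccd(mode1, function(w)
    pgpde:::log_joint_w(w, ts$times, y, pr))
  expect_equal(nrow(grid1$W), 1 + 2 + 2)
  # all integration weights positive; normalised mixture weight of the mode
  # is the largest
  expect_true(all(is.finite(grid3$logdelta)))
  expect_true(all(grid3$weights > 0))
  expect_equal(which.max(grid3$weights), grid3$mode_index)
})

test_that("star points sit at the whitened radius under an identity Hessian", {
  # quadratic log joint with unit curvature: split scales are 1, so the star
  # points land exactly at distance r0 = f * sqrt(d) from the mode
  w0 <- c(lengthscale = 0, signal_variance = 0, noise_variance = 0)
  mode <- list(w = w0, free = rep(TRUE, 3), hessian = diag(3), log_joint = 0,
               hyperparameters = exp(w0))
  grid <- build_ccd(mode, function(w) -0.5 * sum(w^2), f = 1.1)
  r0 <- 1.1 * sqrt(3)
  stars <- grid$W[2:7, , drop = FALSE]
  expect_equal(unname(apply(stars, 1, function(w) sqrt(sum(w^2)))),
               rep(r0, 6), tolerance = 1e-2)
  expect_equal(unname(grid$split), matrix(1, 3, 2), tolerance = 1e-2,
               ignore_attr = TRUE)
})

test_that("CCD log marginal likelihood is within 0.5 nats of grid quadrature", {
  pr <- hyper_priors()
  cases <- list(
    list(seed = 1, free = "lengthscale",
         fixed = list(signal_variance = 1, noise_variance = 0.1),
         lo = 0.5, hi = 400),
    list(seed = 2, free = "signal_variance",
         fixed = list(lengthscale = 25, noise_variance = 0.1),
         lo = 1e-4, hi = 50),
    list(seed = 3, free = "noise_variance",
         fixed = list(lengthscale = 25, signal_variance = 1),
         lo = 1e-5, hi = 10))
  for (cs in cases) {
    set.seed(cs$seed)
    t <- sort(runif(3, 0, 60))
    y <- rnorm(3, sd = 0.7)
    y <- y - mean(y)
    est <- estimate_log_ml(t, y, pr, fixed = cs$fixed)
    fx <- cs$fixed
    fx[[cs$free]] <- NA
    oracle <- quad_log_ml(t, y, pr, fx, cs$free, cs$lo, cs$hi)
    expect_lt(abs(est - oracle), 0.5)
  }
})

test_that("a single-point grid reduces the estimate to the mode's log joint", {
  ts <- toy_series(5)
  y <- ts$values - mean(ts$values)
  pr <- hyper_priors()
  mode <- find_mode(ts$times, y, pr)
  # degenerate grid: R = 1, delta = 1, unit volume
  lml <- pgpde:::logsumexp(mode$log_joint + log(1) + 0)
  expect_equal(lml, mode$log_joint)
})

test_that("predictive mixture reduces to the mode posterior for R = 1 and is
           invariant to weight rescaling", {
  ts <- toy_series(6)
  y <- ts$values - mean(ts$values)
  pr <- hyper_priors()
  fit <- pgpde:::ccd_fit(ts$times, y, pr)
  tt <- c(10, 35, 70)
  # R = 1: keep only the mode row
  g1 <- fit$grid
  g1$W <- g1$W[1, , drop = FALSE]
  g1$hyperparameters <- g1$hyperparameters[1, , drop = FALSE]
  g1$weights <- 1
  p1 <- predictive_distribution(ts$times, y, tt, g1)
  hp <- fit$mode$hyperparameters
  p0 <- gp_posterior(ts$times, y, tt, hp[1], hp[2], hp[3])
  expect_equal(p1$mean, p0$mean)
  expect_equal(p1$cov, p0$cov)
  # doubling all raw weights changes nothing after renormalisation
  g2 <- fit$grid
  lw <- g2$logq + g2$logdelta + log(2) + g2$logvol
  g2$weights <- exp(lw - pgpde:::logsumexp(lw))
  pa <- predictive_distribution(ts$times, y, tt, fit$grid)
  pb <- predictive_distribution(ts$times, y, tt, g2)
  expect_equal(pa$mean, pb$mean)
  expect_equal(pa$cov, pb$cov)
})

test_that("a two-point mixture is the hand-computed weighted average", {
  ts <- toy_series(7)
  y <- ts$values - mean(ts$values)
  pr <- hyper_priors()
  fit <- pgpde:::ccd_fit(ts$times, y, pr)
  g <- fit$grid
  g$W <- g$W[1:2, , drop = FALSE]
  g$hyperparameters <- g$hyperparameters[1:2, , drop = FALSE]
  g$weights <- c(0.3, 0.7)
  tt <- c(5, 50)
  p <- predictive_distribution(ts$times, y, tt, g)
  h1 <- g$hyperparameters[1, ]; h2 <- g$hyperparameters[2, ]
  q1 <- gp_posterior(ts$times, y, tt, h1[1], h1[2], h1[3])
  q2 <- gp_posterior(ts$times, y, tt, h2[1], h2[2], h2[3])
  expect_equal(p$mean, 0.3 * q1$mean + 0.7 * q2$mean)
  expect_equal(p$cov, 0.3 * q1$cov + 0.7 * q2$cov)
})

test_that("the mode is invariant to reordering of observations", {
  ts <- toy_series(8)
  y <- ts$values - mean(ts$values)
  pr <- hyper_priors()
  m1 <- find_mode(ts$times, y, pr)
  o <- sample(length(y))
  m2 <- find_mode(ts$times[o], y[o], pr)
  expect_equal(m1$hyperparameters, m2$hyperparameters, tolerance = 1e-4)
})
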