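test_that("squared-exponential kernel matches direct evaluation and limits", {
  expect_equal(se_kernel(0, 0, lengthscale = 30, signal_variance = 1),
               matrix(1))
  expect_equal(se_kernel(0, 30, lengthscale = 30, signal_variance = 2)[1, 1],
               2 * exp(-1 / 2))
  expect_lt(se_kernel(0, 1e5, lengthscale = 30, signal_variance = 1)[1, 1],
            1e-12)
  K <- se_kernel(c(1, 5, 9), c(1, 5, 9), 10, 1.5)
  expect_equal(K, t(K))
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  expect_error(se_kernel(0, 0, -1, 1), "lengthscale")
  expect_error(se_kernel(0, 0, 1, 0), "signal_variance")
  expect_error(se_kernel(NaN, 0, 1, 1), "finite")
})

test_that("GP posterior matches a dense-inverse oracle on random series", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:10, 1)
    t <- sort(runif(n, 0, 60))
    y <- rnorm(n)
    tt <- seq(0, 60, length.out = 7)
    hp <- c(l = runif(1, 5, 40), s = runif(1, 0.5, 2), v = runif(1, 0.05, 0.5))
    post <- gp_posterior(t, y, tt, hp[1], hp[2], hp[3])
    # naive dense solve of the same equations
    A <- se_kernel(t, t, hp[1], hp[2]) + diag(hp[3], n)
    Ks <- se_kernel(tt, t, hp[1], hp[2])
    mu <- Ks %*% solve(A, y)
    S <- se_kernel(tt, tt, hp[1], hp[2]) - Ks %*% solve(A, t(Ks))
    expect_equal(post$mean, drop(mu), tolerance = 1e-8)
    expect_equal(post$cov, (S + t(S)) / 2, tolerance = 1e-8)
    expect_true(all(diag(post$cov) > -1e-8))
  }
})

test_that("GP posterior interpolates noiselessly and reverts to the prior", {
  ts <- toy_series(2)
  y <- ts$values - mean(ts$values)
  post <- gp_posterior(ts$times, y, ts$times, 20, 1, 1e-12)
  expect_equal(post$mean, y, tolerance = 1e-5)
  far <- gp_posterior(ts$times, y, max(ts$times) + 500, 20, 1.7, 0.1)
  expect_equal(far$mean, 0, tolerance = 1e-6)
  expect_equal(far$cov[1, 1], 1.7, tolerance = 1e-6)
})

test_that("log joint matches independent density oracles", {
  pr <- hyper_priors()
  # likelihood part via differences (prior cancels): N = 1
  for (x in c(0.5, -1.2)) {
    d <- log_joint(0, x, 25, 1.3, 0.2, pr) - log_joint(0, 0, 25, 1.3, 0.2, pr)
    s <- sqrt(1.3 + 0.2)
    expect_equal(d, dnorm(x, 0, s, log = TRUE) - dnorm(0, 0, s, log = TRUE))
  }
  # full value against a test-side re-derivation of likelihood + priors
  lp_oracle <- function(l, sv, nv, pr) {
    lp_l <- dnorm(l, pr$lengthscale_mean, sqrt(pr$lengthscale_var),
                  log = TRUE) + log(l)
    s <- sqrt(sv)
    lp_s <- log(2) + dt(s / pr$signal_scale, pr$signal_df, log = TRUE) -
      log(pr$signal_scale) + log(s / 2)
    nu <- pr$noise_df; tau2 <- pr$noise_scale2
    lp_v <- (nu / 2) * log(tau2 * nu / 2) - lgamma(nu / 2) -
      (nu / 2) * log(nv) - nu * tau2 / (2 * nv)
    lp_l + lp_s + lp_v
  }
  t3 <- c(2, 9, 30); y3 <- c(0.3, -0.4, 0.1)
  for (hp in list(c(30, 1, 0.1), c(12, 0.5, 0.03))) {
    A <- se_kernel(t3, t3, hp[1], hp[2]) + diag(hp[3], 3)
    expect_equal(log_joint(t3, y3, hp[1], hp[2], hp[3], pr),
                 ldmvn(y3, rep(0, 3), A) + lp_oracle(hp[1], hp[2], hp[3], pr),
                 tolerance = 1e-10)
  }
  # well-posedness at the prior means
  expect_true(is.finite(log_joint(t3, y3, pr$lengthscale_mean, 1,
                                  pr$noise_scale2, pr)))
  expect_error(log_joint(t3, y3, -1, 1, 0.1, pr), "> 0")
})

test_that("joint scaling of data and variances shifts the likelihood by -N/2 log c", {
  t4 <- c(1, 7, 15, 22); y4 <- c(0.2, -0.3, 0.5, 0.1)
  cc <- 3
  base <- pgpde:::gp_log_lik(t4, y4, c(20, 0.8, 0.1))
  scaled <- pgpde:::gp_log_lik(t4, y4 * sqrt(cc), c(20, 0.8 * cc, 0.1 * cc))
  expect_equal(scaled, base - length(t4) / 2 * log(cc), tolerance = 1e-10)
})

test_that("analytic gradient of the log joint matches central differences", {
  pr <- hyper_priors()
  ts <- toy_series(3)
  w <- log(c(18, 0.9, 0.12))
  g <- pgpde:::log_joint_w(w, ts$times, ts$values - mean(ts$values), pr,
                           grad = TRUE)
  h <- 1e-5
  for (i in 1:3) {
    wp <- w; wp[i] <- wp[i] + h
    wm <- w; wm[i] <- wm[i] - h
    num <- (pgpde:::log_joint_w(wp, ts$times, ts$values - mean(ts$values), pr) -
              pgpde:::log_joint_w(wm, ts$times, ts$values - mean(ts$values), pr)) /
      (2 * h)
    expect_equal(g$grad[i], num, tolerance = 1e-5)
  }
})
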