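test_that("BF score is invariant to common offsets and joint negation", {
  p <- toy_pair(function(t) sin(t / 12), function(t) cos(t / 18), seed = 2)
  bf <- bf_score_pair(p$case_times, p$case_values,
                      p$control_times, p$control_values)
  # a shared level shift is removed by every centring step
  bf_off <- bf_score_pair(p$case_times, p$case_values + 7,
                          p$control_times, p$control_values + 7)
  expect_equal(bf, bf_off, tolerance = 1e-8)
  # mirroring both trajectories leaves the score unchanged
  bf_neg <- bf_score_pair(p$case_times, -p$case_values,
                          p$control_times, -p$control_values)
  expect_equal(bf, bf_neg, tolerance = 1e-6)
  # a case-only level shift, by contrast, is visible to the pooled joint
  # model (the pooled series is centred by its own mean) and raises the score
  bf_case_off <- bf_score_pair(p$case_times, p$case_values + 7,
                               p$control_times, p$control_values)
  expect_gt(bf_case_off, bf)
})

test_that("null features drawn from one shared process score below threshold", {
  set.seed(42)
  n <- 7
  scores <- replicate(50, {
    t_all <- sort(runif(2 * n, 0, 90))
    K <- se_kernel(t_all, t_all, 25, 1)
    f <- drop(crossprod(chol(K + diag(1e-8, 2 * n)), rnorm(2 * n)))
    obs <- f + rnorm(2 * n, sd = 0.5)
    ci <- sample(2 * n, n)
    bf_score_pair(t_all[ci], obs[ci], t_all[-ci], obs[-ci], restarts = 2)
  })
  expect_lt(median(scores), 4)
})

test_that("de_scores flags follow the score threshold", {
  p1 <- toy_pair(function(t) sin(t / 12), function(t) sin(t / 12), seed = 3)
  ds <- pair_dataset(list(p1))
  sc <- score_tc(ds$exprs, ds$metadata, restarts = 2)
  expect_s3_class(sc, "de_scores")
  expect_equal(sc$is_de, sc$score > 4)
  expect_equal(attr(sc, "threshold"), 4)
  expect_output(print(sc), "DE scores")
})

test_that("pairs with an unobserved group are skipped, not scored", {
  p1 <- toy_pair(function(t) sin(t / 12), function(t) sin(t / 12), seed = 4)
  ds <- pair_dataset(list(p1))
  md <- ds$metadata
  extra <- data.frame(sample_id = "P2_case_1", pair_id = "P2",
                      group = "case", time_weeks = 10)
  exprs <- cbind(ds$exprs, matrix(0.1, 1, 1,
                                  dimnames = list("F1", "P2_case_1")))
  expect_message(
    sc <- score_tc(exprs, rbind(md, extra), restarts = 2), "skipping")
  expect_equal(attr(sc, "skipped"), "P2")
  expect_false("P2" %in% sc$pair_id)
})

test_that("multivariate-normal KL matches closed forms and Monte Carlo", {
  # identical distributions
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(kl_mvn(c(1, 2), S, c(1, 2), S), 0, tolerance = 1e-8)
  # 1-d shift: KL = mu^2 / 2
  expect_equal(kl_mvn(1, matrix(1), 0, matrix(1)), 0.5, tolerance = 1e-6)
  # 4-d Monte-Carlo oracle
  set.seed(9)
  A <- matrix(rnorm(16), 4); S0 <- crossprod(A) + diag(4)
  B <- matrix(rnorm(16), 4); S1 <- crossprod(B) + diag(4)
  mu0 <- rnorm(4); mu1 <- rnorm(4)
  kl <- kl_mvn(mu0, S0, mu1, S1)
  n <- 2e5
  Z <- matrix(rnorm(4 * n), 4)
  X <- crossprod(chol(S0), Z) + mu0
  l0 <- apply(X, 2, ldmvn, mu = mu0, sigma = S0)
  l1 <- apply(X, 2, ldmvn, mu = mu1, sigma = S1)
  d <- l0 - l1
  expect_lt(abs(kl - mean(d)), 3 * sd(d) / sqrt(n))
  expect_gt(kl, 0)
})

test_that("window model pair has the documented structure and symmetric score", {
  p <- toy_pair(function(t) sin(t / 12), function(t) -sin(t / 12), seed = 5,
                horizon = 80)
  tt <- window_test_times(70)
  expect_length(tt, 26)
  expect_equal(tt[26], 70)
  wm <- window_predictives(p$case_times, p$case_values, p$control_times,
                           p$control_values, tt, restarts = 2)
  expect_equal(wm$k, 52)
  expect_equal(wm$M1$mean[1:26], wm$M1$mean[27:52])
  s <- kl_score(wm)
  expect_gte(s, 0)
  swapped <- structure(list(M0 = wm$M1, M1 = wm$M0, k = wm$k,
                            test_times = tt), class = "window_models")
  expect_equal(kl_score(swapped), s)
  # M0 = M1 gives zero
  same <- structure(list(M0 = wm$M1, M1 = wm$M1, k = wm$k, test_times = tt),
                    class = "window_models")
  expect_equal(kl_score(same), 0, tolerance = 1e-5)
})

test_that("window scoring is finite and reproducible with no in-window samples", {
  # all observations before the window [44, 70]: the GPs extrapolate
  p <- toy_pair(function(t) sin(t / 10), function(t) cos(t / 10), seed = 6,
                horizon = 40)
  tt <- window_test_times(70)
  s1 <- kl_score(window_predictives(p$case_times, p$case_values,
                                    p$control_times, p$control_values, tt,
                                    restarts = 2))
  s2 <- kl_score(window_predictives(p$case_times, p$case_values,
                                    p$control_times, p$control_values, tt,
                                    restarts = 2))
  expect_true(is.finite(s1))
  expect_gte(s1, 0)
  expect_identical(s1, s2)
})

test_that("a window-divergent feature outscores its matched null", {
  set.seed(7)
  n <- 9
  ci <- seq(1, 2 * n, by = 2); di <- seq(2, 2 * n, by = 2)
  t_all <- numeric(2 * n)
  t_all[ci] <- sort(runif(n, 0, 80))      # case and control each span the
  t_all[di] <- sort(runif(n, 0, 80))      # full horizon, incl. the window
  K <- se_kernel(t_all, t_all, 25, 1)
  f <- drop(crossprod(chol(K + diag(1e-8, 2 * n)), rnorm(2 * n)))
  noise <- rnorm(2 * n, sd = 0.4)
  tt <- window_test_times(75)
  bump <- 2.5 * exp(-((t_all - 62)^2) / (2 * 6^2))   # inside [50, 75]
  null_case <- f[ci] + noise[ci]
  de_case <- f[ci] + bump[ci] + noise[ci]
  ctrl <- f[di] + noise[di]
  s_null <- kl_score(window_predictives(t_all[ci], null_case, t_all[di],
                                        ctrl, tt, restarts = 2))
  s_de <- kl_score(window_predictives(t_all[ci], de_case, t_all[di], ctrl,
                                      tt, restarts = 2))
  expect_gt(s_de, s_null)
})

test_that("KL threshold calibration recovers modes and falls back safely", {
  # degenerate: identical borderline scores
  expect_equal(calibrate_kl_threshold(rep(4, 40), rep(123, 40)), 123)
  # too few borderline features: default with a warning
  expect_warning(thr <- calibrate_kl_threshold(rep(10, 40), rep(5, 40)),
                 "default")
  expect_equal(thr, 250)
  # unimodal density: recovered mode within the KDE bandwidth of the truth
  set.seed(12)
  x <- rnorm(2000, mean = 3, sd = 0.3)
  kl <- expm1(x)
  thr <- calibrate_kl_threshold(rep(4, 2000), kl)
  bw <- bw.nrd0(log1p(kl))
  expect_lt(abs(log1p(thr) - 3), 3 * bw)
})

test_that("probe-set collapsing keeps the best probe-set per gene per pair", {
  scores <- structure(data.frame(
    feature_id = c("ps1", "ps2", "ps1", "ps2", "ps3"),
    pair_id = c("A", "A", "B", "B", "A"),
    score_type = "BF",
    score = c(3.1, 6.2, 5.0, 2.0, 1.0),
    is_de = c(FALSE, TRUE, TRUE, FALSE, FALSE)),
    class = c("de_scores", "data.frame"), threshold = 4)
  mapping <- data.frame(probe_id = c("ps1", "ps2", "ps3"),
                        gene_symbol = c("G1", "G1", "G2"))
  g <- collapse_probesets(scores, mapping)
  gA <- g[g$feature_id == "G1" & g$pair_id == "A", ]
  gB <- g[g$feature_id == "G1" & g$pair_id == "B", ]
  expect_equal(gA$score, 6.2)
  expect_equal(gA$probe_id, "ps2")     # different probe-sets selected
  expect_equal(gB$score, 5.0)
  expect_equal(gB$probe_id, "ps1")
  # one-to-one mapping is the identity on scores
  one <- collapse_probesets(scores, data.frame(
    probe_id = c("ps1", "ps2", "ps3"),
    gene_symbol = c("g_ps1", "g_ps2", "g_ps3")))
  expect_equal(sort(one$score), sort(scores$score))
  # unmapped probe-sets dropped with a message
  expect_message(
    dropped <- collapse_probesets(scores, mapping[1:2, ]), "unmapped")
  expect_false("ps3" %in% dropped$probe_id)
})

test_that("a gene DE through different probe-sets is called DE in every pair", {
  # two probe-sets of one gene, each DE in a different pair
  scores <- structure(data.frame(
    feature_id = rep(c("ps_a", "ps_b"), 2),
    pair_id = rep(c("P1", "P2"), each = 2),
    score_type = "BF",
    score = c(9.0, 0.2, 0.4, 7.5),
    is_de = c(TRUE, FALSE, FALSE, TRUE)),
    class = c("de_scores", "data.frame"), threshold = 4)
  mapping <- data.frame(probe_id = c("ps_a", "ps_b"),
                        gene_symbol = c("GENE", "GENE"))
  g <- collapse_probesets(scores, mapping)
  expect_equal(nrow(g), 2)
  expect_true(all(g$is_de))
  expect_equal(sort(g$probe_id), c("ps_a", "ps_b"))
})

test_that("score_matrix reshapes long scores with -Inf for unscored cells", {
  scores <- data.frame(feature_id = c("f1", "f2", "f1"),
                       pair_id = c("A", "A", "B"),
                       score_type = "BF", score = c(1, 2, 3),
                       is_de = FALSE)
  S <- score_matrix(scores)
  expect_equal(dim(S), c(2, 2))
  expect_equal(S["f1", "B"], 3)
  expect_equal(S["f2", "B"], -Inf)
})
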