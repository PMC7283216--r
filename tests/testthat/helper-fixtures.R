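# Shared fixtures: small deterministic series and pair datasets built in code.

toy_series <- function(seed = 1, n = 6, horizon = 80, sd = 0.3) {
  set.seed(seed)
  t <- sort(runif(n, 0, horizon))
  list(times = t, values = sin(t / 15) + rnorm(n, sd = sd))
}

# One pair observing smooth curves f_case / f_control at irregular times.
# Stratified sampling (one draw per bin) keeps the times uneven but spread
# over the horizon, so the curves are actually observed.
toy_pair <- function(f_case, f_control, seed = 1, n = 8, horizon = 80,
                     sd = 0.15) {
  set.seed(seed)
  ct <- (seq_len(n) - runif(n)) * horizon / n
  dt <- (seq_len(n) - runif(n)) * horizon / n
  list(case_times = ct, case_values = f_case(ct) + rnorm(n, sd = sd),
       control_times = dt, control_values = f_control(dt) + rnorm(n, sd = sd))
}

# Build an expression matrix + metadata from a list of pairs for one feature
# per row of `value_fun(pair_index)`.
pair_dataset <- function(pairs) {
  cols <- list(); md <- list()
  for (j in seq_along(pairs)) {
    p <- pairs[[j]]
    ids <- c(sprintf("P%d_case_%d", j, seq_along(p$case_times)),
             sprintf("P%d_control_%d", j, seq_along(p$control_times)))
    md[[j]] <- data.frame(sample_id = ids, pair_id = sprintf("P%d", j),
                          group = rep(c("case", "control"),
                                      c(length(p$case_times),
                                        length(p$control_times))),
                          time_weeks = c(p$case_times, p$control_times))
    cols[[j]] <- matrix(c(p$case_values, p$control_values), nrow = 1,
                        dimnames = list("F1", ids))
  }
  list(exprs = do.call(cbind, cols), metadata = do.call(rbind, md))
}

# Independent log-density oracle for a multivariate Gaussian (test-side).
ldmvn <- function(x, mu, sigma) {
  L <- chol(sigma)
  z <- forwardsolve(t(L), x - mu)
  -0.5 * sum(z * z) - sum(log(diag(L))) - length(mu) / 2 * log(2 * pi)
}

# Column-wise variant for Monte-Carlo oracles on large draw matrices.
ldmvn_cols <- function(X, mu, sigma) {
  L <- chol(sigma)
  Z <- forwardsolve(t(L), X - mu)
  -0.5 * colSums(Z * Z) - sum(log(diag(L))) - length(mu) / 2 * log(2 * pi)
}

# Fine-grid quadrature oracle for the log marginal likelihood with one free
# hyperparameter (the others clamped).
quad_log_ml <- function(times, values, priors, fixed, free_name, lo, hi,
                        n = 4000) {
  grid <- seq(log(lo), log(hi), length.out = n)
  lj <- vapply(grid, function(w) {
    hp <- list(lengthscale = fixed$lengthscale,
               signal_variance = fixed$signal_variance,
               noise_variance = fixed$noise_variance)
    hp[[free_name]] <- exp(w)
    log_joint(times, values, hp$lengthscale, hp$signal_variance,
              hp$noise_variance, priors)
  }, 0)
  m <- max(lj)
  m + log(sum(exp(lj - m)) * (grid[2] - grid[1]))
}

# Brute-force enrichment statistic: loops and set operations only.
brute_agm <- function(S, gene_of, pathways, thr, alpha) {
  vapply(pathways, function(pw) {
    f <- vapply(seq_len(ncol(S)), function(j) {
      de <- unique(gene_of[S[, j] > thr])
      length(intersect(de, pw)) / length(de) + alpha
    }, 0)
    exp(mean(log(f)))
  }, 0)
}
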