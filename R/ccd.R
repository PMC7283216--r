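# Central composite design integration over GP hyperparameters.
#
# All internals parameterise the hyperparameters on the natural-log scale
# w = (log lengthscale, log signal_variance, log noise_variance); priors are
# stated on the natural scale so log_joint carries the change-of-variables
# Jacobian (see log_prior).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate RNG-consuming code without disturbing the caller's RNG stream.
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

log_joint_w <- function(w, times, values, priors, grad = FALSE,
                        what = "series") {
  lp <- log_prior(w, priors)
  if (!is.finite(lp)) {
    if (grad) return(list(value = -Inf, grad = rep(0, 3)))
    return(-Inf)
  }
  hp <- exp(w)
  ll <- gp_log_lik(times, values, hp, grad = grad, what = what)
  if (!grad) return(ll + lp)
  list(value = ll$value + lp, grad = ll$grad + log_prior_grad(w, priors))
}

#' Unnormalised log posterior of the GP hyperparameters
#'
#' Log Gaussian marginal likelihood \eqn{\log N(x; 0, K + \sigma^2_\epsilon I)}
#' plus the log prior density of the hyperparameters.  This is the integrand of
#' the CCD marginal-likelihood approximation, evaluated on the log scale with
#' the transform Jacobian included.  Degenerate hyperparameters yield `-Inf`
#' explicitly.
#'
#' @inheritParams gp_posterior
#' @param priors A [hyper_priors()] object.
#' @return A single numeric value (possibly `-Inf`).
#' @export
log_joint <- function(times, values, lengthscale, signal_variance,
                      noise_variance, priors = hyper_priors()) {
  if (any(c(lengthscale, signal_variance, noise_variance) <= 0))
    stop("hyperparameters must be > 0", call. = FALSE)
  log_joint_w(log(c(lengthscale, signal_variance, noise_variance)),
              times, values, priors)
}

w_init <- function(priors, fixed) {
  w <- c(lengthscale = log(priors$lengthscale_mean),
         signal_variance = 0,
         noise_variance = log(priors$noise_scale2))
  for (nm in names(fixed)) w[nm] <- log(fixed[[nm]])
  w
}

free_mask <- function(fixed) {
  !(c("lengthscale", "signal_variance", "noise_variance") %in% names(fixed))
}

#' MAP hyperparameters and curvature for a time series
#'
#' Multi-start BFGS maximisation of [log_joint()] over the log
#' hyperparameters, with analytic gradients, followed by a central-difference
#' Hessian of the negative log joint at the mode.  Restart initialisations are
#' drawn around the prior-based starting point from a fixed, self-contained
#' RNG substream, so the result is deterministic and independent of
#' evaluation order.
#'
#' @inheritParams log_joint
#' @param fixed Optional named list clamping a subset of
#'   `lengthscale`, `signal_variance`, `noise_variance` to given values;
#'   clamped parameters are excluded from optimisation and CCD integration.
#' @param restarts Number of optimisation starts (>= 1).
#' @param seed Seed for the restart jitter substream.
#' @param what Label for error messages.
#' @return A list with the mode on the natural scale (`hyperparameters`), the
#'   log-scale mode `w`, the free-coordinate mask, the negative-log-joint
#'   Hessian at the mode, and the attained `log_joint` value.
#' @export
find_mode <- function(times, values, priors = hyper_priors(), fixed = NULL,
                      restarts = 5, seed = 0, what = "series") {
  stopifnot(restarts >= 1)
  w0 <- w_init(priors, fixed)
  free <- free_mask(fixed)
  d <- sum(free)
  if (d == 0L) stop("all hyperparameters fixed; nothing to optimise",
                    call. = FALSE)
  neg <- function(p) {
    w <- w0; w[free] <- p
    v <- log_joint_w(w, times, values, priors, what = what)
    if (!is.finite(v)) 1e10 else -v
  }
  neg_grad <- function(p) {
    w <- w0; w[free] <- p
    g <- log_joint_w(w, times, values, priors, grad = TRUE, what = what)
    if (!is.finite(g$value)) rep(0, d) else -g$grad[free]
  }
  starts <- with_preserved_rng({
    set.seed(seed)
    jit <- matrix(stats::rnorm((restarts - 1L) * d, sd = 0.5), ncol = d)
    rbind(rep(0, d), jit)
  })
  best <- NULL
  for (r in seq_len(restarts)) {
    p0 <- w0[free] + starts[r, ]
    res <- tryCatch(
      stats::optim(p0, neg, neg_grad, method = "BFGS",
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("hyperparameter optimisation failed for ", what, call. = FALSE)
  w <- w0; w[free] <- best$par
  # central differences of the analytic gradient of the negative log joint
  H <- matrix(0, d, d)
  h <- 1e-4 * pmax(1, abs(best$par))
  for (i in seq_len(d)) {
    pp <- best$par; pp[i] <- pp[i] + h[i]
    pm <- best$par; pm[i] <- pm[i] - h[i]
    H[, i] <- (neg_grad(pp) - neg_grad(pm)) / (2 * h[i])
  }
  H <- (H + t(H)) / 2
  list(hyperparameters = stats::setNames(exp(w), names(w0)),
       w = w, free = free, hessian = H, log_joint = -best$value)
}

# Nearest positive-definite projection by eigenvalue clipping.
make_pd <- function(H, what = "hessian") {
  e <- eigen(H, symmetric = TRUE)
  floor_ev <- max(e$values) * 1e-6
  if (max(e$values) <= 0) floor_ev <- 1e-6
  if (any(e$values < floor_ev)) {
    warning("non-positive-definite ", what,
            "; projected to nearest positive-definite", call. = FALSE)
    ev <- pmax(e$values, floor_ev)
    H <- e$vectors %*% (ev * t(e$vectors))
  }
  H
}

#' Build a central composite design around the posterior mode
#'
#' Places the mode, `2d` star points and a full `2^d` factorial in the
#' whitened log-hyperparameter space at radius \eqn{r_0 = f \sqrt{d}}
#' (`f = 1.1`), stretches each half-axis by a split-Gaussian scale found by
#' bisection (so the log joint drops by \eqn{r_0^2/2} at each design point),
#' and attaches the standard CCD integration weights: the rule integrates a
#' standard Gaussian exactly, giving the mode the weight complement
#' \eqn{(2\pi)^{d/2}(1 - f^{-2})} and each of the remaining points
#' \eqn{(2\pi)^{d/2} e^{r_0^2/2} / (n_p f^2)}.
#'
#' @param mode A fit from [find_mode()].
#' @param log_joint_fn Function of a full log-scale hyperparameter vector
#'   returning the unnormalised log posterior.
#' @param f Radius scaling factor (> 1).
#' @return A list of class `"ccd_grid"`: design points (`W`, log scale, one
#'   row per point, mode first; `hyperparameters` on the natural scale), the
#'   split-Gaussian values `logq`, integration weights `logdelta`, volume
#'   corrections `logvol`, normalised mixture weights `weights`, and the
#'   evaluated `logjoint` values.
#' @export
build_ccd <- function(mode, log_joint_fn, f = 1.1) {
  free <- mode$free
  d <- sum(free)
  H <- make_pd(mode$hessian)
  e <- eigen(H, symmetric = TRUE)
  Lw <- e$vectors %*% diag(1 / sqrt(e$values), d)   # z -> w map
  logdetL <- -0.5 * sum(log(e$values))
  r0 <- f * sqrt(d)
  target <- mode$log_joint - r0^2 / 2
  to_w <- function(z) {
    w <- mode$w
    w[free] <- mode$w[free] + drop(Lw %*% z)
    w
  }
  # split-Gaussian scale on each half-axis: bisection for the distance at
  # which the log joint has dropped by r0^2/2
  split <- matrix(1, d, 2, dimnames = list(NULL, c("neg", "pos")))
  for (i in seq_len(d)) {
    for (side in 1:2) {
      sgn <- if (side == 1L) -1 else 1
      fdrop <- function(s) {
        z <- rep(0, d); z[i] <- sgn * s * r0
        log_joint_fn(to_w(z)) - target
      }
      lo <- 0.05; hi <- 10
      if (fdrop(hi) > 0) { split[i, side] <- hi; next }
      if (fdrop(lo) < 0) { split[i, side] <- lo; next }
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (fdrop(mid) > 0) lo <- mid else hi <- mid
        if (hi - lo < 1e-3) break
      }
      split[i, side] <- (lo + hi) / 2
    }
  }
  # design points in z space: mode, stars, full factorial
  Z <- rbind(rep(0, d),
             diag(r0, d), -diag(r0, d),
             as.matrix(do.call(expand.grid,
                               rep(list(c(-1, 1) * r0 / sqrt(d)), d))))
  R <- nrow(Z)
  np <- R - 1L
  stretch <- function(z) {
    s <- ifelse(z > 0, split[, "pos"], split[, "neg"])
    z * s
  }
  vol_factors <- function(z) {
    ifelse(z == 0, (split[, "neg"] + split[, "pos"]) / 2,
           ifelse(z > 0, split[, "pos"], split[, "neg"]))
  }
  W <- t(apply(Z, 1L, function(z) to_w(stretch(z))))
  logvol <- apply(Z, 1L, function(z) logdetL + sum(log(vol_factors(z))))
  logq <- c(0, rep(-r0^2 / 2, np))
  logdelta <- c((d / 2) * log(2 * pi) + log1p(-1 / f^2),
                rep((d / 2) * log(2 * pi) + r0^2 / 2 - log(np * f^2), np))
  logjoint <- apply(W, 1L, log_joint_fn)
  lw <- logq + logdelta + logvol
  weights <- exp(lw - logsumexp(lw))
  structure(list(W = W,
                 hyperparameters = exp(W),
                 logq = logq, logdelta = logdelta, logvol = logvol,
                 logjoint = logjoint, weights = weights,
                 split = split, f = f, d = d, mode_index = 1L,
                 mode = mode),
            class = "ccd_grid")
}

#' @export
print.ccd_grid <- function(x, ...) {
  cat(sprintf("CCD grid: %d points in %d whitened log-hyperparameter dims (f = %g)\n",
              nrow(x$W), x$d, x$f))
  cat("mode (natural scale):\n")
  print(signif(x$hyperparameters[x$mode_index, ], 4))
  invisible(x)
}

# Fit mode + CCD grid and the CCD log marginal likelihood for one series.
ccd_fit <- function(times, values, priors = hyper_priors(), fixed = NULL,
                    restarts = 5, seed = 0, f = 1.1, what = "series") {
  mode <- find_mode(times, values, priors, fixed = fixed,
                    restarts = restarts, seed = seed, what = what)
  ljf <- function(w) log_joint_w(w, times, values, priors, what = what)
  grid <- build_ccd(mode, ljf, f = f)
  log_ml <- logsumexp(grid$logjoint + grid$logdelta + grid$logvol)
  list(mode = mode, grid = grid, log_ml = log_ml)
}

#' CCD estimate of the log marginal likelihood
#'
#' Approximates \eqn{\log p(x) = \log \int p(x | \theta) p(\theta) d\theta}
#' by the CCD-weighted sum over design points, evaluated in log space.
#'
#' @inheritParams find_mode
#' @param f CCD radius scaling factor.
#' @return The log marginal likelihood estimate (a single numeric).
#' @export
estimate_log_ml <- function(times, values, priors = hyper_priors(),
                            fixed = NULL, restarts = 5, seed = 0, f = 1.1,
                            what = "series") {
  ccd_fit(times, values, priors, fixed, restarts, seed, f, what)$log_ml
}

#' CCD-weighted posterior predictive distribution
#'
#' Mixes the fixed-hyperparameter posteriors [gp_posterior()] over the CCD
#' design points with weights proportional to \eqn{q(\theta_r) \Delta_r}
#' (renormalised to sum to one):
#' \eqn{\mu_{pred} = \sum_r w_r \mu_*^r}, \eqn{\Sigma_{pred} = \sum_r w_r \Sigma_*^r}.
#'
#' @inheritParams gp_posterior
#' @param grid A `"ccd_grid"` from [build_ccd()].
#' @return A list with `mean`, `cov` and `test_times`.
#' @export
predictive_distribution <- function(times, values, test_times, grid,
                                    what = "series") {
  R <- nrow(grid$W)
  mu <- numeric(length(test_times))
  S <- matrix(0, length(test_times), length(test_times))
  for (r in seq_len(R)) {
    hp <- grid$hyperparameters[r, ]
    post <- gp_posterior(times, values, test_times, hp[1L], hp[2L], hp[3L],
                         what = what)
    mu <- mu + grid$weights[r] * post$mean
    S <- S + grid$weights[r] * post$cov
  }
  list(mean = mu, cov = (S + t(S)) / 2, test_times = test_times)
}
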