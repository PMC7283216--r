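#' Squared-exponential covariance between two sets of time points
#'
#' Evaluates \eqn{k(t_i, t_j) = \sigma^2_{se} \exp(-(t_i - t_j)^2 / (2 \ell^2))}.
#'
#' @param t1,t2 Numeric vectors of time points (weeks).
#' @param lengthscale Length-scale \eqn{\ell} in weeks, > 0.
#' @param signal_variance Signal variance \eqn{\sigma^2_{se}}, > 0.
#' @return A `length(t1) x length(t2)` covariance matrix.
#' @examples
#' se_kernel(0, 30, lengthscale = 30, signal_variance = 2)  # 2 * exp(-1/2)
#' @export
se_kernel <- function(t1, t2, lengthscale, signal_variance) {
  if (!is.finite(lengthscale) || lengthscale <= 0)
    stop("'lengthscale' must be finite and > 0", call. = FALSE)
  if (!is.finite(signal_variance) || signal_variance <= 0)
    stop("'signal_variance' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(t1)) || any(!is.finite(t2)))
    stop("time points must be finite", call. = FALSE)
  d <- outer(t1, t2, "-")
  signal_variance * exp(-(d * d) / (2 * lengthscale^2))
}

# Cholesky of K + noise*I with an escalating jitter ladder.  Jitter starts at
# 1e-8 * mean(diag) and multiplies by 10 up to 1e-2 * mean(diag) before
# failing.  `what` names the feature/pair for the error message.
chol_jitter <- function(A, what = "matrix") {
  scale <- mean(diag(A))
  jit <- 0
  repeat {
    L <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) 1e-8 * scale else jit * 10
    if (jit > 1e-2 * scale)
      stop("Cholesky factorisation failed after jitter escalation for ",
           what, call. = FALSE)
  }
}

#' GP posterior at test times for fixed hyperparameters
#'
#' Computes the posterior of the latent function under a zero-mean GP with
#' squared-exponential kernel and iid Gaussian observation noise:
#' \eqn{\mu_* = K_{*T}(K_{TT} + \sigma^2_\epsilon I)^{-1} x} and
#' \eqn{\Sigma_* = K_{**} - K_{*T}(K_{TT} + \sigma^2_\epsilon I)^{-1} K_{T*}},
#' via a Cholesky factorisation with an escalating jitter ladder.
#'
#' @param times,values Observed time points (weeks) and centred responses.
#' @param test_times Time points at which to evaluate the posterior.
#' @param lengthscale,signal_variance,noise_variance Kernel and noise
#'   hyperparameters, all > 0.
#' @param what Label used in error messages (e.g. feature/pair id).
#' @return A list with components `mean`, `cov` and `test_times`.
#' @export
gp_posterior <- function(times, values, test_times, lengthscale,
                         signal_variance, noise_variance, what = "series") {
  stopifnot(length(times) == length(values), length(times) >= 1L)
  if (!is.finite(noise_variance) || noise_variance <= 0)
    stop("'noise_variance' must be finite and > 0", call. = FALSE)
  K <- se_kernel(times, times, lengthscale, signal_variance)
  Ks <- se_kernel(test_times, times, lengthscale, signal_variance)
  Kss <- se_kernel(test_times, test_times, lengthscale, signal_variance)
  L <- chol_jitter(K + diag(noise_variance, length(times)), what)
  a <- backsolve(L, forwardsolve(t(L), values))
  V <- forwardsolve(t(L), t(Ks))
  S <- Kss - crossprod(V)
  S <- (S + t(S)) / 2
  list(mean = drop(Ks %*% a), cov = S, test_times = test_times)
}

# Gaussian log marginal likelihood log N(x; 0, K + noise*I) and, optionally,
# its gradient with respect to w = log(lengthscale, signal_var, noise_var).
gp_log_lik <- function(times, values, hp, grad = FALSE, what = "series") {
  n <- length(times)
  K <- se_kernel(times, times, hp[1L], hp[2L])
  A <- K + diag(hp[3L], n)
  L <- chol_jitter(A, what)
  alpha <- backsolve(L, forwardsolve(t(L), values))
  ll <- -0.5 * sum(values * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  if (!grad) return(ll)
  Ainv <- chol2inv(L)
  W <- tcrossprod(alpha) - Ainv
  d <- outer(times, times, "-")
  dK_l <- K * (d * d) / hp[1L]^2          # d K / d log lengthscale
  g <- c(0.5 * sum(W * dK_l),
         0.5 * sum(W * K),                # d K / d log signal_var = K
         0.5 * sum(diag(W)) * hp[3L])     # d A / d log noise_var = noise*I
  list(value = ll, grad = g)
}
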