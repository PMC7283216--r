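#' Hyperparameter priors for the squared-exponential GP
#'
#' Constructs the prior specification for the three kernel hyperparameters:
#' a Gaussian prior on the length-scale (in weeks), a half-Student-t prior on
#' the signal standard deviation, and a scaled-inverse-chi-squared prior on
#' the noise variance.  The defaults target weekly-resolution expression time
#' courses: a length-scale centred at 30 weeks discourages implausibly wiggly
#' fits, the half-t with 20 degrees of freedom keeps the signal magnitude
#' weakly informative, and the noise prior concentrates on small variances.
#'
#' @param lengthscale_mean Mean (weeks) of the Gaussian length-scale prior.
#' @param lengthscale_var Variance of the Gaussian length-scale prior.
#' @param signal_scale Scale of the half-Student-t prior on the signal
#'   standard deviation.
#' @param signal_df Degrees of freedom of the half-Student-t prior.
#' @param noise_scale2 Scale parameter (sigma^2) of the scaled-inverse-chi-squared
#'   prior on the noise variance.
#' @param noise_df Degrees of freedom (nu) of the noise-variance prior.
#' @return An object of class `"hyper_priors"`.
#' @examples
#' pr <- hyper_priors()
#' pr
#' @export
hyper_priors <- function(lengthscale_mean = 30, lengthscale_var = 6,
                         signal_scale = 1, signal_df = 20,
                         noise_scale2 = 0.01, noise_df = 1) {
  stopifnot(lengthscale_var > 0, signal_scale > 0, signal_df > 0,
            noise_scale2 > 0, noise_df > 0)
  structure(list(lengthscale_mean = lengthscale_mean,
                 lengthscale_var = lengthscale_var,
                 signal_scale = signal_scale,
                 signal_df = signal_df,
                 noise_scale2 = noise_scale2,
                 noise_df = noise_df),
            class = "hyper_priors")
}

#' @export
print.hyper_priors <- function(x, ...) {
  cat("GP hyperparameter priors\n")
  cat(sprintf("  lengthscale     ~ Normal(mean = %g, var = %g)  [weeks]\n",
              x$lengthscale_mean, x$lengthscale_var))
  cat(sprintf("  signal sd       ~ half-Student-t(scale = %g, df = %g)\n",
              x$signal_scale, x$signal_df))
  cat(sprintf("  noise variance  ~ scaled-inv-chi^2(scale = %g, df = %g)\n",
              x$noise_scale2, x$noise_df))
  invisible(x)
}

# Log prior density of the hyperparameters, parameterised on the log scale
# w = (log lengthscale, log signal_variance, log noise_variance).
# Priors are stated on the natural scale, so each term carries the Jacobian
# of its transform.  Returns -Inf for non-finite inputs.
log_prior <- function(w, priors) {
  if (any(!is.finite(w))) return(-Inf)
  l <- exp(w[1L])
  s <- exp(w[2L] / 2)                 # signal sd
  v <- exp(w[3L])                     # noise variance
  # Gaussian on lengthscale; Jacobian d l / d log l = l
  lp_l <- stats::dnorm(l, priors$lengthscale_mean,
                       sqrt(priors$lengthscale_var), log = TRUE) + w[1L]
  # half-t on signal sd; Jacobian d s / d log sigma2 = s / 2
  z <- s / priors$signal_scale
  lp_s <- log(2) + stats::dt(z, priors$signal_df, log = TRUE) -
    log(priors$signal_scale) + log(s / 2)
  # scaled-inverse-chi^2 on noise variance; Jacobian d v / d log v = v
  nu <- priors$noise_df
  tau2 <- priors$noise_scale2
  lp_v <- (nu / 2) * log(tau2 * nu / 2) - lgamma(nu / 2) -
    (1 + nu / 2) * w[3L] - nu * tau2 / (2 * v) + w[3L]
  lp_l + lp_s + lp_v
}

# Gradient of log_prior with respect to w (log scale).
log_prior_grad <- function(w, priors) {
  l <- exp(w[1L])
  s <- exp(w[2L] / 2)
  v <- exp(w[3L])
  g1 <- -(l - priors$lengthscale_mean) / priors$lengthscale_var * l + 1
  z <- s / priors$signal_scale
  dlogt_ds <- -(priors$signal_df + 1) * z /
    ((priors$signal_df + z^2) * priors$signal_scale)
  g2 <- dlogt_ds * s / 2 + 0.5
  nu <- priors$noise_df
  tau2 <- priors$noise_scale2
  g3 <- -nu / 2 + nu * tau2 / (2 * v)
  c(g1, g2, g3)
}
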