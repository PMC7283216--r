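#' Fit a Gaussian-process regression with CCD hyperparameter integration
#'
#' The central model fit: a zero-mean GP with squared-exponential kernel and
#' iid Gaussian noise is fit to a single (possibly irregularly sampled,
#' possibly replicated) time series.  Instead of optimising the
#' hyperparameters (type-II maximum likelihood, which is unstable at the
#' sample sizes typical of longitudinal omics), the posterior over the three
#' hyperparameters is summarised by a central composite design around its
#' mode, which provides both a marginal-likelihood estimate (used for Bayes
#' factor model selection) and a mixture predictive distribution.
#'
#' @param times Numeric vector of observation times (weeks).
#' @param values Numeric vector of responses (log-scale expression).
#' @param priors A [hyper_priors()] object.
#' @param centre If `TRUE` (default), the empirical mean of `values` is
#'   subtracted before fitting and re-added by [predict.gp_fit()].
#' @inheritParams find_mode
#' @inheritParams build_ccd
#' @return An object of class `"gp_fit"` with components `times`, `values`,
#'   `centre`, `mode`, `grid` (the CCD grid), `log_ml` and `priors`.
#' @examples
#' t <- c(0, 8, 20, 33, 47, 60)
#' y <- sin(t / 15) + rnorm(6, sd = 0.2)
#' fit <- gp_fit(t, y)
#' fit
#' predict(fit, seq(0, 60, by = 10))
#' @export
gp_fit <- function(times, values, priors = hyper_priors(), centre = TRUE,
                   fixed = NULL, restarts = 5, seed = 0, f = 1.1,
                   what = "series") {
  stopifnot(length(times) == length(values), length(times) >= 1L)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite", call. = FALSE)
  mu <- if (centre) mean(values) else 0
  cv <- values - mu
  fit <- ccd_fit(times, cv, priors, fixed = fixed, restarts = restarts,
                 seed = seed, f = f, what = what)
  structure(list(times = times, values = values, centre = mu,
                 cvalues = cv, priors = priors,
                 mode = fit$mode, grid = fit$grid, log_ml = fit$log_ml,
                 call = match.call()),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("GP fit: %d observations over [%.3g, %.3g] weeks\n",
              length(x$times), min(x$times), max(x$times)))
  cat("MAP hyperparameters:\n")
  print(signif(coef(x), 4))
  cat(sprintf("CCD log marginal likelihood: %.4f\n", x$log_ml))
  invisible(x)
}

#' @export
coef.gp_fit <- function(object, ...) object$mode$hyperparameters

#' @export
logLik.gp_fit <- function(object, ...) {
  structure(object$log_ml, df = sum(object$mode$free), class = "logLik")
}

#' Predict from a fitted GP
#'
#' CCD-mixture posterior of the latent function at new time points; the
#' centring constant removed before fitting is added back to the mean.
#'
#' @param object A [gp_fit()] object.
#' @param newtimes Time points (weeks) at which to predict; defaults to the
#'   observed times.
#' @param cov If `TRUE`, return the full posterior covariance as well.
#' @param ... Unused.
#' @return A `data.frame` with columns `time`, `mean`, `sd`; if `cov = TRUE`,
#'   a list with elements `mean`, `cov`, `test_times` instead (mean
#'   un-centred).
#' @export
predict.gp_fit <- function(object, newtimes = object$times, cov = FALSE, ...) {
  p <- predictive_distribution(object$times, object$cvalues, newtimes,
                               object$grid)
  if (cov)
    return(list(mean = p$mean + object$centre, cov = p$cov,
                test_times = newtimes))
  data.frame(time = newtimes, mean = p$mean + object$centre,
             sd = sqrt(pmax(diag(p$cov), 0)))
}

#' @export
fitted.gp_fit <- function(object, ...) {
  predict(object)$mean
}

#' @export
residuals.gp_fit <- function(object, ...) {
  object$values - fitted(object)
}

#' Plot a fitted GP with a 95% credible band
#'
#' @param x A [gp_fit()] object.
#' @param n_grid Number of grid points for the predictive curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gp_fit <- function(x, n_grid = 200, ...) {
  tg <- seq(min(x$times), max(x$times), length.out = n_grid)
  p <- predict(x, tg)
  ylim <- range(p$mean + 2 * p$sd, p$mean - 2 * p$sd, x$values)
  graphics::plot(x$times, x$values, ylim = ylim,
                 xlab = "time (weeks)", ylab = "expression", ...)
  graphics::polygon(c(tg, rev(tg)),
                    c(p$mean + 1.96 * p$sd, rev(p$mean - 1.96 * p$sd)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(tg, p$mean, col = "steelblue", lwd = 2)
  graphics::points(x$times, x$values, pch = 19)
  invisible(x)
}
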