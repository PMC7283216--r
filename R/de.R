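# Per-pair differential-expression scoring.
#
# Each feature in each matched case-control pair is scored by comparing a
# "separate" model (independent GPs for case and control) against a "joint"
# model (one GP over the pooled samples).  The whole time course is scored by
# the log Bayes factor of the two models' CCD marginal likelihoods; a fixed
# pre-event window is scored by the symmetric KL divergence between the
# models' predictive distributions over the window grid.  Case, control and
# pooled data are each mean-centred independently before fitting, so pure
# level shifts between the groups are not treated as differential expression.

fit_pair_models <- function(case_times, case_values, control_times,
                            control_values, priors = hyper_priors(),
                            restarts = 5, seed = 0, f = 1.1,
                            what = "pair") {
  list(case = gp_fit(case_times, case_values, priors, restarts = restarts,
                     seed = seed, f = f, what = paste0(what, "/case")),
       control = gp_fit(control_times, control_values, priors,
                        restarts = restarts, seed = seed, f = f,
                        what = paste0(what, "/control")),
       joint = gp_fit(c(case_times, control_times),
                      c(case_values, control_values), priors,
                      restarts = restarts, seed = seed, f = f,
                      what = paste0(what, "/joint")))
}

#' Bayes-factor DE score for one feature in one case-control pair
#'
#' Fits the separate (case, control) and joint (pooled) GP models, each to
#' independently mean-centred data, and returns the log Bayes factor
#' \eqn{\log [p(x^A) p(x^B) / p(x^S)]} of separate over joint, using CCD
#' marginal likelihoods.  Scores above 4 (about 54.6 on the linear scale)
#' are conventionally treated as strong evidence for differential expression.
#'
#' @param case_times,case_values Case observations (weeks, log expression).
#' @param control_times,control_values Control observations.
#' @inheritParams find_mode
#' @inheritParams build_ccd
#' @return The log Bayes factor (a single numeric, unbounded in sign).
#' @export
bf_score_pair <- function(case_times, case_values, control_times,
                          control_values, priors = hyper_priors(),
                          restarts = 5, seed = 0, f = 1.1, what = "pair") {
  m <- fit_pair_models(case_times, case_values, control_times, control_values,
                       priors, restarts, seed, f, what)
  m$case$log_ml + m$control$log_ml - m$joint$log_ml
}

#' Weekly test grid for a pre-event time window
#'
#' The grid spans `window_weeks` weeks at `resolution`-week spacing and ends
#' at (and includes) the event week, giving
#' `window_weeks / resolution` points (26 by default).
#'
#' @param event_time Event anchor (weeks).
#' @param window_weeks Window length in weeks (default 26, about 6 months).
#' @param resolution Grid spacing in weeks (default 1).
#' @return Numeric vector of test times.
#' @export
window_test_times <- function(event_time, window_weeks = 26, resolution = 1) {
  stopifnot(window_weeks > 0, resolution > 0)
  seq(event_time - window_weeks + resolution, event_time, by = resolution)
}

#' Separate- and joint-model predictive Gaussians over a time window
#'
#' Builds the two multivariate Gaussians compared by the window KL score: the
#' separate model stacks the case and control CCD predictives with zero
#' cross-covariance, and the joint model duplicates the pooled predictive,
#' each of dimension `2 * length(test_times)`.  The GPs interpolate, so the
#' window may contain no observations at all.
#'
#' @inheritParams bf_score_pair
#' @param test_times Window grid, e.g. from [window_test_times()].
#' @return An object of class `"window_models"` with elements `M0`, `M1`
#'   (each a list `mean`, `cov`), dimension `k` and `test_times`.
#' @export
window_predictives <- function(case_times, case_values, control_times,
                               control_values, test_times,
                               priors = hyper_priors(), restarts = 5,
                               seed = 0, f = 1.1, what = "pair") {
  m <- fit_pair_models(case_times, case_values, control_times, control_values,
                       priors, restarts, seed, f, what)
  pc <- predictive_distribution(m$case$times, m$case$cvalues, test_times,
                                m$case$grid, what = what)
  pd <- predictive_distribution(m$control$times, m$control$cvalues,
                                test_times, m$control$grid, what = what)
  pj <- predictive_distribution(m$joint$times, m$joint$cvalues, test_times,
                                m$joint$grid, what = what)
  k <- 2L * length(test_times)
  zero <- matrix(0, length(test_times), length(test_times))
  M0 <- list(mean = c(pc$mean, pd$mean),
             cov = rbind(cbind(pc$cov, zero), cbind(zero, pd$cov)))
  M1 <- list(mean = c(pj$mean, pj$mean),
             cov = rbind(cbind(pj$cov, zero), cbind(zero, pj$cov)))
  structure(list(M0 = M0, M1 = M1, k = k, test_times = test_times),
            class = "window_models")
}

#' Kullback-Leibler divergence between two multivariate Gaussians
#'
#' \eqn{KL(P || Q) = \frac12 (tr(\Sigma_1^{-1}\Sigma_0) +
#' (\mu_1-\mu_0)^T \Sigma_1^{-1} (\mu_1-\mu_0) - k +
#' \ln \det\Sigma_1 - \ln \det\Sigma_0)}, computed via Cholesky
#' log-determinants with the package's jitter ladder.
#'
#' @param mu0,sigma0 Mean and covariance of P.
#' @param mu1,sigma1 Mean and covariance of Q.
#' @return The divergence in nats (>= 0 up to numerical tolerance).
#' @export
kl_mvn <- function(mu0, sigma0, mu1, sigma1) {
  k <- length(mu0)
  stopifnot(length(mu1) == k, all(dim(sigma0) == k), all(dim(sigma1) == k))
  sigma0 <- (sigma0 + t(sigma0)) / 2
  sigma1 <- (sigma1 + t(sigma1)) / 2
  # GP predictive covariances on a dense grid are numerically rank-deficient;
  # a shared ridge (escalated jointly so both factorisations use the same
  # regularisation) keeps the divergence well-defined and nonnegative
  scale <- mean(diag(sigma0) + diag(sigma1)) / 2
  ridge <- 1e-8 * scale
  repeat {
    L0 <- tryCatch(chol(sigma0 + diag(ridge, k)), error = function(e) NULL)
    L1 <- tryCatch(chol(sigma1 + diag(ridge, k)), error = function(e) NULL)
    if (!is.null(L0) && !is.null(L1)) break
    ridge <- ridge * 10
    if (ridge > 1e-2 * scale)
      stop("KL covariance factorisation failed after jitter escalation",
           call. = FALSE)
  }
  Q1 <- chol2inv(L1)
  dm <- mu1 - mu0
  0.5 * (sum(Q1 * (sigma0 + diag(ridge, k))) +
           drop(crossprod(dm, Q1 %*% dm)) - k +
           2 * sum(log(diag(L1))) - 2 * sum(log(diag(L0))))
}

#' Symmetric KL score of a window model pair
#'
#' \eqn{\frac12 KL(M_0 || M_1) + \frac12 KL(M_1 || M_0)}; nonnegative, zero
#' when the separate and joint predictive distributions coincide.
#'
#' @param models A `"window_models"` object from [window_predictives()].
#' @return The symmetric KL divergence in nats.
#' @export
kl_score <- function(models) {
  stopifnot(inherits(models, "window_models"))
  0.5 * kl_mvn(models$M0$mean, models$M0$cov, models$M1$mean, models$M1$cov) +
    0.5 * kl_mvn(models$M1$mean, models$M1$cov, models$M0$mean, models$M0$cov)
}

# ---- drivers over an expression matrix -------------------------------------

check_metadata <- function(exprs, metadata) {
  need <- c("sample_id", "pair_id", "group", "time_weeks")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(metadata$group %in% c("case", "control")))
    stop("metadata 'group' must be 'case' or 'control'", call. = FALSE)
  absent <- setdiff(metadata$sample_id, colnames(exprs))
  if (length(absent))
    stop("sample(s) in metadata missing from expression matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Split metadata into per-pair column indices and times; pairs with an
# entirely unobserved group are skipped and reported via the "skipped" field.
pair_layout <- function(exprs, metadata) {
  pairs <- unique(metadata$pair_id)
  layout <- list()
  skipped <- character()
  for (p in pairs) {
    md <- metadata[metadata$pair_id == p, ]
    ca <- md[md$group == "case", ]
    co <- md[md$group == "control", ]
    if (nrow(ca) == 0L || nrow(co) == 0L) {
      skipped <- c(skipped, p)
      next
    }
    layout[[as.character(p)]] <- list(
      pair_id = p,
      case_idx = match(ca$sample_id, colnames(exprs)),
      control_idx = match(co$sample_id, colnames(exprs)),
      case_times = ca$time_weeks,
      control_times = co$time_weeks)
  }
  list(pairs = layout, skipped = skipped)
}

score_driver <- function(exprs, metadata, score_fun, score_type, threshold,
                         threads = 1L) {
  check_metadata(exprs, metadata)
  lay <- pair_layout(exprs, metadata)
  if (length(lay$skipped))
    message("skipping pair(s) with an unobserved group: ",
            paste(lay$skipped, collapse = ", "))
  features <- rownames(exprs)
  if (is.null(features)) features <- as.character(seq_len(nrow(exprs)))
  one_feature <- function(g) {
    out <- vector("list", length(lay$pairs))
    for (i in seq_along(lay$pairs)) {
      p <- lay$pairs[[i]]
      what <- sprintf("feature %s, pair %s", features[g], p$pair_id)
      sc <- tryCatch(
        score_fun(exprs[g, p$case_idx], p$case_times,
                  exprs[g, p$control_idx], p$control_times, p, what),
        error = function(e) e)
      out[[i]] <- if (inherits(sc, "error"))
        list(pair_id = p$pair_id, score = NA_real_,
             err = conditionMessage(sc))
      else list(pair_id = p$pair_id, score = sc, err = NA_character_)
    }
    out
  }
  res <- if (threads > 1L)
    parallel::mclapply(seq_along(features), one_feature, mc.cores = threads)
  else lapply(seq_along(features), one_feature)
  n_pairs <- length(lay$pairs)
  df <- data.frame(
    feature_id = rep(features, each = n_pairs),
    pair_id = unlist(lapply(res, function(r) vapply(r, `[[`, "", "pair_id"))),
    score_type = score_type,
    score = unlist(lapply(res, function(r)
      vapply(r, `[[`, 0, "score"))),
    stringsAsFactors = FALSE)
  errs <- unlist(lapply(res, function(r)
    vapply(r, `[[`, "", "err")))
  rejects <- df[!is.na(errs), c("feature_id", "pair_id")]
  if (nrow(rejects)) rejects$message <- errs[!is.na(errs)]
  df$is_de <- !is.na(df$score) & df$score > threshold
  df <- df[is.na(errs), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("de_scores", "data.frame"),
            threshold = threshold, skipped = lay$skipped, rejects = rejects)
}

#' Score every feature in every pair over the whole time course
#'
#' Computes the per-pair log Bayes factor ([bf_score_pair()]) for each row of
#' the expression matrix; features are flagged DE where the score exceeds
#' `bf_threshold`.
#'
#' @param exprs Numeric matrix, features x samples, log-scale expression;
#'   rownames are feature (probe-set or gene) ids, colnames sample ids.
#' @param metadata Data frame with columns `sample_id`, `pair_id`,
#'   `group` (`"case"`/`"control"`) and `time_weeks`.
#' @param priors A [hyper_priors()] object.
#' @param bf_threshold DE call threshold on the log Bayes factor (default 4).
#' @param restarts,seed,f Passed to the GP fits.
#' @param threads Number of worker processes; results are independent of the
#'   worker count.
#' @return A `"de_scores"` data frame (`feature_id`, `pair_id`, `score_type`,
#'   `score`, `is_de`) with skipped pairs and quarantined failures in
#'   attributes `"skipped"` and `"rejects"`.
#' @export
score_tc <- function(exprs, metadata, priors = hyper_priors(),
                     bf_threshold = 4, restarts = 5, seed = 0, f = 1.1,
                     threads = 1L) {
  fun <- function(cv, ct, dv, dt, pair, what)
    bf_score_pair(ct, cv, dt, dv, priors, restarts, seed, f, what)
  score_driver(exprs, metadata, fun, "BF", bf_threshold, threads)
}

#' Score every feature in every pair within a pre-event time window
#'
#' Computes the symmetric KL divergence between the separate and joint
#' models' predictive distributions over a weekly grid ending at each pair's
#' event time.
#'
#' @inheritParams score_tc
#' @param events Data frame with columns `pair_id` and `event_time` (weeks),
#'   or a named numeric vector of event times.
#' @param window_weeks,resolution Window length and grid spacing in weeks.
#' @param kl_threshold DE call threshold on the KL score (default 250; see
#'   [calibrate_kl_threshold()]).
#' @return A `"de_scores"` data frame with `score_type = "KL"`.
#' @export
score_window <- function(exprs, metadata, events, window_weeks = 26,
                         resolution = 1, priors = hyper_priors(),
                         kl_threshold = 250, restarts = 5, seed = 0, f = 1.1,
                         threads = 1L) {
  if (is.data.frame(events)) {
    ev <- stats::setNames(events$event_time, events$pair_id)
  } else ev <- events
  miss <- setdiff(unique(metadata$pair_id), names(ev))
  if (length(miss))
    stop("no event time for pair(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fun <- function(cv, ct, dv, dt, pair, what) {
    tt <- window_test_times(ev[[as.character(pair$pair_id)]], window_weeks,
                            resolution)
    kl_score(window_predictives(ct, cv, dt, dv, tt, priors, restarts, seed,
                                f, what))
  }
  score_driver(exprs, metadata, fun, "KL", kl_threshold, threads)
}

#' @export
print.de_scores <- function(x, ...) {
  cat(sprintf("DE scores (%s): %d features x %d pairs\n",
              x$score_type[1L], length(unique(x$feature_id)),
              length(unique(x$pair_id))))
  cat(sprintf("threshold %.4g: %d of %d scores called DE\n",
              attr(x, "threshold"), sum(x$is_de), nrow(x)))
  if (length(attr(x, "skipped")))
    cat("skipped pairs:", paste(attr(x, "skipped"), collapse = ", "), "\n")
  rj <- attr(x, "rejects")
  if (!is.null(rj) && nrow(rj))
    cat(sprintf("%d feature/pair fits quarantined\n", nrow(rj)))
  invisible(x)
}

#' Calibrate the window KL threshold from borderline Bayes-factor features
#'
#' The KL score has no absolute interpretation, so the DE threshold for
#' window analyses is anchored to the time-course analysis: among all
#' feature/pair scores whose BF score lies within +/- 1 of the BF threshold
#' (borderline DE), the mode of the corresponding KL scores is taken as the
#' KL threshold.  The mode is estimated by a Gaussian kernel density
#' (Silverman bandwidth) on `log(1 + score)`, maximised on a 512-point grid.
#' With fewer than `min_n` borderline features the configured `default` is
#' returned with a warning.
#'
#' @param bf_scores,kl_scores Numeric vectors of matched feature/pair scores
#'   (same ordering).
#' @param bf_threshold Bayes-factor DE threshold (default 4).
#' @param default Fallback threshold (default 250).
#' @param min_n Minimum borderline-set size for calibration.
#' @return The calibrated KL threshold (a single numeric).
#' @export
calibrate_kl_threshold <- function(bf_scores, kl_scores, bf_threshold = 4,
                                   default = 250, min_n = 30) {
  stopifnot(length(bf_scores) == length(kl_scores))
  sel <- is.finite(bf_scores) & is.finite(kl_scores) &
    bf_scores >= bf_threshold - 1 & bf_scores <= bf_threshold + 1
  if (sum(sel) < min_n) {
    warning(sprintf(
      "only %d borderline features (need >= %d); using default KL threshold %g",
      sum(sel), min_n, default), call. = FALSE)
    return(default)
  }
  x <- log1p(kl_scores[sel])
  if (stats::sd(x) == 0) return(expm1(x[1L]))   # degenerate: all identical
  d <- stats::density(x, bw = "nrd0", n = 512)
  expm1(d$x[which.max(d$y)])
}

#' Collapse probe-set scores to gene scores
#'
#' Each gene is represented, independently in each pair, by its
#' maximum-scoring probe-set, so different pairs may select different
#' probe-sets of the same gene.  Unmapped probe-sets are dropped with a
#' message.
#'
#' @param scores A `"de_scores"` data frame (probe-set level).
#' @param mapping Data frame with columns `probe_id` and `gene_symbol`.
#' @return A `"de_scores"` data frame at gene level, with the selected
#'   probe-set recorded in column `probe_id`.
#' @export
collapse_probesets <- function(scores, mapping) {
  if (nrow(scores) == 0L) return(scores)
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(mapping)))
  gene <- mapping$gene_symbol[match(scores$feature_id, mapping$probe_id)]
  dropped <- unique(scores$feature_id[is.na(gene)])
  if (length(dropped))
    message(length(dropped), " unmapped probe-set(s) dropped")
  df <- scores[!is.na(gene), , drop = FALSE]
  gene <- gene[!is.na(gene)]
  o <- order(-df$score)
  df <- df[o, , drop = FALSE]
  gene <- gene[o]
  key <- paste(gene, df$pair_id, df$score_type, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(feature_id = gene[keep],
                    pair_id = df$pair_id[keep],
                    score_type = df$score_type[keep],
                    score = df$score[keep],
                    is_de = df$is_de[keep],
                    probe_id = df$feature_id[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$feature_id, out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("de_scores", "data.frame"),
            threshold = attr(scores, "threshold"),
            skipped = attr(scores, "skipped"),
            rejects = attr(scores, "rejects"))
}

#' Reshape long DE scores into a features x pairs score matrix
#'
#' @param scores A `"de_scores"` data frame with one score type.
#' @return A numeric matrix with feature ids as rownames and pair ids as
#'   colnames; unscored combinations are `-Inf`.
#' @export
score_matrix <- function(scores) {
  stopifnot(length(unique(scores$score_type)) <= 1L)
  feats <- unique(scores$feature_id)
  pairs <- unique(scores$pair_id)
  S <- matrix(-Inf, length(feats), length(pairs),
              dimnames = list(feats, as.character(pairs)))
  S[cbind(match(scores$feature_id, feats),
          match(scores$pair_id, pairs))] <- scores$score
  S
}
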