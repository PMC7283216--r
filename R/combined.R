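# Population-wide baseline: pool all cases and all controls into one
# "combined" pair, score once per feature with the same GP machinery, and
# test pathway enrichment with a one-sided Fisher's exact test.

#' Pool all pairs into a single combined case-control pair
#'
#' @param metadata Sample metadata (see [score_tc()]).
#' @return Metadata with every sample assigned to pair `"combined"`.
#' @export
pool_pairs <- function(metadata) {
  metadata$pair_id <- "combined"
  metadata
}

#' Combined (population-wide) DE scoring
#'
#' Pools the expressions of all cases and all controls into one combined
#' pair (assuming homogeneous differential expression across the study
#' population) and applies the identical scoring machinery: Bayes factor for
#' the whole time course, symmetric window KL for `mode = "window"`.  The
#' same thresholds as the personalised path apply.
#'
#' @inheritParams score_tc
#' @param mode `"tc"` or `"window"`.
#' @param event_time Event anchor (weeks) for the pooled pair in window
#'   mode; pooled window analyses normally re-anchor each pair's times
#'   relative to its event first, so a common anchor is meaningful.
#' @param window_weeks,resolution,kl_threshold Window parameters, as in
#'   [score_window()].
#' @return A `"de_scores"` data frame with the single pair `"combined"`.
#' @export
combined_de <- function(exprs, metadata, mode = c("tc", "window"),
                        priors = hyper_priors(), bf_threshold = 4,
                        event_time = NULL, window_weeks = 26, resolution = 1,
                        kl_threshold = 250, restarts = 5, seed = 0, f = 1.1,
                        threads = 1L) {
  mode <- match.arg(mode)
  md <- pool_pairs(metadata)
  if (mode == "tc")
    return(score_tc(exprs, md, priors, bf_threshold, restarts, seed, f,
                    threads))
  if (is.null(event_time))
    stop("'event_time' is required for combined window scoring",
         call. = FALSE)
  score_window(exprs, md, c(combined = event_time), window_weeks, resolution,
               priors, kl_threshold, restarts, seed, f, threads)
}

#' One-sided Fisher's exact test for pathway enrichment
#'
#' Tests each pathway for over-representation of DE genes against the
#' platform universe using the hypergeometric tail
#' \eqn{P(X \ge overlap)} on the 2x2 table (DE-in-pathway, DE-outside,
#' non-DE-in-pathway, rest), with Benjamini-Hochberg correction.
#'
#' @param de_genes Character vector of DE genes (subset of `universe`).
#' @param universe Character vector: all genes on the platform after
#'   probe-set mapping.
#' @param pathways Named list of gene sets.
#' @param fdr_levels FDR annotation levels.
#' @return An `"enrichment_result"` data frame with columns `pathway`,
#'   `n_genes`, `overlap`, `p_value`, `fdr` and significance flags.
#' @export
fisher_enrichment <- function(de_genes, universe, pathways,
                              fdr_levels = c(0.1, 0.05)) {
  universe <- unique(universe)
  de_genes <- unique(de_genes)
  extra <- setdiff(de_genes, universe)
  if (length(extra))
    stop("DE gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  N <- length(universe)
  n_de <- length(de_genes)
  psets <- lapply(pathways, function(p) intersect(p, universe))
  K <- lengths(psets)
  ov <- vapply(psets, function(p) length(intersect(p, de_genes)), 0L)
  p <- stats::phyper(ov - 1L, K, N - K, n_de, lower.tail = FALSE)
  out <- data.frame(pathway = names(pathways), n_genes = K, overlap = ov,
                    p_value = p, fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  for (lev in fdr_levels)
    out[[sprintf("sig_fdr_%g", lev)]] <- out$fdr < lev
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            B = NA_integer_, method = "combined")
}
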