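# Heterogeneity-aware pathway enrichment.
#
# Per-pair DE gene lists are summarised per pathway by the adjusted geometric
# mean of scaled overlaps; significance comes from a feature-label permutation
# null that shuffles whole rows of the score matrix (one shared permutation
# across pairs, preserving cross-pair score correlations) and redoes
# probe-set collapsing and thresholding inside every permutation.

#' Scaled pathway overlap for one pair
#'
#' \eqn{f_{i,j} = |DE_j \cap P_i| / |DE_j| + \alpha}: the fraction of pair
#' `j`'s DE genes that fall in pathway `i`, floored away from zero by the
#' small constant `alpha` so the geometric mean over pairs is defined.
#'
#' @param de_genes Character vector of DE genes for the pair (non-empty).
#' @param pathway Character vector of pathway member genes.
#' @param alpha Small positive constant (default `1e-6`).
#' @return A value in `(alpha, 1 + alpha]`.
#' @export
scaled_overlap <- function(de_genes, pathway, alpha = 1e-6) {
  if (length(de_genes) == 0L)
    stop("pair has no DE genes; drop the pair before enrichment",
         call. = FALSE)
  stopifnot(alpha > 0)
  length(intersect(de_genes, pathway)) / length(unique(de_genes)) + alpha
}

#' Adjusted geometric mean of per-pair scaled overlaps
#'
#' \eqn{(\prod_j f_{i,j})^{1/m}}, computed in log space; bounded by the range
#' of `f`, so no single pair can dominate the pathway's enrichment score.
#'
#' @param f Numeric vector of per-pair scaled overlaps, all > 0.
#' @return The geometric mean.
#' @export
adjusted_geometric_mean <- function(f) {
  stopifnot(all(f > 0))
  exp(mean(log(f)))
}

# Precompute the static pieces of the permutation loop.
enrich_setup <- function(S, mapping, pathways, alpha) {
  feats <- rownames(S)
  if (is.null(feats)) stop("score matrix needs feature rownames",
                           call. = FALSE)
  if (is.null(mapping)) {
    gene_of <- feats
  } else {
    gene_of <- mapping$gene_symbol[match(feats, mapping$probe_id)]
    if (any(is.na(gene_of))) {
      keep <- !is.na(gene_of)
      message(sum(!keep), " unmapped probe-set(s) dropped")
      S <- S[keep, , drop = FALSE]
      gene_of <- gene_of[keep]
    }
  }
  genes <- sort(unique(gene_of))
  gidx <- match(gene_of, genes)
  # pathway membership restricted to the platform universe, as index pairs
  psets <- lapply(pathways, function(p) match(intersect(p, genes), genes))
  mem_path <- rep(seq_along(psets), lengths(psets))
  mem_gene <- unlist(psets, use.names = FALSE)
  list(S = S, genes = genes, gidx = gidx, n_gene = length(genes),
       psets = psets, mem_path = mem_path, mem_gene = mem_gene,
       n_path = length(pathways), alpha = alpha)
}

# Adjusted geometric means for one labelling: relabel rows by `perm`,
# collapse probe-sets to genes (max rule == any-above-threshold on the
# indicator), threshold per pair, and score every pathway.
agm_stats <- function(setup, Dp, perm) {
  glab <- setup$gidx[perm]
  Dg <- rowsum(Dp, glab) > 0                       # genes x pairs indicator
  degs <- colSums(Dg)
  ov <- matrix(0, setup$n_path, ncol(Dg))
  if (length(setup$mem_gene)) {
    o <- rowsum(Dg[setup$mem_gene, , drop = FALSE] + 0, setup$mem_path)
    ov[as.integer(rownames(o)), ] <- o
  }
  frac <- sweep(ov, 2L, pmax(degs, 1L), "/")
  frac[, degs == 0L] <- 0
  f <- frac + setup$alpha
  list(stat = exp(rowMeans(log(f))), overlap = ov, degs = degs)
}

#' Permutation test for pathway enrichment of personalised DE results
#'
#' For each pathway the observed statistic is the adjusted geometric mean of
#' per-pair scaled overlaps between the pathway and each pair's DE genes.
#' The null distribution is generated by shuffling the feature labels of the
#' score-matrix rows -- one shared permutation across all pairs per
#' iteration, so cross-pair score correlations are retained -- and, inside
#' every permutation, re-collapsing probe-sets to genes (max rule),
#' re-thresholding per pair, and recomputing every pathway's statistic.
#' Empirical p-values use the add-one estimator
#' \eqn{p = (1 + \#\{stat_b \ge stat_{obs}\}) / (B + 1)}, so they are never
#' exactly zero, and are Benjamini-Hochberg adjusted.
#'
#' @param scores A `"de_scores"` data frame (single score type) or a numeric
#'   features x pairs score matrix with rownames/colnames.
#' @param pathways Named list of gene-symbol sets (e.g. from [read_gmt()]).
#' @param mapping Optional probe-set to gene mapping (`probe_id`,
#'   `gene_symbol` columns); omit when rows are already genes.
#' @param de_threshold Score threshold for a DE call; defaults to the
#'   threshold attribute of `scores`.
#' @param B Number of permutations (default 100000).
#' @param alpha Scaled-overlap constant (default `1e-6`).
#' @param seed RNG seed for the permutation stream (required for
#'   reproducibility; default 0).
#' @param permutations Optional integer matrix (`B` x features) of explicit
#'   row-label permutations, overriding the random stream (used e.g. for
#'   exhaustive enumeration on small problems).
#' @param fdr_levels FDR annotation levels (default 0.1 and 0.05).
#' @param progress_every Print a progress message every this many
#'   permutations; `0` disables.
#' @return An `"enrichment_result"` data frame: `pathway`, `n_genes` (in the
#'   platform universe), `adj_geo_mean`, `p_value`, `fdr`, significance
#'   flags, and per-pair overlap counts `overlap_<pair>`.
#' @export
enrich_permutation <- function(scores, pathways, mapping = NULL,
                               de_threshold = NULL, B = 1e5, alpha = 1e-6,
                               seed = 0, permutations = NULL,
                               fdr_levels = c(0.1, 0.05),
                               progress_every = 0) {
  if (is.data.frame(scores)) {
    if (is.null(de_threshold)) de_threshold <- attr(scores, "threshold")
    S <- score_matrix(scores)
  } else S <- as.matrix(scores)
  if (is.null(de_threshold))
    stop("'de_threshold' is required when scores carry no threshold",
         call. = FALSE)
  setup <- enrich_setup(S, mapping, pathways, alpha)
  Dp <- (setup$S > de_threshold) + 0
  G <- nrow(Dp)
  obs <- agm_stats(setup, Dp, seq_len(G))
  if (any(obs$degs == 0L))
    stop("pair(s) with no DE genes at threshold ", de_threshold, ": ",
         paste(colnames(S)[obs$degs == 0L], collapse = ", "),
         "; drop them before enrichment", call. = FALSE)
  if (!is.null(permutations)) {
    stopifnot(ncol(permutations) == G)
    B <- nrow(permutations)
  }
  count <- integer(setup$n_path)
  with_preserved_rng({
    set.seed(seed)
    for (b in seq_len(B)) {
      perm <- if (is.null(permutations)) sample.int(G) else permutations[b, ]
      stat_b <- agm_stats(setup, Dp, perm)$stat
      count <- count + (stat_b >= obs$stat)
      if (progress_every > 0 && b %% progress_every == 0L)
        message("permutation ", b, " / ", B)
    }
  })
  p <- (1 + count) / (B + 1)
  out <- data.frame(pathway = names(pathways),
                    n_genes = lengths(setup$psets),
                    adj_geo_mean = obs$stat,
                    p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  for (lev in fdr_levels)
    out[[sprintf("sig_fdr_%g", lev)]] <- out$fdr < lev
  ovl <- obs$overlap
  colnames(ovl) <- paste0("overlap_", colnames(setup$S))
  out <- cbind(out, ovl)
  out <- out[order(out$p_value, -out$adj_geo_mean), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            B = B, de_threshold = de_threshold, alpha = alpha, seed = seed,
            method = "personalised")
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat(sprintf("Pathway enrichment (%s method, B = %d permutations)\n",
              attr(x, "method") %||% "personalised", attr(x, "B") %||% NA))
  sig <- grep("^sig_fdr_", names(x), value = TRUE)
  for (s in sig)
    cat(sprintf("  %s: %d pathways\n", sub("sig_", "", s), sum(x[[s]])))
  cat("top pathways:\n")
  cols <- intersect(c("pathway", "n_genes", "overlap", "adj_geo_mean",
                      "p_value", "fdr"), names(x))
  print(utils::head(as.data.frame(x)[, cols], n))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
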