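# Synthetic matched case-control time-course generator.
#
# Emulates the study design the method targets: a handful of case-control
# pairs, 3-12 irregular sampling times per individual (case and control of a
# pair deliberately sampled at non-identical times), probe-sets mapping
# many-to-one onto genes, and planted differential expression whose per-pair
# activation, direction and probe-set may all differ between pairs.  Null
# features observe one shared latent GP draw per pair through independent
# noise; DE features diverge by one of three mechanisms (independent case
# draw, additive in-window bump, sign flip).

#' Simulation configuration
#'
#' Defaults describe the regime the package is designed for: 6 matched
#' pairs, 3-12 samples per individual over a two-year horizon, smooth
#' trajectories (length-scale 20 weeks) with signal-to-noise
#' \eqn{\sigma^2_{se}/\sigma^2_\epsilon = 4}, 20% of genes DE-capable, and
#' sparse per-pair activation (probability 0.15) that produces the low
#' (roughly 15%) pairwise DEG overlap characteristic of heterogeneous
#' disease cohorts.
#'
#' @param n_pairs Number of case-control pairs.
#' @param samples_range Range (min, max) of samples per individual.
#' @param time_horizon Study length in weeks.
#' @param n_genes Number of genes.
#' @param probesets_per_gene Range of probe-sets per gene.
#' @param frac_de_genes Fraction of genes that are DE-capable.
#' @param activation_prob Per-pair probability that a DE-capable gene is
#'   actually DE in that pair (the heterogeneity dial).
#' @param flip_prob Probability that an active gene's effect direction is
#'   flipped in a pair (used by the bump and sign-flip mechanisms).
#' @param de_mechanism `"independent"` (case gets its own GP draw),
#'   `"window_bump"` (smooth additive bump inside the pre-event window) or
#'   `"sign_flip"` (case observes the mirrored trajectory).
#' @param bump_height Amplitude (expression units) of the window bump.
#' @param lengthscale,signal_variance,noise_variance GP parameters of the
#'   latent trajectories and the iid observation noise.
#' @param n_pathways Number of unplanted (random) pathways.
#' @param pathway_size_range Size range of random pathways.
#' @param n_planted Number of planted enriched pathways.
#' @param planted_size Genes per planted pathway.
#' @param planted_member_frac Fraction of a planted pathway's members forced
#'   DE in each pair (a fresh random subset per pair).
#' @param event_times Optional numeric vector (length `n_pairs`) of event
#'   anchors in weeks; drawn uniformly in `[0.6, 0.9] * time_horizon` when
#'   `NULL`.
#' @param window_weeks Window length used by the bump mechanism.
#' @param seed RNG seed; identical config + seed gives byte-identical data.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_pairs = 6, samples_range = c(3, 12),
                       time_horizon = 104, n_genes = 200,
                       probesets_per_gene = c(1, 3), frac_de_genes = 0.2,
                       activation_prob = 0.15, flip_prob = 0.2,
                       de_mechanism = c("independent", "window_bump",
                                        "sign_flip"),
                       bump_height = 2, lengthscale = 20,
                       signal_variance = 1, noise_variance = 0.25,
                       n_pathways = 20, pathway_size_range = c(10, 40),
                       n_planted = 1, planted_size = 30,
                       planted_member_frac = 0.4, event_times = NULL,
                       window_weeks = 26, seed = 0) {
  de_mechanism <- match.arg(de_mechanism)
  cfg <- as.list(environment())
  stopifnot(n_pairs >= 1, n_genes >= 1,
            samples_range[1] >= 1, samples_range[2] >= samples_range[1],
            probesets_per_gene[1] >= 1,
            frac_de_genes >= 0, frac_de_genes <= 1,
            activation_prob >= 0, activation_prob <= 1,
            flip_prob >= 0, flip_prob <= 1,
            signal_variance > 0, noise_variance > 0, lengthscale > 0)
  if (n_planted * planted_size > n_genes)
    stop("planted pathways need more genes than available", call. = FALSE)
  if (round(frac_de_genes * n_genes) > n_genes)
    stop("more DE genes than genes", call. = FALSE)
  if (!is.null(event_times) && length(event_times) != n_pairs)
    stop("'event_times' must have one entry per pair", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Irregular sampling times
#'
#' Sorted, non-uniform times emulating the uneven sampling of longitudinal
#' cohorts: one draw per scheduled visit window (the range split into `n`
#' equal windows, a uniform draw within each), the way follow-up studies
#' sample around planned visit ages rather than uniformly at random.  Case
#' and control of a pair call this independently, so their times never
#' coincide.
#'
#' @param range Numeric length-2 vector (weeks).
#' @param n Number of samples (>= 1).
#' @param seed Optional seed (evaluated in a preserved RNG substream); when
#'   `NULL` the current RNG stream is used.
#' @return Sorted numeric vector of length `n` within `range`.
#' @export
irregular_sampling <- function(range, n, seed = NULL) {
  stopifnot(n >= 1, length(range) == 2L, range[2] > range[1])
  draw <- function()
    range[1] + (seq_len(n) - stats::runif(n)) * diff(range) / n
  if (is.null(seed)) return(draw())
  with_preserved_rng({
    set.seed(seed)
    draw()
  })
}

gp_draws <- function(times, n, lengthscale, signal_variance) {
  K <- se_kernel(times, times, lengthscale, signal_variance)
  L <- chol_jitter(K, "simulation kernel")
  crossprod(L, matrix(stats::rnorm(length(times) * n), length(times), n))
}

#' Simulate a matched case-control time-course dataset
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_dataset"`: `exprs` (probe-sets x samples),
#'   `metadata`, `mapping` (probe-set to gene), `pathways` (named list,
#'   planted sets first), `events` (per-pair event weeks), `truth` (per-pair
#'   active DE genes, chosen probe-sets and directions, plus planted pathway
#'   names and the full activation matrix) and the `config`.
#' @examples
#' sim <- simulate_expression(sim_config(n_pairs = 2, n_genes = 10, seed = 1))
#' dim(sim$exprs)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_rng({
    set.seed(config$seed)
    simulate_expression_impl(config)
  })
}

simulate_expression_impl <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_ps <- if (cfg$probesets_per_gene[1] == cfg$probesets_per_gene[2])
    rep(cfg$probesets_per_gene[1], cfg$n_genes)
  else sample(cfg$probesets_per_gene[1]:cfg$probesets_per_gene[2],
              cfg$n_genes, replace = TRUE)
  probes <- unlist(lapply(seq_len(cfg$n_genes), function(g)
    paste0(genes[g], "_p", seq_len(n_ps[g]))))
  probe_gene <- rep(genes, n_ps)
  mapping <- data.frame(probe_id = probes, gene_symbol = probe_gene,
                        stringsAsFactors = FALSE)

  n_de <- round(cfg$frac_de_genes * cfg$n_genes)
  de_capable <- if (n_de > 0) sample(genes, n_de) else character()

  # planted pathways: members become DE-capable with forced per-pair subsets
  planted <- list()
  if (cfg$n_planted > 0) {
    pool <- genes
    for (i in seq_len(cfg$n_planted)) {
      members <- sample(pool, cfg$planted_size)
      pool <- setdiff(pool, members)
      planted[[sprintf("PLANTED_%d", i)]] <- members
    }
  }
  planted_members <- unique(unlist(planted))
  de_capable <- union(de_capable, planted_members)

  pair_ids <- sprintf("P%02d", seq_len(cfg$n_pairs))
  active <- matrix(FALSE, cfg$n_genes, cfg$n_pairs,
                   dimnames = list(genes, pair_ids))
  dir <- matrix(1, cfg$n_genes, cfg$n_pairs,
                dimnames = list(genes, pair_ids))
  for (j in seq_len(cfg$n_pairs)) {
    act <- de_capable[stats::runif(length(de_capable)) < cfg$activation_prob]
    active[act, j] <- TRUE
    for (nm in names(planted)) {
      mem <- planted[[nm]]
      k <- max(1L, round(cfg$planted_member_frac * length(mem)))
      active[sample(mem, k), j] <- TRUE
    }
    flip <- genes[stats::runif(cfg$n_genes) < cfg$flip_prob]
    dir[flip, j] <- -1
  }

  chosen <- matrix(1L, cfg$n_genes, cfg$n_pairs,
                   dimnames = list(genes, pair_ids))
  for (j in seq_len(cfg$n_pairs))
    chosen[, j] <- vapply(n_ps, function(k) sample.int(k, 1L), 0L)

  events <- cfg$event_times
  if (is.null(events))
    events <- stats::runif(cfg$n_pairs, 0.6, 0.9) * cfg$time_horizon
  names(events) <- pair_ids

  exprs_cols <- list()
  metadata <- list()
  sd_noise <- sqrt(cfg$noise_variance)
  draw_n <- function(rng) {
    if (rng[1] == rng[2]) return(rng[1])   # guard sample()'s scalar rule
    sample(rng[1]:rng[2], 1L)
  }
  for (j in seq_len(cfg$n_pairs)) {
    n_case <- draw_n(cfg$samples_range)
    n_ctrl <- draw_n(cfg$samples_range)
    ct <- irregular_sampling(c(0, cfg$time_horizon), n_case)
    dt <- irregular_sampling(c(0, cfg$time_horizon), n_ctrl)
    t_all <- c(ct, dt)
    ci <- seq_len(n_case)
    di <- n_case + seq_len(n_ctrl)
    Fsh <- gp_draws(t_all, cfg$n_genes, cfg$lengthscale,
                    cfg$signal_variance)                       # shared draws
    Fin <- gp_draws(ct, cfg$n_genes, cfg$lengthscale,
                    cfg$signal_variance)                       # case-only draws
    bump <- cfg$bump_height *
      exp(-((t_all - (events[j] - cfg$window_weeks / 2))^2) /
            (2 * (cfg$window_weeks / 4)^2))
    M <- matrix(NA_real_, length(probes), n_case + n_ctrl)
    row <- 0L
    for (g in seq_len(cfg$n_genes)) {
      for (p in seq_len(n_ps[g])) {
        row <- row + 1L
        f_case <- Fsh[ci, g]
        f_ctrl <- Fsh[di, g]
        if (active[g, j] && p == chosen[g, j]) {
          f_case <- switch(cfg$de_mechanism,
                           independent = Fin[, g],
                           window_bump = Fsh[ci, g] + dir[g, j] * bump[ci],
                           sign_flip = dir[g, j] * -Fsh[ci, g])
        }
        M[row, ] <- c(f_case, f_ctrl) +
          stats::rnorm(n_case + n_ctrl, sd = sd_noise)
      }
    }
    ids <- c(sprintf("%s_case_%02d", pair_ids[j], seq_len(n_case)),
             sprintf("%s_control_%02d", pair_ids[j], seq_len(n_ctrl)))
    colnames(M) <- ids
    exprs_cols[[j]] <- M
    metadata[[j]] <- data.frame(
      sample_id = ids,
      pair_id = pair_ids[j],
      group = rep(c("case", "control"), c(n_case, n_ctrl)),
      time_weeks = t_all,
      stringsAsFactors = FALSE)
  }
  exprs <- do.call(cbind, exprs_cols)
  rownames(exprs) <- probes
  metadata <- do.call(rbind, metadata)
  rownames(metadata) <- NULL

  pathways <- planted
  if (cfg$n_pathways > 0) {
    sizes <- pmin(sample(cfg$pathway_size_range[1]:cfg$pathway_size_range[2],
                         cfg$n_pathways, replace = TRUE), cfg$n_genes)
    for (i in seq_len(cfg$n_pathways))
      pathways[[sprintf("PW_%03d", i)]] <- sample(genes, sizes[i])
  }

  truth <- list(
    de_capable = sort(de_capable),
    activation = active,
    direction = dir,
    chosen_probeset = chosen,
    per_pair_de = lapply(stats::setNames(seq_len(cfg$n_pairs), pair_ids),
                         function(j) genes[active[, j]]),
    planted_pathways = names(planted))

  structure(list(exprs = exprs, metadata = metadata, mapping = mapping,
                 pathways = pathways, events = events, truth = truth,
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d probe-sets (%d genes) x %d samples, %d pairs\n",
    nrow(x$exprs), x$config$n_genes, ncol(x$exprs), x$config$n_pairs))
  cat(sprintf("DE-capable genes: %d; planted pathways: %d; mechanism: %s\n",
              length(x$truth$de_capable), length(x$truth$planted_pathways),
              x$config$de_mechanism))
  invisible(x)
}
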