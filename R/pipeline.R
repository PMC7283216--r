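# Top-level orchestration: simulate/read -> score -> enrich -> report.

#' Pipeline configuration
#'
#' Either `input_dir` (a directory holding `matrix.tsv`, `metadata.tsv`,
#' optional `mapping.tsv`, `pathways.gmt` and, for window mode,
#' `events.tsv`, as written by [write_dataset()]) or `sim` (a
#' [sim_config()], simulated on the fly) must be given.
#'
#' @param input_dir Input directory, or `NULL`.
#' @param sim A [sim_config()], or `NULL`.
#' @param mode `"tc"` (whole time course, Bayes factor) or `"window"`
#'   (pre-event window, symmetric KL).
#' @param bf_threshold Bayes-factor DE threshold.
#' @param kl_threshold Numeric KL threshold, or `"calibrate"` to anchor it
#'   to borderline BF features via [calibrate_kl_threshold()].
#' @param B Number of enrichment permutations.
#' @param alpha Scaled-overlap constant.
#' @param fdr_levels FDR reporting levels.
#' @param run_combined Also run the population-wide baseline.
#' @param combined_event_time Event anchor for combined window scoring.
#' @param restarts,seed,threads As in [score_tc()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input_dir = NULL, sim = NULL,
                       mode = c("tc", "window"), bf_threshold = 4,
                       kl_threshold = "calibrate", B = 1000, alpha = 1e-6,
                       fdr_levels = c(0.1, 0.05), run_combined = TRUE,
                       combined_event_time = NULL, restarts = 5, seed = 0,
                       threads = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(input_dir) && is.null(sim))
    stop("one of 'input_dir' or 'sim' is required", call. = FALSE)
  if (!identical(kl_threshold, "calibrate") && !is.numeric(kl_threshold))
    stop("'kl_threshold' must be numeric or \"calibrate\"", call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

load_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- simulate_expression(config$sim)
    return(list(exprs = sim$exprs, metadata = sim$metadata,
                mapping = sim$mapping, pathways = sim$pathways,
                events = sim$events, sim = sim))
  }
  d <- config$input_dir
  mapping_path <- file.path(d, "mapping.tsv")
  events_path <- file.path(d, "events.tsv")
  events <- NULL
  if (file.exists(events_path)) {
    ev <- utils::read.delim(events_path, stringsAsFactors = FALSE)
    events <- stats::setNames(ev$event_time, ev$pair_id)
  }
  list(exprs = read_expression(file.path(d, "matrix.tsv")),
       metadata = read_metadata(file.path(d, "metadata.tsv")),
       mapping = if (file.exists(mapping_path)) read_mapping(mapping_path),
       pathways = read_gmt(file.path(d, "pathways.gmt")),
       events = events, sim = NULL)
}

config_digest <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  cfg <- config
  cfg$out_dir <- NULL        # hash the analysis-defining fields only
  cfg$threads <- NULL
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim)
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tf))
}

#' Run the full personalised (and combined) analysis
#'
#' Executes scoring and pathway enrichment per the configuration, optionally
#' writes score tables, enrichment tables, a machine-readable manifest
#' (config hash, seed, package version) and a human-readable summary, and
#' returns everything as a result bundle.  A rerun with an identical
#' configuration and seed reproduces identical score and p-value tables.
#'
#' @param config A [run_config()] object.
#' @return A list of class `"run_bundle"`: `scores` (probe-set level),
#'   `gene_scores`, `enrichment`, `kl_threshold` (window mode), combined
#'   results (`combined_scores`, `combined_enrichment`) when requested, and
#'   the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- load_inputs(config)
  priors <- hyper_priors()
  kl_thr <- NULL
  if (config$mode == "tc") {
    scores <- score_tc(inp$exprs, inp$metadata, priors,
                       bf_threshold = config$bf_threshold,
                       restarts = config$restarts, seed = config$seed,
                       threads = config$threads)
  } else {
    if (is.null(inp$events))
      stop("window mode needs per-pair event times", call. = FALSE)
    kl_thr <- config$kl_threshold
    bf <- score_tc(inp$exprs, inp$metadata, priors,
                   bf_threshold = config$bf_threshold,
                   restarts = config$restarts, seed = config$seed,
                   threads = config$threads)
    kl <- score_window(inp$exprs, inp$metadata, inp$events,
                       priors = priors, kl_threshold = 250,
                       restarts = config$restarts, seed = config$seed,
                       threads = config$threads)
    if (identical(kl_thr, "calibrate")) {
      key <- paste(kl$feature_id, kl$pair_id)
      bfm <- bf$score[match(key, paste(bf$feature_id, bf$pair_id))]
      kl_thr <- calibrate_kl_threshold(bfm, kl$score,
                                       bf_threshold = config$bf_threshold)
    }
    kl$is_de <- kl$score > kl_thr
    attr(kl, "threshold") <- kl_thr
    scores <- kl
  }
  gene_scores <- if (!is.null(inp$mapping))
    collapse_probesets(scores, inp$mapping)
  else scores
  enr <- enrich_permutation(scores, inp$pathways, mapping = inp$mapping,
                            B = config$B, alpha = config$alpha,
                            seed = config$seed,
                            fdr_levels = config$fdr_levels)
  bundle <- list(scores = scores, gene_scores = gene_scores,
                 enrichment = enr, kl_threshold = kl_thr)

  if (config$run_combined) {
    cs <- combined_de(inp$exprs, inp$metadata, mode = config$mode,
                      priors = priors, bf_threshold = config$bf_threshold,
                      event_time = config$combined_event_time %||%
                        if (!is.null(inp$events)) mean(inp$events),
                      kl_threshold = if (is.numeric(kl_thr)) kl_thr else 250,
                      restarts = config$restarts, seed = config$seed,
                      threads = config$threads)
    cg <- if (!is.null(inp$mapping)) collapse_probesets(cs, inp$mapping)
    else cs
    universe <- if (!is.null(inp$mapping))
      unique(inp$mapping$gene_symbol[inp$mapping$probe_id %in%
                                       rownames(inp$exprs)])
    else rownames(inp$exprs)
    ce <- fisher_enrichment(unique(cg$feature_id[cg$is_de]), universe,
                            inp$pathways, fdr_levels = config$fdr_levels)
    bundle$combined_scores <- cs
    bundle$combined_enrichment <- ce
  }

  manifest <- list(package = "pgpde",
                   version = as.character(utils::packageVersion("pgpde")),
                   seed = config$seed,
                   mode = config$mode,
                   kl_threshold = kl_thr,
                   config_md5 = config_digest(config))
  bundle$manifest <- manifest

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_scores(bundle$scores, file.path(d, "scores_personalised.tsv"))
    utils::write.table(as.data.frame(bundle$enrichment),
                       file.path(d, "enrichment_personalised.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (config$run_combined) {
      write_scores(bundle$combined_scores,
                   file.path(d, "scores_combined.tsv"))
      utils::write.table(as.data.frame(bundle$combined_enrichment),
                         file.path(d, "enrichment_combined.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    summ <- c(sprintf("pgpde run (mode = %s, seed = %d, config %s)",
                      config$mode, config$seed, manifest$config_md5),
              sprintf("features scored: %d",
                      length(unique(bundle$scores$feature_id))),
              sprintf("pairs: %d", length(unique(bundle$scores$pair_id))),
              vapply(config$fdr_levels, function(lev) {
                n_p <- sum(bundle$enrichment$fdr < lev)
                n_c <- if (config$run_combined)
                  sum(bundle$combined_enrichment$fdr < lev) else NA
                sprintf("enriched pathways at FDR < %g: personalised %d%s",
                        lev, n_p,
                        if (is.na(n_c)) "" else sprintf(", combined %d", n_c))
              }, ""))
    writeLines(summ, file.path(d, "summary.txt"))
  }
  structure(bundle, class = "run_bundle")
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("pgpde run bundle\n")
  print(x$scores)
  print(x$enrichment)
  invisible(x)
}
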