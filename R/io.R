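# Readers and writers.  All tabular IO is TSV; pathway input is GMT
# (MSigDB-style: name, description, member genes, tab-delimited).

#' Read a features x samples expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' `NA`/`NaN` cells are rejected with their location.
#'
#' @param path File path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite expression value at row '%s', column '%s'",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]),
         call. = FALSE)
  m
}

#' Write an expression matrix as TSV
#'
#' @param exprs Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @export
write_expression <- function(exprs, path) {
  df <- data.frame(feature_id = rownames(exprs), exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `pair_id`, `group`, `time_weeks`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pair_id", "group", "time_weeks")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  md
}

#' Read a probe-set to gene mapping from TSV
#'
#' Requires columns `probe_id` and `gene_symbol`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_mapping <- function(path) {
  mp <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("probe_id", "gene_symbol"), names(mp))
  if (length(miss))
    stop("mapping lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mp
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited lines `name<TAB>description<TAB>gene...`; tolerant of CRLF
#' line endings and trailing tabs.  Duplicate pathway names are an error;
#' duplicate genes within a set are dropped with a message.
#'
#' @param path File path.
#' @return Named list of character vectors, with the file recorded in the
#'   `"source"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  ndup <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts) | seq_along(parts) <= 2L]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 50), call. = FALSE)
    nm <- parts[1L]
    if (nm %in% names(out))
      stop("duplicate pathway name in GMT: ", nm, call. = FALSE)
    genes <- parts[-(1:2)]
    ndup <- ndup + sum(duplicated(genes))
    out[[nm]] <- unique(genes)
  }
  if (ndup > 0L)
    message(ndup, " duplicate gene entr(ies) within sets deduplicated")
  attr(out, "source") <- path
  out
}

#' Write gene sets to a GMT file
#'
#' @param pathways Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(pathways, path, description = "na") {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, description, pathways[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Emits `matrix.tsv`, `metadata.tsv`, `mapping.tsv`, `pathways.gmt`,
#' `events.tsv` and `truth.json` -- exactly the formats the scoring and
#' enrichment functions read back.
#'
#' @param sim A `"sim_dataset"` from [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$exprs, file.path(dir, "matrix.tsv"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$mapping, file.path(dir, "mapping.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  utils::write.table(
    data.frame(pair_id = names(sim$events), event_time = sim$events),
    file.path(dir, "events.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- sim$truth
  truth$activation <- as.data.frame(truth$activation)
  truth$direction <- as.data.frame(truth$direction)
  truth$chosen_probeset <- as.data.frame(truth$chosen_probeset)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write DE scores as long-format TSV
#'
#' @param scores A `"de_scores"` data frame.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
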