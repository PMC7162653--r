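# Readers, writers, configuration and the simulate -> analyze -> report
# pipeline. Pair and cell tables travel as tab- (or comma-) separated text
# with a header; expression as matrix-market sparse plus gene/cell sidecars;
# configuration as JSON or YAML. Lengths in files are micrometres.

#' Read a pair-test table
#'
#' Reads a delimited table of tested directed connections (TSV by default;
#' the comma dialect is auto-detected), validates the schema, normalizes
#' layer tokens (e.g. `L23` to `L2/3`) and reports malformed rows by line.
#'
#' @param path file path.
#' @return a validated pair-table tibble.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("pre_layer", "post_layer", "relation", "connected")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Pair table at %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  for (col in c("pre_layer", "post_layer")) {
    bad <- which(is.na(suppressWarnings(
      tryCatch(normalize_layer(raw[[col]]), error = function(e) rep(NA, nrow(raw)))
    )) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Invalid layer token in column `%s` at data row(s): %s",
                    col, paste(utils::head(bad, 5), collapse = ", ")))
    }
    raw[[col]] <- normalize_layer(raw[[col]])
  }
  if (!all(raw$relation %in% c("related", "unrelated", "control_any_unlabeled"))) {
    bad <- which(!raw$relation %in%
                   c("related", "unrelated", "control_any_unlabeled"))
    abort(sprintf("Invalid relation at data row(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  raw$connected <- as.logical(raw$connected)
  if (anyNA(raw$connected)) {
    abort(sprintf("Non-boolean `connected` at data row(s): %s",
                  paste(utils::head(which(is.na(raw$connected)), 5),
                        collapse = ", ")))
  }
  if ("rostrocaudal" %in% names(raw) &&
      !all(is.na(raw$rostrocaudal) | raw$rostrocaudal %in% 1:5)) {
    abort("`rostrocaudal` must take integer values 1-5.")
  }
  raw
}

#' Write a pair-test table as TSV
#'
#' @param pairs a pair table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  validate_pair_table(pairs)
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' Write an expression matrix as sparse matrix-market with sidecars
#'
#' Writes `<prefix>.mtx` (sparse counts), `<prefix>.genes.tsv` and
#' `<prefix>.cells.tsv`.
#'
#' @param counts genes x cells count matrix.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_expression_mtx <- function(counts, prefix) {
  m <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  readr::write_tsv(tibble(gene = rownames(counts)),
                   paste0(prefix, ".genes.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(tibble(cell = colnames(counts)),
                   paste0(prefix, ".cells.tsv"), col_names = FALSE,
                   progress = FALSE)
  invisible(prefix)
}

#' Read an expression matrix written by [write_expression_mtx()]
#'
#' @param prefix path prefix used at write time.
#' @return a dense genes x cells count matrix with dimnames.
#' @export
read_expression_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  genes <- readr::read_tsv(paste0(prefix, ".genes.tsv"), col_names = "gene",
                           show_col_types = FALSE, progress = FALSE)$gene
  cells <- readr::read_tsv(paste0(prefix, ".cells.tsv"), col_names = "cell",
                           show_col_types = FALSE, progress = FALSE)$cell
  dimnames(m) <- list(genes, cells)
  storage.mode(m) <- "integer"
  m
}

#' Read a run configuration from JSON or YAML
#'
#' @param path a `.json`, `.yaml` or `.yml` file of [sim_config()] arguments
#'   (plus optional `stages` and `out_dir`).
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$layer_fractions)) {
    cfg$layer_fractions <- unlist(cfg$layer_fractions)
  }
  if (!is.null(cfg$conn_probs)) cfg$conn_probs <- as_tibble(cfg$conn_probs)
  cfg
}

#' Run a simulate / analyze / report pipeline
#'
#' Simulates a clone population and pair-test table, runs the connectivity
#' analyses (per-type connection probabilities, pooled vertical/lateral
#' comparison, smoothed log-ratios), and writes the pair table (TSV) plus a
#' JSON summary carrying the package version, master seed, configuration
#' hash and every statistic with its interval. Two runs with the same
#' configuration produce byte-identical summaries.
#'
#' @param config a [sim_config()], or a list of arguments for one (e.g. from
#'   [read_run_config()]); `stages` (subset of `"simulate"`, `"connectivity"`)
#'   and `out_dir` entries are honoured when given as a list.
#' @param out_dir output directory (default: temporary directory).
#' @param stages pipeline stages to run (default both).
#' @return a list with the generated objects and output paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir = tempfile("run"),
                         stages = c("simulate", "connectivity")) {
  if (!inherits(config, "sim_config")) {
    extra <- intersect(names(config), c("stages", "out_dir"))
    if ("stages" %in% extra) stages <- config$stages
    if ("out_dir" %in% extra) out_dir <- config$out_dir
    config <- do.call(sim_config, config[setdiff(names(config), extra)])
  }
  stages <- match.arg(stages, c("simulate", "connectivity"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- digest::digest(config)
  result <- list(out_dir = out_dir, config = config, config_hash = cfg_hash)

  cells <- simulate_clone_population(config)
  pairs <- simulate_pair_tests(cells, config)
  if ("simulate" %in% stages) {
    write_pair_table(pairs, file.path(out_dir, "pair_table.tsv"))
    result$cells <- cells
    result$pairs <- pairs
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("clonecircuits")),
    seed = config$seed,
    config_hash = cfg_hash,
    n_cells = nrow(cells),
    n_pairs = nrow(pairs)
  )
  if ("connectivity" %in% stages) {
    per_type <- connection_probability(
      pairs, .data$relation %in% c("related", "unrelated"),
      by = c("relation", "pre_layer", "post_layer"))
    pooled <- connection_probability(
      pairs, .data$relation %in% c("related", "unrelated"),
      by = c("relation", "class"))
    lr <- log_ratio_table(pairs, seed = substream_seed(config$seed, "logratio"))
    readr::write_tsv(per_type, file.path(out_dir, "connection_probability.tsv"),
                     progress = FALSE)
    readr::write_tsv(lr, file.path(out_dir, "log_ratios.tsv"), progress = FALSE)
    summary$connection_probability <- per_type
    summary$pooled <- pooled
    summary$log_ratios <- lr
    result$connection_probability <- per_type
    result$log_ratios <- lr
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result$summary_path <- file.path(out_dir, "summary.json")
  invisible(result)
}
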