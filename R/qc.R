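# Single-cell quality control and normalization.

#' Remove low-quality cells by robust outlier detection
#'
#' Flags cells more than `n_mads` median absolute deviations below the
#' median on either total counts (library size) or number of genes detected,
#' and removes them.
#'
#' @param counts genes x cells count matrix (column names are cell ids).
#' @param metadata optional data frame with a `cell_id` column, subset in
#'   step with the counts.
#' @param n_mads threshold in MADs (default 3).
#' @return a list with `counts`, `metadata` (NULL if not supplied) and
#'   `removed_cells` (character). Errors if every cell would be removed.
#' @export
qc_filter_cells <- function(counts, metadata = NULL, n_mads = 3) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 4) abort("Need at least 4 cells for robust QC.")
  lib <- colSums(counts)
  ngene <- colSums(counts > 0)
  low <- function(x) x < median(x) - n_mads * mad(x)
  bad <- low(lib) | low(ngene)
  if (all(bad)) abort("QC would remove every cell; check the input.")
  removed <- colnames(counts)[bad]
  out <- list(counts = counts[, !bad, drop = FALSE],
              metadata = NULL, removed_cells = removed)
  if (!is.null(metadata)) {
    if (!"cell_id" %in% names(metadata)) abort("`metadata` needs a `cell_id` column.")
    out$metadata <- filter(as_tibble(metadata), !.data$cell_id %in% removed)
  }
  out
}

#' Remove genes with low average expression
#'
#' Keeps genes with at least `min_mean` counts per cell on average (genes
#' with strictly less are removed; a mean of exactly `min_mean` is kept).
#'
#' @param counts genes x cells count matrix.
#' @param min_mean minimum mean count per cell (default 1).
#' @return the subset count matrix, with attribute `kept_genes`.
#' @export
filter_genes <- function(counts, min_mean = 1) {
  counts <- as.matrix(counts)
  keep <- rowMeans(counts) >= min_mean
  out <- counts[keep, , drop = FALSE]
  attr(out, "kept_genes") <- rownames(counts)[keep]
  out
}

#' Size-factor normalization and log transform
#'
#' Size factor = library size / geometric mean of library sizes (so factors
#' average to 1 on the log scale); normalized expression =
#' `log2(count / size_factor + 1)`. Precomputed size factors (e.g. from a
#' pooling-based method) can be supplied instead.
#'
#' @param counts genes x cells count matrix with positive library sizes.
#' @param size_factors optional positive numeric vector, one per cell.
#' @return a list with `size_factors` (named per cell) and `logcounts`
#'   (genes x cells matrix of normalized log2 expression).
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort("Zero-library cells present; run qc_filter_cells() first.")
  }
  if (is.null(size_factors)) {
    size_factors <- lib / exp(mean(log(lib)))
  } else if (length(size_factors) != ncol(counts) || any(size_factors <= 0)) {
    abort("`size_factors` must be positive, one per cell.")
  }
  names(size_factors) <- colnames(counts)
  logcounts <- log2(sweep(counts, 2, size_factors, "/") + 1)
  list(size_factors = size_factors, logcounts = logcounts)
}
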