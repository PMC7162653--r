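# Reference-atlas mapping: variable-gene selection, kNN embedding placement,
# bootstrap precision, nearest-centroid cluster assignment and same-type
# pair statistics.

#' Select highly variable genes by the dropout-vs-expression curve
#'
#' Targets genes with simultaneously high non-zero expression and high
#' probability of near-zero expression. Genes with counts of at least
#' `count_threshold` in fewer than `min_cells` cells are excluded. For each
#' remaining gene, `mu` is the mean log2 count over counts strictly above
#' the threshold and `tau` is the fraction of counts strictly below it
#' (counts equal to the threshold enter neither statistic). A binary search
#' over the offset `b` finds the value at which exactly `n_target` genes
#' satisfy `tau > exp(slope * mu + b) + margin`, or the closest achievable
#' count when ties on the curve make the exact count unattainable.
#'
#' @param counts genes x cells raw count matrix (reference data).
#' @param count_threshold expression threshold (default 32).
#' @param min_cells minimum number of cells at or above the threshold
#'   (default 10).
#' @param slope exponential-law slope (default -1.5).
#' @param margin additive offset on the curve (default 0.02).
#' @param n_target number of genes to select (default 3000).
#' @return character vector of selected gene names, with attributes `b`
#'   (fitted offset) and `stats` (tibble of `gene`, `mu`, `tau` for all
#'   candidates). If fewer than `n_target` candidates survive exclusion, all
#'   are returned with a warning.
#' @export
select_variable_genes <- function(counts, count_threshold = 32, min_cells = 10,
                                  slope = -1.5, margin = 0.02, n_target = 3000) {
  counts <- as.matrix(counts)
  if (count_threshold <= 0) abort("`count_threshold` must be positive.")
  check_count(n_target, "n_target", min = 1)
  n_high <- rowSums(counts >= count_threshold)
  cand <- which(n_high >= min_cells)
  if (length(cand) == 0) abort("No genes survive the expression exclusion rule.")
  mu <- unname(apply(counts[cand, , drop = FALSE], 1, function(x) {
    mean(log2(x[x > count_threshold]))
  }))
  tau <- unname(rowMeans(counts[cand, , drop = FALSE] < count_threshold))
  stats <- tibble(gene = rownames(counts)[cand], mu = mu, tau = tau)

  n_selected <- function(b) sum(tau > exp(slope * mu + b) + margin)
  if (length(cand) < n_target) {
    warn(sprintf("Only %d candidate genes for n_target = %d; returning all.",
                 length(cand), n_target))
    out <- stats$gene
    attr(out, "b") <- -Inf
    attr(out, "stats") <- stats
    return(out)
  }
  # n_selected is non-increasing in b: bracket then bisect
  lo <- -50; hi <- 50
  best_b <- NA_real_
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    n_mid <- n_selected(mid)
    if (n_mid == n_target) { best_b <- mid; break }
    if (n_mid > n_target) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  if (is.na(best_b)) best_b <- (lo + hi) / 2
  sel <- tau > exp(slope * mu + best_b) + margin
  out <- stats$gene[sel]
  attr(out, "b") <- best_b
  attr(out, "stats") <- stats
  out
}

#' Position query cells on a reference embedding by correlation kNN
#'
#' For each query cell, computes the Pearson correlation of its log2(x+1)
#' expression with every reference cell over the shared gene set, finds the
#' `k` most correlated reference cells, and places the query at the
#' coordinate-wise median of their embedding positions.
#'
#' @param query_log genes x cells matrix of log2(x+1) expression (query).
#' @param ref_log genes x cells matrix of log2(x+1) expression (reference).
#' @param embedding data frame with `cell_id`, `dim1`, `dim2` for reference
#'   cells (a fixed, precomputed 2-D embedding; it is never computed here).
#' @param genes character vector of shared genes to use; defaults to the
#'   intersection of the two row name sets.
#' @param k number of nearest neighbours (default 10).
#' @return a tibble with `cell_id`, `dim1`, `dim2`, `flagged` (TRUE for
#'   query cells with zero variance over the shared genes, whose position is
#'   NA).
#' @export
map_cells_knn <- function(query_log, ref_log, embedding, genes = NULL, k = 10) {
  check_count(k, "k", min = 1)
  if (is.null(genes)) genes <- intersect(rownames(query_log), rownames(ref_log))
  if (length(genes) == 0) abort("The shared gene set is empty.")
  q <- as.matrix(query_log)[genes, , drop = FALSE]
  r <- as.matrix(ref_log)[genes, , drop = FALSE]
  ref_pos <- as_tibble(embedding)
  if (!all(colnames(r) %in% ref_pos$cell_id)) {
    abort("Every reference cell needs an embedding position.")
  }
  ref_pos <- ref_pos[match(colnames(r), ref_pos$cell_id), ]

  flagged <- apply(q, 2, sd) == 0 | is.na(apply(q, 2, sd))
  pos <- matrix(NA_real_, ncol(q), 2)
  ok <- which(!flagged)
  if (length(ok) > 0) {
    cors <- suppressWarnings(cor(q[, ok, drop = FALSE], r))
    for (i in seq_along(ok)) {
      nn <- order(cors[i, ], decreasing = TRUE)[seq_len(min(k, ncol(r)))]
      pos[ok[i], ] <- c(median(ref_pos$dim1[nn]), median(ref_pos$dim2[nn]))
    }
  }
  if (any(flagged)) {
    warn(sprintf("%d query cell(s) had zero variance over the shared genes and were skipped.",
                 sum(flagged)))
  }
  tibble(cell_id = colnames(q), dim1 = pos[, 1], dim2 = pos[, 2],
         flagged = unname(flagged))
}

#' Gene-bootstrap precision of the embedding placement
#'
#' Repeats [map_cells_knn()] on bootstrap resamples of the shared gene set
#' (with replacement, same size) and reports, per query cell, the 80th
#' percentile (configurable) of the Euclidean displacement from the original
#' position — small when the placement is stable. Size classes follow the
#' display convention: precision > 10 "small" (uncertain), (5, 10]
#' "intermediate", <= 5 "large" (confident).
#'
#' @inheritParams map_cells_knn
#' @param reps bootstrap resamples (default 100).
#' @param percentile displacement percentile reported (default 80).
#' @param seed optional integer seed.
#' @return a tibble with `cell_id`, `precision`, `size_class`.
#' @export
mapping_precision_bootstrap <- function(query_log, ref_log, embedding,
                                        genes = NULL, reps = 100,
                                        percentile = 80, k = 10, seed = NULL) {
  check_count(reps, "reps", min = 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes)) genes <- intersect(rownames(query_log), rownames(ref_log))
  base <- map_cells_knn(query_log, ref_log, embedding, genes, k)
  disp <- matrix(NA_real_, nrow(base), reps)
  for (b in seq_len(reps)) {
    g_boot <- sample(genes, length(genes), replace = TRUE)
    pos_b <- suppressWarnings(
      map_cells_knn(query_log, ref_log, embedding, g_boot, k))
    disp[, b] <- sqrt((pos_b$dim1 - base$dim1)^2 + (pos_b$dim2 - base$dim2)^2)
  }
  precision <- apply(disp, 1, function(d) {
    if (all(is.na(d))) NA_real_ else quantile(d, percentile / 100, na.rm = TRUE)
  })
  tibble(
    cell_id = base$cell_id,
    precision = unname(precision),
    size_class = dplyr::case_when(
      is.na(precision) ~ NA_character_,
      precision > 10 ~ "small",
      precision > 5 ~ "intermediate",
      TRUE ~ "large"
    )
  )
}

#' Mean log-expression centroids of reference clusters
#'
#' @param ref_log genes x cells matrix of log2(x+1) reference expression.
#' @param clusters cluster label per reference cell (named or in column
#'   order).
#' @return clusters x genes matrix of mean log profiles.
#' @export
cluster_centroids <- function(ref_log, clusters) {
  ref_log <- as.matrix(ref_log)
  if (length(clusters) != ncol(ref_log)) {
    abort("`clusters` must have one label per reference cell.")
  }
  labs <- sort(unique(as.character(clusters)))
  cent <- vapply(labs, function(cl) {
    rowMeans(ref_log[, clusters == cl, drop = FALSE])
  }, numeric(nrow(ref_log)))
  t(cent)
}

#' Nearest-centroid cluster assignment
#'
#' Assigns each query cell to the reference cluster whose mean log2(x+1)
#' profile has the highest Pearson correlation with the cell, over the
#' shared gene set. Ties go to the first cluster in sorted label order and
#' are reported via the `tie` column.
#'
#' @param query_log genes x cells matrix of log2(x+1) query expression.
#' @param centroids clusters x genes centroid matrix from
#'   [cluster_centroids()].
#' @param genes shared genes to use (default: intersection).
#' @param class_map optional data frame with `cluster`, `class` columns
#'   mapping clusters to broad classes.
#' @return a tibble with `cell_id`, `cluster`, `best_cor`, `tie` and, when
#'   `class_map` is given, `class`.
#' @export
assign_to_clusters <- function(query_log, centroids, genes = NULL,
                               class_map = NULL) {
  q <- as.matrix(query_log)
  cent <- as.matrix(centroids)
  if (is.null(genes)) genes <- intersect(rownames(q), colnames(cent))
  if (length(genes) == 0) abort("The shared gene set is empty.")
  cors <- suppressWarnings(cor(q[genes, , drop = FALSE],
                               t(cent[, genes, drop = FALSE])))
  labs <- rownames(cent)[order(rownames(cent))]
  cors <- cors[, order(colnames(cors)), drop = FALSE]
  best <- apply(cors, 1, which.max)
  ties <- apply(cors, 1, function(x) sum(x == max(x)) > 1)
  out <- tibble(
    cell_id = colnames(q),
    cluster = colnames(cors)[best],
    best_cor = cors[cbind(seq_len(nrow(cors)), best)],
    tie = unname(ties)
  )
  if (!is.null(class_map)) {
    out <- left_join(out, as_tibble(class_map), by = "cluster")
  }
  out
}

#' Probability that cell pairs map to the same type
#'
#' For each lineage group, the number of pairs whose two cells carry the
#' same type label as a fraction of all pairs in the group, with 95%
#' Clopper-Pearson intervals and a chi-squared comparison between groups.
#'
#' @param pairs data frame with columns `cell1`, `cell2`, `group` (e.g.
#'   "related"/"unrelated").
#' @param types data frame with `cell_id`, `type` and, if
#'   `condition_on_layer`, `layer`.
#' @param condition_on_layer keep only pairs whose cells sit in the same
#'   layer (default FALSE).
#' @param dedupe drop duplicated (unordered) pairs before counting
#'   (default FALSE).
#' @return a tibble with one row per group (`group`, `k`, `n`, `fraction`,
#'   `ci_low`, `ci_high`) and the between-group chi-squared test in
#'   attribute `test`.
#' @export
same_type_pair_probability <- function(pairs, types,
                                       condition_on_layer = FALSE,
                                       dedupe = FALSE) {
  need <- c("cell1", "cell2", "group")
  if (!all(need %in% names(pairs))) abort("`pairs` needs cell1, cell2, group.")
  if (!all(c("cell_id", "type") %in% names(types))) {
    abort("`types` needs cell_id and type.")
  }
  dat <- as_tibble(pairs) |>
    left_join(as_tibble(types) |> rename(type1 = "type"),
              by = c(cell1 = "cell_id")) |>
    left_join(as_tibble(types) |> rename(type2 = "type"),
              by = c(cell2 = "cell_id"), suffix = c("_1", "_2"))
  if (anyNA(dat$type1) || anyNA(dat$type2)) {
    abort("Some pairs reference cells without a type label.")
  }
  if (condition_on_layer) {
    if (!all(c("layer_1", "layer_2") %in% names(dat))) {
      abort("`types` needs a layer column when condition_on_layer = TRUE.")
    }
    dat <- filter(dat, .data$layer_1 == .data$layer_2)
  }
  if (dedupe) {
    key <- paste(pmin(dat$cell1, dat$cell2), pmax(dat$cell1, dat$cell2),
                 dat$group)
    dat <- dat[!duplicated(key), ]
  }
  if (nrow(dat) == 0) abort("No pairs left to analyse.")
  out <- dat |>
    group_by(.data$group) |>
    summarise(k = sum(.data$type1 == .data$type2), n = dplyr::n(),
              .groups = "drop")
  if (any(out$n == 0)) abort("A group has no pairs.")
  out <- dplyr::bind_cols(out, clopper_pearson(out$k, out$n)) |>
    mutate(fraction = .data$k / .data$n) |>
    select("group", "k", "n", "fraction", "ci_low", "ci_high")
  if (nrow(out) > 1) {
    tab <- as.matrix(out[, c("k", "n")])
    tab <- cbind(tab[, 1], tab[, 2] - tab[, 1])
    attr(out, "test") <- tryCatch(chi_squared_test(tab),
                                  error = function(e) NULL)
  }
  out
}
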