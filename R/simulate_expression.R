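# Synthetic expression matrices and a clustered reference atlas.

#' Simulate query expression and a clustered reference atlas
#'
#' Draws negative-binomial counts per cell around its cluster's mean profile,
#' scaled by a per-cell library-size factor. Cluster means share a common
#' baseline with disjoint sets of upregulated marker genes, so clusters are
#' separable by construction. The reference atlas carries a fixed 2-D
#' embedding: cluster centroids equally spaced on a circle, reference cells
#' jittered around their centroid.
#'
#' Expression settings (in `config$expression`): `n_genes`, `n_clusters`,
#' `n_markers_per_cluster`, `baseline_mean`, `marker_mean`, `dispersion`
#' (NB size parameter; must be positive), `poisson` (TRUE for the
#' infinite-dispersion Poisson limit), `lib_size_range`,
#' `n_ref_per_cluster`, `embedding_separation`, `embedding_jitter`.
#'
#' @param cells a cell table from [simulate_clone_population()]; labeled
#'   cells become query cells, each assigned uniformly to a cluster.
#' @param config a [sim_config()].
#' @param seed optional integer overriding the config's expression substream.
#' @return a list with elements
#'   \describe{
#'     \item{bundle}{query data: `counts` (genes x cells), `metadata` tibble
#'       (`cell_id`, `clone_id`, `layer`, `tdtomato`, `region`,
#'       `true_cluster`).}
#'     \item{atlas}{reference data of class `reference_atlas`: `counts`,
#'       `clusters` (label per reference cell), `embedding` tibble
#'       (`cell_id`, `dim1`, `dim2`), `centroid_positions`.}
#'   }
#' @export
simulate_expression <- function(cells, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  if (!isTRUE(ex$poisson) && ex$dispersion <= 0) {
    abort("Expression `dispersion` must be positive (or set `poisson = TRUE`).")
  }
  if (ex$n_clusters < 2) abort("Need at least 2 clusters.")
  set.seed(if (is.null(seed)) substream_seed(config$seed, "expression") else seed)

  genes <- sprintf("gene_%04d", seq_len(ex$n_genes))
  k <- ex$n_clusters
  if (k * ex$n_markers_per_cluster > ex$n_genes) {
    abort("Not enough genes for the requested marker sets.")
  }
  # disjoint marker blocks per cluster
  means <- matrix(ex$baseline_mean, nrow = ex$n_genes, ncol = k,
                  dimnames = list(genes, paste0("cluster_", seq_len(k))))
  for (cl in seq_len(k)) {
    block <- ((cl - 1) * ex$n_markers_per_cluster + 1):(cl * ex$n_markers_per_cluster)
    means[block, cl] <- ex$marker_mean
  }

  draw_counts <- function(cluster_idx, ids) {
    lib <- runif(length(cluster_idx), ex$lib_size_range[1], ex$lib_size_range[2])
    mu <- sweep(means[, cluster_idx, drop = FALSE], 2, lib, "*")
    counts <- if (isTRUE(ex$poisson)) {
      matrix(rpois(length(mu), mu), nrow = ex$n_genes)
    } else {
      matrix(rnbinom(length(mu), size = ex$dispersion, mu = mu),
             nrow = ex$n_genes)
    }
    dimnames(counts) <- list(genes, ids)
    counts
  }

  query_cells <- filter(as_tibble(cells), .data$tdtomato)
  q_cluster <- sample.int(k, nrow(query_cells), replace = TRUE)
  q_counts <- draw_counts(q_cluster, query_cells$cell_id)
  metadata <- query_cells |>
    select("cell_id", "clone_id", "layer", "tdtomato") |>
    mutate(region = ifelse(query_cells$rostrocaudal <= 3, "SS1", "V1"),
           true_cluster = colnames(means)[q_cluster])

  n_ref <- k * ex$n_ref_per_cluster
  ref_cluster <- rep(seq_len(k), each = ex$n_ref_per_cluster)
  ref_ids <- sprintf("ref_%05d", seq_len(n_ref))
  ref_counts <- draw_counts(ref_cluster, ref_ids)

  angle <- 2 * pi * (seq_len(k) - 1) / k
  centroids <- cbind(dim1 = ex$embedding_separation * cos(angle),
                     dim2 = ex$embedding_separation * sin(angle))
  embedding <- tibble(
    cell_id = ref_ids,
    dim1 = centroids[ref_cluster, 1] + rnorm(n_ref, sd = ex$embedding_jitter),
    dim2 = centroids[ref_cluster, 2] + rnorm(n_ref, sd = ex$embedding_jitter)
  )

  atlas <- structure(
    list(counts = ref_counts,
         clusters = setNames(colnames(means)[ref_cluster], ref_ids),
         embedding = embedding,
         centroid_positions = tibble(cluster = colnames(means),
                                     dim1 = centroids[, 1],
                                     dim2 = centroids[, 2])),
    class = "reference_atlas"
  )
  list(bundle = list(counts = q_counts, metadata = metadata), atlas = atlas)
}
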