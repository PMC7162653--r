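# Synthetic clone populations and pair-test tables.
#
# The generator emulates the study design: translaminar clones of labeled
# excitatory neurons (each pooling several radial-glial lineages) embedded
# in a cortical cylinder of unlabeled background cells, with paired tests of
# directed connections drawn Bernoulli at configurable per-type rates.

#' Simulation configuration
#'
#' Study conditions for the synthetic-data generators. Defaults follow the
#' measured design: median clone size 60 split over 2 radial-glial lineages,
#' layer occupancy 35/15/25/25% over L2/3-L6, a cylinder of tangential
#' radius 0.087 mm at 100,000 neurons/mm^2 (80% excitatory), and
#' per-connection-type probabilities equal to the published rates
#' ([default_conn_probs()]).
#'
#' @param clone_size labeled neurons per clone (default 60).
#' @param n_lineages radial-glial lineages per clone, `N` (default 2).
#' @param n_clones number of clones (default 5).
#' @param layer_fractions named fractions over layers, summing to 1.
#' @param conn_probs data frame with columns `relation`, `pre_layer`,
#'   `post_layer`, `prob` (default [default_conn_probs()]).
#' @param n_pairs_per_type tested pairs drawn per `conn_probs` row
#'   (default 100).
#' @param bidir_fraction fraction of sampled pairs also tested in the
#'   reverse direction (default 0.5).
#' @param cylinder_radius_mm tangential radius of the cylinder (default 0.087).
#' @param neurons_per_mm2,excitatory_fraction background density (defaults
#'   100,000 and 0.8).
#' @param cortical_depth_um total depth spanned by the layers (default 1200).
#' @param expression list of expression-model settings; see
#'   [simulate_expression()]. Missing entries take defaults.
#' @param seed integer master seed; per-operation substreams are derived
#'   from it so the generators can be used independently.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(clone_size = 60,
                       n_lineages = 2,
                       n_clones = 5,
                       layer_fractions = c("L2/3" = 0.35, "L4" = 0.15,
                                           "L5" = 0.25, "L6" = 0.25),
                       conn_probs = default_conn_probs(),
                       n_pairs_per_type = 100,
                       bidir_fraction = 0.5,
                       cylinder_radius_mm = 0.087,
                       neurons_per_mm2 = 1e5,
                       excitatory_fraction = 0.8,
                       cortical_depth_um = 1200,
                       expression = list(),
                       seed = 1L) {
  check_count(clone_size, "clone_size", min = 1)
  check_count(n_lineages, "n_lineages", min = 1)
  check_count(n_clones, "n_clones", min = 1)
  if (clone_size < n_lineages) abort("`clone_size` must be >= `n_lineages`.")
  if (abs(sum(layer_fractions) - 1) > 1e-9) abort("`layer_fractions` must sum to 1.")
  check_prob(layer_fractions, "layer_fractions")
  need <- c("relation", "pre_layer", "post_layer", "prob")
  if (!all(need %in% names(conn_probs))) {
    abort("`conn_probs` needs columns relation, pre_layer, post_layer, prob.")
  }
  if (anyNA(conn_probs$prob)) abort("`conn_probs` contains a missing probability.")
  check_prob(conn_probs$prob, "conn_probs$prob")
  check_count(n_pairs_per_type, "n_pairs_per_type", min = 1)
  check_prob(bidir_fraction, "bidir_fraction")
  expr_defaults <- list(
    n_genes = 200, n_clusters = 4, n_markers_per_cluster = 15,
    baseline_mean = 0.5, marker_mean = 8, dispersion = 2, poisson = FALSE,
    lib_size_range = c(0.5, 2), n_ref_per_cluster = 30,
    embedding_separation = 20, embedding_jitter = 1
  )
  expression <- utils::modifyList(expr_defaults, expression)
  if (!isTRUE(expression$poisson) && expression$dispersion <= 0) {
    abort("Expression `dispersion` must be positive (or set `poisson = TRUE`).")
  }
  structure(
    list(clone_size = clone_size, n_lineages = n_lineages, n_clones = n_clones,
         layer_fractions = layer_fractions, conn_probs = as_tibble(conn_probs),
         n_pairs_per_type = n_pairs_per_type, bidir_fraction = bidir_fraction,
         cylinder_radius_mm = cylinder_radius_mm,
         neurons_per_mm2 = neurons_per_mm2,
         excitatory_fraction = excitatory_fraction,
         cortical_depth_um = cortical_depth_um,
         expression = expression, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Published per-type connection probabilities as generator defaults
#'
#' The per-connection-type rates measured in the study (see
#' [clonal_connection_counts()]) as Bernoulli probabilities for
#' [simulate_pair_tests()].
#'
#' @return a tibble with columns `relation`, `pre_layer`, `post_layer`,
#'   `prob`.
#' @export
default_conn_probs <- function() {
  counts <- clonal_connection_counts()
  bind_rows(
    counts |>
      mutate(relation = "related", prob = .data$k_r / .data$m_r) |>
      select("relation", "pre_layer", "post_layer", "prob"),
    counts |>
      mutate(relation = "unrelated", prob = .data$k_u / .data$m_u) |>
      select("relation", "pre_layer", "post_layer", "prob")
  )
}

# deterministic per-operation substream of the master seed
substream_seed <- function(seed, salt) {
  abs(digest::digest2int(paste(seed, salt, sep = "/"))) %% 2147483646L + 1L
}

#' Simulate clone populations in cortical cylinders
#'
#' Generates, for each clone, `clone_size` labeled cells split multinomially
#' over `n_lineages` lineages and over layers by `layer_fractions`, plus
#' unlabeled background cells filling the cylinder to the configured
#' excitatory density. Tangential positions are uniform in the cylinder
#' disc; depth is uniform within the cell's layer band.
#'
#' @param config a [sim_config()].
#' @return a tibble (one row per cell): `cell_id`, `cylinder_id`, `clone_id`
#'   (NA for background), `lineage_id` (NA for background), `layer`, `x_um`,
#'   `y_um`, `depth_um`, `tdtomato`, `rostrocaudal` (clone position, 1-5).
#' @export
simulate_clone_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "clones"))
  r_um <- config$cylinder_radius_mm * 1000
  n_bg <- max(0L, round(pi * config$cylinder_radius_mm^2 *
                          config$neurons_per_mm2 * config$excitatory_fraction) -
                config$clone_size)
  layers <- names(config$layer_fractions)
  bounds <- c(0, cumsum(config$layer_fractions)) * config$cortical_depth_um

  one_clone <- function(cl) {
    n_lab <- config$clone_size
    lineage <- sample.int(config$n_lineages, n_lab, replace = TRUE)
    n_tot <- n_lab + n_bg
    layer_idx <- sample.int(length(layers), n_tot, replace = TRUE,
                            prob = config$layer_fractions)
    # uniform positions in the disc
    rho <- r_um * sqrt(runif(n_tot))
    theta <- runif(n_tot, 0, 2 * pi)
    depth <- runif(n_tot, bounds[layer_idx], bounds[layer_idx + 1])
    tibble(
      cylinder_id = cl,
      clone_id = c(rep(cl, n_lab), rep(NA_integer_, n_bg)),
      lineage_id = c(lineage, rep(NA_integer_, n_bg)),
      layer = layers[layer_idx],
      x_um = rho * cos(theta),
      y_um = rho * sin(theta),
      depth_um = depth,
      tdtomato = c(rep(TRUE, n_lab), rep(FALSE, n_bg))
    )
  }

  rc <- sample.int(5, config$n_clones, replace = TRUE)
  cells <- map(seq_len(config$n_clones), one_clone) |> bind_rows()
  cells |>
    mutate(cell_id = sprintf("cell_%05d", row_number()),
           rostrocaudal = rc[.data$cylinder_id]) |>
    select("cell_id", "cylinder_id", "clone_id", "lineage_id", "layer",
           "x_um", "y_um", "depth_um", "tdtomato", "rostrocaudal")
}

pair_distances <- function(cells, i, j) {
  dx <- cells$x_um[i] - cells$x_um[j]
  dy <- cells$y_um[i] - cells$y_um[j]
  dz <- cells$depth_um[i] - cells$depth_um[j]
  tibble(tangential_um = sqrt(dx^2 + dy^2),
         vertical_um = abs(dz),
         euclidean_um = sqrt(dx^2 + dy^2 + dz^2))
}

#' Simulate pair-test tables
#'
#' Draws, for every row of `config$conn_probs`, `n_pairs_per_type` tested
#' cell pairs from the clone population (within one cylinder, matching the
#' row's relation and layers) and tests each direction as an independent
#' Bernoulli trial at the configured probability. A configurable fraction of
#' pairs is tested in both directions. Relations: `"related"` (both labeled,
#' same clone), `"unrelated"` (exactly one labeled),
#' `"control_any_unlabeled"` (at least one unlabeled).
#'
#' @param cells a cell table from [simulate_clone_population()].
#' @param config the [sim_config()] used to generate it.
#' @param seed optional integer overriding the config's pair-test substream.
#' @return a pair table (one row per tested directed connection): `pair_id`,
#'   `pre_layer`, `post_layer`, `relation`, `connected`,
#'   `bidirectional_tested`, `tangential_um`, `vertical_um`, `euclidean_um`,
#'   `rostrocaudal`, `clone_id`.
#' @export
simulate_pair_tests <- function(cells, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) substream_seed(config$seed, "pairs") else seed)

  idx_all <- seq_len(nrow(cells))
  # partner lookup tables: indices by (cylinder, layer, label) and
  # (clone, layer) for labeled cells
  key_cyl <- paste(cells$cylinder_id, cells$layer, cells$tdtomato)
  by_cyl <- split(idx_all, key_cyl)
  lab <- which(cells$tdtomato)
  key_clone <- paste(cells$clone_id[lab], cells$layer[lab])
  by_clone <- split(lab, key_clone)

  pick_one <- function(cand, excl) {
    cand <- cand[cand != excl]
    if (length(cand) == 0) return(NA_integer_)
    if (length(cand) == 1) cand else sample(cand, 1)
  }

  rows <- pmap(config$conn_probs, function(relation, pre_layer, post_layer, prob) {
    n_pairs <- config$n_pairs_per_type
    if (!relation %in% c("related", "unrelated", "control_any_unlabeled")) {
      abort(sprintf("Unknown relation `%s` in conn_probs.", relation))
    }
    cand_pre <- if (relation == "control_any_unlabeled") {
      which(!cells$tdtomato & cells$layer == pre_layer)
    } else {
      which(cells$tdtomato & cells$layer == pre_layer)
    }
    # keep only pre cells that have at least one eligible partner
    n_partners <- vapply(cand_pre, function(i) {
      cand <- switch(relation,
        related = by_clone[[paste(cells$clone_id[i], post_layer)]],
        unrelated = by_cyl[[paste(cells$cylinder_id[i], post_layer, FALSE)]],
        control_any_unlabeled =
          by_cyl[[paste(cells$cylinder_id[i], post_layer, FALSE)]]
      )
      length(setdiff(cand, i))
    }, integer(1))
    cand_pre <- cand_pre[n_partners > 0]
    if (length(cand_pre) == 0) {
      abort(sprintf("No eligible pre cells for %s %s->%s.",
                    relation, pre_layer, post_layer))
    }
    pre <- sample(cand_pre, n_pairs, replace = TRUE)
    post <- vapply(pre, function(i) {
      cand <- switch(relation,
        related = by_clone[[paste(cells$clone_id[i], post_layer)]],
        unrelated = by_cyl[[paste(cells$cylinder_id[i], post_layer, FALSE)]],
        control_any_unlabeled =
          by_cyl[[paste(cells$cylinder_id[i], post_layer, FALSE)]]
      )
      if (is.null(cand)) NA_integer_ else pick_one(cand, i)
    }, integer(1))
    if (anyNA(post)) {
      abort(sprintf("No eligible post cells for %s %s->%s.",
                    relation, pre_layer, post_layer))
    }
    bidir <- runif(n_pairs) < config$bidir_fraction
    d <- pair_distances(cells, pre, post)
    fwd <- tibble(
      pre_layer = pre_layer, post_layer = post_layer, relation = relation,
      connected = runif(n_pairs) < prob,
      bidirectional_tested = bidir
    ) |> dplyr::bind_cols(d) |>
      mutate(rostrocaudal = cells$rostrocaudal[pre],
             clone_id = dplyr::coalesce(cells$clone_id[pre], cells$clone_id[post]),
             pair_key = paste(relation, pre_layer, post_layer, seq_len(n_pairs)))
    rev <- fwd[bidir, ] |>
      mutate(pre_layer = post_layer, post_layer = fwd$pre_layer[bidir],
             connected = runif(sum(bidir)) < prob)
    bind_rows(fwd, rev)
  })
  out <- bind_rows(rows) |>
    mutate(pair_id = as.integer(factor(.data$pair_key,
                                       levels = unique(.data$pair_key)))) |>
    select("pair_id", "pre_layer", "post_layer", "relation", "connected",
           "bidirectional_tested", "tangential_um", "vertical_um",
           "euclidean_um", "rostrocaudal", "clone_id")
  out
}
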