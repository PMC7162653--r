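# Shared fixtures, built in code.

# minimal pair table with explicit geometry; distances in micrometres
make_pair_table <- function(n, relation, p, pre_layer = "L4",
                            post_layer = "L5", tangential = 50, vertical = 120,
                            rostrocaudal = 1L, connected = NULL) {
  tibble::tibble(
    pair_id = seq_len(n),
    pre_layer = pre_layer,
    post_layer = post_layer,
    relation = relation,
    connected = if (is.null(connected)) stats::runif(n) < p else connected,
    bidirectional_tested = FALSE,
    tangential_um = tangential,
    vertical_um = vertical,
    euclidean_um = sqrt(tangential^2 + vertical^2),
    rostrocaudal = rostrocaudal,
    clone_id = 1L
  )
}

# small simulation config with a thin background (a few hundred unlabeled
# cells per cylinder), for fast generator unit tests
fast_config <- function(...) {
  args <- list(...)
  defaults <- list(neurons_per_mm2 = 2e4, n_clones = 2, n_pairs_per_type = 20,
                   seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# reference with controllable dropout structure: each gene has `n_high`
# cells at a high count and zeros elsewhere, so mu and tau are explicit
dropout_reference <- function(n_genes = 500, n_cells = 200, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n_genes, n_cells,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%04d", seq_len(n_cells))))
  for (g in seq_len(n_genes)) {
    n_high <- sample(10:150, 1)
    vals <- 33L + stats::rpois(n_high, sample(5:200, 1))
    m[g, sample(n_cells, n_high)] <- vals
  }
  m
}

# independent two-sided Fisher oracle: enumerate all tables at fixed margins
# and sum point probabilities <= that of the observed table
fisher_enumeration <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  obs <- stats::dhyper(k1, n1, n2, m)
  ks <- max(0, m - n2):min(n1, m)
  probs <- stats::dhyper(ks, n1, n2, m)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# independent Clopper-Pearson oracle: invert the binomial tails on a fine
# p-grid
cp_grid_inversion <- function(k, n, alpha = 0.05, step = 1e-5) {
  grid <- seq(step, 1 - step, by = step)
  upper_tail <- stats::pbinom(k - 1, n, grid, lower.tail = FALSE)  # P(X >= k)
  lower_tail <- stats::pbinom(k, n, grid)                          # P(X <= k)
  lo <- if (k == 0) 0 else min(grid[upper_tail >= alpha / 2])
  hi <- if (k == n) 1 else max(grid[lower_tail >= alpha / 2])
  c(lo, hi)
}
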