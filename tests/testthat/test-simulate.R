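# Clone-population and pair-test generators.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(layer_fractions = c("L2/3" = 0.5, "L4" = 0.4)),
               "sum to 1")
  expect_error(sim_config(clone_size = 1, n_lineages = 2), ">=")
  expect_error(sim_config(conn_probs = tibble::tibble(
    relation = "related", pre_layer = "L4", post_layer = "L5", prob = NA_real_
  )), "missing probability")
  expect_error(sim_config(conn_probs = tibble::tibble(
    relation = "related", pre_layer = "L4", post_layer = "L5", prob = 1.2
  )), "probability")
})

test_that("clone population respects lineage and layer structure", {
  cfg1 <- fast_config(n_lineages = 1)
  cells1 <- simulate_clone_population(cfg1)
  expect_true(all(cells1$lineage_id[cells1$tdtomato] == 1))

  # degenerate fractions put every cell in one layer
  cfg_l23 <- fast_config(layer_fractions = c("L2/3" = 1.0))
  expect_true(all(simulate_clone_population(cfg_l23)$layer == "L2/3"))

  # labeled cells: clone_size per clone, each in exactly one clone/lineage
  cfg <- fast_config(n_clones = 4)
  cells <- simulate_clone_population(cfg)
  lab <- cells[cells$tdtomato, ]
  expect_equal(unname(table(lab$clone_id)), rep(60L, 4L),
               ignore_attr = TRUE)
  expect_false(anyNA(lab$lineage_id))
  # positions inside the cylinder disc
  expect_true(all(sqrt(cells$x_um^2 + cells$y_um^2) <= 87 + 1e-9))
  # background cells fill the cylinder to the configured density
  full <- sim_config(n_clones = 1, seed = 2)
  n_exp <- round(pi * 0.087^2 * 1e5 * 0.8)
  expect_equal(nrow(simulate_clone_population(full)), n_exp)
})

test_that("lineage splitting is multinomial over lineages", {
  cfg <- fast_config(n_clones = 1000, n_lineages = 2, seed = 77,
                     neurons_per_mm2 = 1)  # no background: labeled cells only
  cells <- simulate_clone_population(cfg)
  lab <- cells[cells$tdtomato, ]
  per_lineage <- tapply(lab$cell_id, list(lab$clone_id, lab$lineage_id), length)
  per_lineage[is.na(per_lineage)] <- 0
  mean1 <- mean(per_lineage[, 1])
  se <- sqrt(60 * 0.25) / sqrt(1000)  # binomial(60, 1/2) clone-wise
  expect_lt(abs(mean1 - 30), 3 * se)
})

test_that("pair tests draw Bernoulli at the configured probabilities", {
  # zero probability everywhere: no connections
  cfg0 <- fast_config(conn_probs = tibble::tibble(
    relation = c("related", "unrelated"), pre_layer = "L4",
    post_layer = "L5", prob = 0
  ), n_pairs_per_type = 50)
  pairs0 <- simulate_pair_tests(simulate_clone_population(cfg0), cfg0)
  expect_equal(sum(pairs0$connected), 0)

  # empirical frequency within the 99% binomial interval at large n
  p <- 7 / 62
  cfg <- fast_config(conn_probs = tibble::tibble(
    relation = "related", pre_layer = "L4", post_layer = "L5", prob = p
  ), n_pairs_per_type = 20000, bidir_fraction = 0, seed = 13)
  pairs <- simulate_pair_tests(simulate_clone_population(cfg), cfg)
  expect_equal(nrow(pairs), 20000)
  band <- qnorm(0.995) * sqrt(p * (1 - p) / 20000)
  expect_lt(abs(mean(pairs$connected) - p), band)
})

test_that("directions are independent so bidirectional rate is near p^2", {
  p <- 0.3
  cfg <- fast_config(conn_probs = tibble::tibble(
    relation = "related", pre_layer = "L4", post_layer = "L4", prob = p
  ), n_pairs_per_type = 5000, bidir_fraction = 1, seed = 23)
  pairs <- simulate_pair_tests(simulate_clone_population(cfg), cfg)
  expect_true(all(pairs$bidirectional_tested))
  both <- tapply(pairs$connected, pairs$pair_id, sum) == 2
  band <- qnorm(0.995) * sqrt(p^2 * (1 - p^2) / 5000)
  expect_lt(abs(mean(both) - p^2), band)
})

test_that("pair relations reflect clone and label membership", {
  cfg <- sim_config(n_clones = 2, n_pairs_per_type = 30, seed = 3,
                    conn_probs = tibble::tibble(
                      relation = c("related", "unrelated",
                                   "control_any_unlabeled"),
                      pre_layer = "L2/3", post_layer = "L5", prob = 0.1))
  cells <- simulate_clone_population(cfg)
  pairs <- simulate_pair_tests(cells, cfg)
  expect_equal(sort(unique(pairs$relation)),
               c("control_any_unlabeled", "related", "unrelated"))
  expect_false(anyNA(pairs$clone_id[pairs$relation == "related"]))
  # distances satisfy the Pythagorean relation between projections
  expect_equal(pairs$euclidean_um,
               sqrt(pairs$tangential_um^2 + pairs$vertical_um^2))
})

test_that("fixed seed reproduces identical outputs", {
  cfg <- fast_config(seed = 99)
  a_cells <- simulate_clone_population(cfg)
  b_cells <- simulate_clone_population(cfg)
  expect_identical(a_cells, b_cells)
  expect_identical(simulate_pair_tests(a_cells, cfg),
                   simulate_pair_tests(b_cells, cfg))
  # substreams differ between operations but are deterministic
  expect_false(clonecircuits:::substream_seed(99, "clones") ==
                 clonecircuits:::substream_seed(99, "pairs"))
})

test_that("pair tables round-trip through the TSV writer and reader", {
  cfg <- fast_config(seed = 7, n_pairs_per_type = 10)
  pairs <- simulate_pair_tests(simulate_clone_population(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(pairs, path)
  back <- read_pair_table(path)
  expect_equal(as.data.frame(back), as.data.frame(pairs), tolerance = 1e-12)
})
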