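# Connection probability, exact intervals and group comparisons.

test_that("Clopper-Pearson interval matches closed forms and grid inversion", {
  # zero successes: lower bound 0, upper bound 1 - (alpha/2)^(1/n)
  ci <- clopper_pearson(0, 20)
  expect_equal(ci$ci_low, 0)
  expect_equal(ci$ci_high, 1 - 0.025^(1 / 20))
  # all successes: upper bound 1
  expect_equal(clopper_pearson(20, 20)$ci_high, 1)
  # brute-force inversion of the binomial tails on a fine p-grid
  oracle <- cp_grid_inversion(7, 62)
  ci7 <- clopper_pearson(7, 62)
  expect_equal(ci7$ci_low, oracle[1], tolerance = 1e-4)
  expect_equal(ci7$ci_high, oracle[2], tolerance = 1e-4)
  expect_error(clopper_pearson(5, 3), "exceed")
})

test_that("Clopper-Pearson empirical coverage is at least nominal", {
  set.seed(9)
  n <- 100
  for (p in c(0.01, 0.05, 0.1)) {
    k <- rbinom(10000, n, p)
    lo <- ifelse(k == 0, 0, qbeta(0.025, k, n - k + 1))
    hi <- ifelse(k == n, 1, qbeta(0.975, k + 1, n - k))
    expect_gte(mean(lo <= p & p <= hi), 0.95)
  }
})

test_that("connection probability is an exact ratio with valid intervals", {
  pairs <- make_pair_table(464, "related", p = NA,
                           connected = c(rep(TRUE, 28), rep(FALSE, 436)))
  est <- connection_probability(pairs)
  expect_equal(est$k, 28)
  expect_equal(est$p_hat, 28 / 464)
  expect_equal(round(est$p_hat, 4), 0.0603)

  none <- make_pair_table(98, "related", p = NA, connected = rep(FALSE, 98))
  est0 <- connection_probability(none)
  expect_equal(est0$p_hat, 0)
  expect_equal(est0$ci_low, 0)

  all_conn <- make_pair_table(10, "related", p = NA, connected = rep(TRUE, 10))
  est1 <- connection_probability(all_conn)
  expect_equal(est1$p_hat, 1)
  expect_equal(est1$ci_high, 1)

  expect_error(connection_probability(pairs, relation == "unrelated"),
               "no tested pairs")
})

test_that("connection probability is invariant to row order and pooling", {
  set.seed(2)
  pairs <- make_pair_table(200, "related", p = 0.1)
  shuffled <- pairs[sample.int(nrow(pairs)), ]
  expect_equal(connection_probability(pairs)[, c("k", "n", "p_hat")],
               connection_probability(shuffled)[, c("k", "n", "p_hat")])
  # split then pool
  halves <- list(pairs[1:100, ], pairs[101:200, ])
  pooled_k <- sum(sapply(halves, function(h) connection_probability(h)$k))
  expect_equal(pooled_k, connection_probability(pairs)$k)
})

test_that("a pair is vertical iff its layers differ", {
  pairs <- dplyr::bind_rows(
    make_pair_table(5, "related", 0.1, pre_layer = "L4", post_layer = "L5"),
    make_pair_table(5, "related", 0.1, pre_layer = "L4", post_layer = "L4")
  )
  cls <- classify_connections(pairs)
  expect_equal(cls$class, ifelse(cls$pre_layer != cls$post_layer,
                                 "vertical", "lateral"))
})

test_that("Fisher exact test matches enumeration, symmetry and the printed p", {
  # reported vertical comparison
  expect_equal(fisher_exact(28, 464, 19, 711)$p_value, 0.0056,
               tolerance = 2e-2)
  # enumeration oracle on all 2x2 tables with n1 = n2 = 5 (the all-zero
  # success margin is exercised separately below)
  for (k1 in 0:5) {
    for (k2 in 0:5) {
      if (k1 + k2 == 0 || k1 + k2 == 10) next  # degenerate margins warn
      expect_equal(fisher_exact(k1, 5, k2, 5)$p_value,
                   fisher_enumeration(k1, 5, k2, 5),
                   tolerance = 1e-9)
    }
  }
  # symmetry under swapping groups
  expect_equal(fisher_exact(7, 62, 2, 89)$p_value,
               fisher_exact(2, 89, 7, 62)$p_value)
  # identical tiny tables (all-zero success margin also warns)
  expect_warning(tiny <- fisher_exact(0, 1, 0, 1), "margin")
  expect_equal(tiny$p_value, 1)
  expect_warning(out <- fisher_exact(0, 10, 0, 20), "margin")
  expect_equal(out$p_value, 1)
})

test_that("chi-squared statistic equals direct arithmetic", {
  tab <- matrix(c(10, 20, 20, 10), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  by_hand <- sum((tab - expected)^2 / expected)
  res <- chi_squared_test(tab)
  expect_equal(res$statistic, by_hand)
  expect_equal(res$df, 1)
  # a table equal to its own expectation has statistic 0, p = 1
  flat <- matrix(c(10, 10, 10, 10), nrow = 2)
  res0 <- chi_squared_test(flat)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # Bonferroni multiplies and caps at 1
  expect_equal(chi_squared_test(tab, bonferroni_m = 13)$p_adjusted,
               min(res$p_value * 13, 1))
  expect_equal(chi_squared_test(flat, bonferroni_m = 13)$p_adjusted, 1)
  expect_error(chi_squared_test(matrix(c(0, 0, 1, 2), nrow = 2)), "margin")
})

test_that("single-stratum analysis equals the unstratified result", {
  set.seed(5)
  pairs <- dplyr::bind_rows(
    make_pair_table(100, "related", 0.1, rostrocaudal = 2L),
    make_pair_table(100, "unrelated", 0.05, rostrocaudal = 2L)
  )
  strat <- stratify_by_rostrocaudal(pairs, split_rule = 3, by_class = FALSE)
  expect_equal(unique(strat$stratum), "rostral")
  flat <- connection_probability(pairs, by = "relation")
  expect_equal(strat$p_hat[order(strat$relation)],
               flat$p_hat[order(flat$relation)])
  expect_equal(unique(strat$fisher_p),
               fisher_exact(flat$k[flat$relation == "related"], 100,
                            flat$k[flat$relation == "unrelated"], 100)$p_value)
})

test_that("stratified comparison is calibrated under equal rates", {
  # equal probabilities in both strata: the per-stratum related-vs-unrelated
  # test rejects at most at its nominal level (plus Monte-Carlo error)
  set.seed(31)
  reps <- 30
  p_values <- numeric(0)
  for (r in seq_len(reps)) {
    pairs <- dplyr::bind_rows(
      make_pair_table(1250, "related", 0.05, rostrocaudal = 1L),
      make_pair_table(1250, "unrelated", 0.05, rostrocaudal = 1L),
      make_pair_table(1250, "related", 0.05, rostrocaudal = 5L),
      make_pair_table(1250, "unrelated", 0.05, rostrocaudal = 5L)
    )
    strat <- stratify_by_rostrocaudal(pairs, by_class = FALSE)
    p_values <- c(p_values, unique(strat$fisher_p[strat$stratum == "rostral"]),
                  unique(strat$fisher_p[strat$stratum == "caudal"]))
  }
  rate <- mean(p_values < 0.05)
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / length(p_values))
  expect_lte(rate, bound)
})

test_that("stratified comparison detects a twofold probability ratio", {
  set.seed(32)
  detected <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    pairs <- dplyr::bind_rows(
      make_pair_table(2500, "related", 0.06, rostrocaudal = 1L),
      make_pair_table(2500, "unrelated", 0.03, rostrocaudal = 1L),
      make_pair_table(2500, "related", 0.06, rostrocaudal = 5L),
      make_pair_table(2500, "unrelated", 0.03, rostrocaudal = 5L)
    )
    strat <- stratify_by_rostrocaudal(pairs, by_class = FALSE)
    if (all(strat$fisher_p < 0.05)) detected <- detected + 1
  }
  expect_gte(detected, 0.9 * reps)
})
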