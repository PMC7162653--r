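# Variable-gene selection, kNN embedding placement, precision bootstrap,
# nearest-centroid assignment and same-type pair statistics.

test_that("low-prevalence genes are excluded before variable-gene selection", {
  m <- dropout_reference(n_genes = 50, seed = 2)
  m["g0001", ] <- 0L
  m["g0001", 1:5] <- 100L  # counts >= 32 in only 5 cells
  sel <- suppressWarnings(
    select_variable_genes(m, min_cells = 10, n_target = 40))
  expect_false("g0001" %in% sel)
  expect_false("g0001" %in% attr(sel, "stats")$gene)
})

test_that("binary search recovers a set constructed to sit above the curve at b = 0", {
  # 300 genes with high dropout (tau = 0.5) sit above the curve at b = 0;
  # 200 genes with tau below the margin floor can never be selected
  n_cells <- 200
  m <- matrix(0L, 500, n_cells,
              dimnames = list(sprintf("g%04d", 1:500),
                              sprintf("c%04d", seq_len(n_cells))))
  for (g in 1:300) m[g, 1:100] <- 64L          # mu = 6, tau = 0.5
  for (g in 301:500) m[g, 1:199] <- 64L        # mu = 6, tau = 1/200
  sel <- select_variable_genes(m, n_target = 300)
  expect_setequal(sel, sprintf("g%04d", 1:300))
  expect_equal(sum(attr(sel, "stats")$tau >
                     exp(-1.5 * 6 + attr(sel, "b")) + 0.02), 300)
})

test_that("selection hits the target size in general position and shrinks with b", {
  m <- dropout_reference(seed = 3)
  sel <- select_variable_genes(m, n_target = 100)
  expect_lte(abs(length(sel) - 100), 1)
  stats <- attr(sel, "stats")
  b <- attr(sel, "b")
  # raising b weakly shrinks the selected set
  n_at <- function(bb) sum(stats$tau > exp(-1.5 * stats$mu + bb) + 0.02)
  bs <- seq(b - 2, b + 2, by = 0.25)
  expect_true(all(diff(sapply(bs, n_at)) <= 0))
  # fewer candidates than the target: return all with a warning
  small <- dropout_reference(n_genes = 20, seed = 4)
  expect_warning(all_sel <- select_variable_genes(small, n_target = 3000),
                 "returning all")
  expect_equal(length(all_sel), nrow(attr(all_sel, "stats")))
})

test_that("counts equal to the threshold enter neither mu nor tau", {
  m <- matrix(0L, 2, 20, dimnames = list(c("gA", "gB"), paste0("c", 1:20)))
  m["gA", 1:12] <- 32L   # exactly at threshold: not high, not low
  m["gA", 13:16] <- 64L
  m["gB", 1:15] <- 64L
  sel <- suppressWarnings(select_variable_genes(m, min_cells = 4, n_target = 1))
  stats <- attr(sel, "stats")
  a <- stats[stats$gene == "gA", ]
  expect_equal(a$mu, 6)            # mean log2 over counts > 32 only
  expect_equal(a$tau, 4 / 20)      # fraction of counts < 32 (zeros only)
})

test_that("kNN mapping reproduces exact matches and respects separability", {
  cfg <- fast_config(n_clones = 4, seed = 61, expression = list(n_clusters = 3))
  sim <- simulate_expression(simulate_clone_population(cfg), cfg)
  ref_log <- log2(sim$atlas$counts + 1)
  emb <- sim$atlas$embedding

  # a query identical to a reference cell lands exactly on it at k = 1
  q <- ref_log[, 1:3, drop = FALSE]
  colnames(q) <- paste0("q", 1:3)
  pos <- map_cells_knn(q, ref_log, emb, k = 1)
  expect_equal(pos$dim1, emb$dim1[1:3])
  expect_equal(pos$dim2, emb$dim2[1:3])

  # well-separated clusters: queries land nearer their own centroid
  q_log <- log2(sim$bundle$counts + 1)
  pos_q <- map_cells_knn(q_log, ref_log, emb)
  cents <- sim$atlas$centroid_positions
  truth <- sim$bundle$metadata$true_cluster
  d_to <- function(cl) {
    sqrt((pos_q$dim1 - cents$dim1[match(cl, cents$cluster)])^2 +
           (pos_q$dim2 - cents$dim2[match(cl, cents$cluster)])^2)
  }
  d_own <- d_to(truth)
  d_other <- do.call(pmin, lapply(setdiff(cents$cluster, NA), function(cl) {
    d <- d_to(rep(cl, nrow(pos_q)))
    d[truth == cl] <- Inf
    d
  }))
  expect_gte(mean(d_own < d_other), 0.99)

  # Pearson correlation is invariant to per-cell affine scaling
  pos_scaled <- map_cells_knn(2 * q + 5, ref_log, emb, k = 1)
  expect_equal(pos_scaled$dim1, pos$dim1)

  # zero-variance queries are flagged, not dropped silently
  q_flat <- q; q_flat[, 1] <- 1
  expect_warning(pos_f <- map_cells_knn(q_flat, ref_log, emb), "zero variance")
  expect_true(pos_f$flagged[1])
  expect_true(is.na(pos_f$dim1[1]))
})

test_that("mapping precision is zero for a degenerate atlas and reproducible", {
  cfg <- fast_config(n_clones = 2, seed = 62, expression = list(n_clusters = 2))
  sim <- simulate_expression(simulate_clone_population(cfg), cfg)
  ref_log <- log2(sim$atlas$counts + 1)
  q_log <- log2(sim$bundle$counts[, 1:5] + 1)

  # all reference cells at one embedding point: displacement is always 0
  emb0 <- sim$atlas$embedding
  emb0$dim1 <- 3; emb0$dim2 <- -2
  prec0 <- mapping_precision_bootstrap(q_log, ref_log, emb0, reps = 10,
                                       seed = 1)
  expect_equal(prec0$precision, rep(0, 5))
  expect_equal(unique(prec0$size_class), "large")

  # fixed seed reproduces the distribution
  emb <- sim$atlas$embedding
  p1 <- mapping_precision_bootstrap(q_log, ref_log, emb, reps = 20, seed = 3)
  p2 <- mapping_precision_bootstrap(q_log, ref_log, emb, reps = 20, seed = 3)
  expect_identical(p1, p2)
  expect_error(mapping_precision_bootstrap(q_log, ref_log, emb, reps = 0),
               "reps")
})

test_that("ambiguous queries between two distant clusters map imprecisely", {
  # two clusters with disjoint markers; the query carries both marker sets,
  # so gene bootstraps flip it between the two centroids
  set.seed(64)
  n_ref <- 40
  genes <- sprintf("g%03d", 1:60)
  ref <- matrix(rpois(60 * n_ref, 0.2), 60, n_ref,
                dimnames = list(genes, sprintf("r%03d", 1:n_ref)))
  ref[1:20, 1:20] <- rpois(20 * 20, 30)    # cluster A markers
  ref[21:40, 21:40] <- rpois(20 * 20, 30)  # cluster B markers
  emb <- tibble::tibble(cell_id = colnames(ref),
                        dim1 = rep(c(-50, 50), each = 20), dim2 = 0)
  q <- matrix(rpois(60, 0.2), 60, 1, dimnames = list(genes, "q1"))
  q[1:40, 1] <- rpois(40, 30)              # both marker sets
  prec <- mapping_precision_bootstrap(log2(q + 1), log2(ref + 1), emb,
                                      reps = 60, seed = 5)
  expect_gt(prec$precision, 100 / 4)  # > cluster separation / 4
})

test_that("nearest-centroid assignment recovers held-out reference cells", {
  cfg <- fast_config(n_clones = 4, seed = 63,
                     expression = list(n_clusters = 5, n_ref_per_cluster = 40,
                                       n_markers_per_cluster = 10))
  sim <- simulate_expression(simulate_clone_population(cfg), cfg)
  ref_log <- log2(sim$atlas$counts + 1)
  clusters <- sim$atlas$clusters
  held_out <- unlist(lapply(split(seq_along(clusters), clusters),
                            function(i) i[1:8]))
  cent <- cluster_centroids(ref_log[, -held_out], clusters[-held_out])
  assigned <- assign_to_clusters(ref_log[, held_out], cent)
  expect_gte(mean(assigned$cluster == clusters[held_out]), 0.95)

  # a query equal to a centroid maps to it with correlation 1
  q_cent <- t(cent)[, 2, drop = FALSE]
  colnames(q_cent) <- "qc"
  hit <- assign_to_clusters(q_cent, cent)
  expect_equal(hit$cluster, rownames(cent)[2])
  expect_equal(hit$best_cor, 1)

  # ties resolve to the first cluster in sorted order and are reported
  cent_tie <- cent[c(1, 1), ]
  rownames(cent_tie) <- c("z_dup", "a_dup")
  tie <- assign_to_clusters(q_cent, cent_tie)
  expect_equal(tie$cluster, "a_dup")
  expect_true(tie$tie)

  # broad-class labels come from the supplied map
  cmap <- tibble::tibble(cluster = rownames(cent),
                         class = rep(c("IT", "PT"), length.out = nrow(cent)))
  with_class <- assign_to_clusters(q_cent, cent, class_map = cmap)
  expect_equal(with_class$class,
               cmap$class[match(with_class$cluster, cmap$cluster)])
})

test_that("same-type pair probability counts pairs correctly", {
  types <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:20),
    type = rep(c("A", "B"), each = 10),
    layer = rep(c("L2/3", "L5"), 10)
  )
  # all cells one label: fraction 1 in every group
  one <- types; one$type <- "A"
  pairs <- tibble::tibble(
    cell1 = sprintf("c%02d", 1:10), cell2 = sprintf("c%02d", 11:20),
    group = rep(c("related", "unrelated"), 5)
  )
  res1 <- same_type_pair_probability(pairs, one)
  expect_equal(res1$fraction, c(1, 1))
  expect_equal(res1$ci_high, c(1, 1))

  # duplicated pairs collapse under the dedupe flag
  dup <- dplyr::bind_rows(pairs, pairs[1, ])
  res_dup <- same_type_pair_probability(dup, one, dedupe = TRUE)
  expect_equal(res_dup$n, res1$n)

  # layer conditioning keeps only same-layer pairs
  res_layer <- same_type_pair_probability(pairs, types,
                                          condition_on_layer = TRUE)
  expect_equal(sum(res_layer$n), 10)  # c1-c11 share parity, hence layer

  expect_error(same_type_pair_probability(pairs[, 1:2], one), "group")
})

test_that("uniform labels over K types give same-type fraction near 1/K", {
  set.seed(65)
  k <- 5
  n_pairs <- 10000
  types <- tibble::tibble(cell_id = sprintf("c%05d", 1:2000),
                          type = sample(LETTERS[1:k], 2000, replace = TRUE))
  pairs <- tibble::tibble(
    cell1 = sample(types$cell_id, n_pairs, replace = TRUE),
    cell2 = sample(types$cell_id, n_pairs, replace = TRUE),
    group = "related"
  )
  pairs <- pairs[pairs$cell1 != pairs$cell2, ]
  res <- same_type_pair_probability(pairs, types)
  band <- 4 * sqrt((1 / k) * (1 - 1 / k) / nrow(pairs))
  expect_lt(abs(res$fraction - 1 / k), band)
})
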