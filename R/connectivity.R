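# Connection probability estimation and comparison for pair-test tables.
#
# A pair table has one row per tested directed connection; see
# read_pair_table() for the schema. Connection probability is the number of
# connections divided by the number tested, with exact (Clopper-Pearson)
# binomial intervals, compared across groups by Fisher's exact test.

pair_table_columns <- function() {
  c("pre_layer", "post_layer", "relation", "connected")
}

validate_pair_table <- function(pairs, need = pair_table_columns()) {
  missing <- setdiff(need, names(pairs))
  if (length(missing) > 0) {
    abort(sprintf("Pair table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(pairs)
}

#' Classify tested pairs as vertical or lateral
#'
#' A tested connection is vertical (translaminar) iff the pre- and
#' post-synaptic layers differ, and lateral (within-layer) otherwise.
#'
#' @param pairs a pair table.
#' @return the table with a `class` column (`"vertical"`/`"lateral"`).
#' @export
classify_connections <- function(pairs) {
  validate_pair_table(pairs)
  mutate(as_tibble(pairs),
         class = ifelse(.data$pre_layer != .data$post_layer,
                        "vertical", "lateral"))
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile form of the exact interval: lower bound
#' `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`), upper bound
#' `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`).
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials.
#' @param alpha two-sided error level (default 0.05 for a 95% interval).
#' @return a tibble with columns `ci_low`, `ci_high`.
#' @examples
#' clopper_pearson(7, 62)
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  check_count(k, "k"); check_count(n, "n", min = 1)
  if (any(k > n)) abort("`k` cannot exceed `n`.")
  if (any(alpha <= 0) || any(alpha >= 1)) abort("`alpha` must be in (0, 1).")
  lo <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble(ci_low = lo, ci_high = hi)
}

#' Connection probability with exact confidence interval
#'
#' Filters the pair table with tidy expressions, optionally groups it, and
#' returns connections / tested with 95% Clopper-Pearson bounds.
#'
#' @param pairs a pair table (one row per tested directed connection).
#' @param ... optional filter expressions evaluated in the table, e.g.
#'   `relation == "related"`, `pre_layer != post_layer`.
#' @param by optional character vector of grouping columns, e.g.
#'   `c("relation")` or `c("relation", "pre_layer", "post_layer")`.
#' @param alpha interval error level (default 0.05).
#' @return a tibble with columns `k`, `n`, `p_hat`, `ci_low`, `ci_high`
#'   (one row per group; a single row when `by` is NULL). Errors if the
#'   filter selects no rows.
#' @examples
#' pairs <- simulate_pair_tests(simulate_clone_population(sim_config(seed = 1)),
#'                              sim_config(seed = 1))
#' connection_probability(pairs, relation == "related", by = "class")
#' @export
connection_probability <- function(pairs, ..., by = NULL, alpha = 0.05) {
  validate_pair_table(pairs)
  dat <- classify_connections(pairs)
  dots <- enquos(...)
  if (length(dots) > 0) dat <- filter(dat, !!!dots)
  if (nrow(dat) == 0) {
    abort("The filter selected no tested pairs; connection probability is undefined.")
  }
  if (!is.null(by)) dat <- group_by(dat, across(dplyr::all_of(by)))
  out <- summarise(dat,
                   k = sum(.data$connected),
                   n = dplyr::n(),
                   .groups = "drop")
  bind_cols_ci <- clopper_pearson(out$k, out$n, alpha)
  out <- mutate(out, p_hat = .data$k / .data$n)
  out <- dplyr::bind_cols(out, bind_cols_ci)
  class(out) <- c("cp_table", class(out))
  out
}

#' Fisher's exact test for two connection probabilities
#'
#' Two-sided exact test on the 2x2 table of connected/unconnected counts,
#' using the minimum-likelihood convention (tables with point probability at
#' most that of the observed table contribute to p).
#'
#' @param k1,n1 connections and tested count in group 1.
#' @param k2,n2 connections and tested count in group 2.
#' @return a tibble with `p1`, `p2`, `odds_ratio` (conditional MLE), and the
#'   two-sided `p_value`. All-zero success and failure margins give p = 1
#'   with a warning.
#' @examples
#' fisher_exact(28, 464, 19, 711)  # p ~0.0056
#' @export
fisher_exact <- function(k1, n1, k2, n2) {
  check_count(k1, "k1"); check_count(n1, "n1", min = 1)
  check_count(k2, "k2"); check_count(n2, "n2", min = 1)
  if (k1 > n1 || k2 > n2) abort("Connected counts cannot exceed tested counts.")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) {
    warn("A margin of the 2x2 table is all zero; the test is uninformative (p = 1).")
    return(tibble(p1 = k1 / n1, p2 = k2 / n2, odds_ratio = NA_real_, p_value = 1))
  }
  ft <- fisher.test(tab)
  tibble(p1 = k1 / n1, p2 = k2 / n2,
         odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Pearson chi-squared test with optional Bonferroni factor
#'
#' Chi-squared test of independence on a contingency table (no continuity
#' correction), with an optional Bonferroni multiplier for post-hoc use.
#'
#' @param tab a counts matrix (r x c) with positive row and column margins.
#' @param bonferroni_m number of comparisons to correct for (default 1, no
#'   correction); the p-value is multiplied by `bonferroni_m` and capped at 1.
#' @return a tibble with `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
chi_squared_test <- function(tab, bonferroni_m = 1) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("Counts must be nonnegative.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Every row and column margin must be positive.")
  }
  check_count(bonferroni_m, "bonferroni_m", min = 1)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic),
         df = unname(ct$parameter),
         p_value = ct$p.value,
         p_adjusted = pmin(ct$p.value * bonferroni_m, 1))
}

#' Stratified connection-probability comparison by rostrocaudal position
#'
#' Sorts clones into rostral and caudal groups and re-runs the
#' related-vs-unrelated comparison (connection probability with exact
#' intervals, Fisher's exact test) within each stratum, optionally within
#' each connection class.
#'
#' @param pairs a pair table with a `rostrocaudal` column (integers 1-5,
#'   1 most rostral).
#' @param split_rule either an integer threshold `t` (positions `<= t` are
#'   "rostral"; default 3) or a function mapping the rostrocaudal vector to
#'   stratum labels.
#' @param by_class also stratify by vertical/lateral class (default TRUE).
#' @return a tibble with one row per (stratum, class, relation) carrying the
#'   connection probability estimate, plus per-(stratum, class) Fisher
#'   p-values in the `fisher_p` column. Empty strata are dropped with a
#'   warning.
#' @export
stratify_by_rostrocaudal <- function(pairs, split_rule = 3, by_class = TRUE) {
  validate_pair_table(pairs, c(pair_table_columns(), "rostrocaudal"))
  rc <- pairs$rostrocaudal
  if (any(!rc %in% 1:5)) abort("`rostrocaudal` must take integer values 1-5.")
  stratum <- if (is.function(split_rule)) {
    split_rule(rc)
  } else {
    ifelse(rc <= split_rule, "rostral", "caudal")
  }
  dat <- classify_connections(pairs) |> mutate(stratum = stratum)
  groups <- c("stratum", if (by_class) "class", "relation")
  est <- connection_probability(dat, .data$relation %in% c("related", "unrelated"),
                                by = groups)
  keys <- setdiff(groups, "relation")
  wide <- est |>
    select(dplyr::all_of(c(keys, "relation", "k", "n"))) |>
    tidyr::pivot_wider(names_from = "relation", values_from = c("k", "n"))
  if (anyNA(wide)) {
    warn("Strata without both relations present were skipped in the Fisher test.")
  }
  tests <- wide |>
    filter(complete.cases(wide)) |>
    mutate(fisher_p = pmap_dbl(
      list(.data$k_related, .data$n_related, .data$k_unrelated, .data$n_unrelated),
      function(k1, n1, k2, n2) fisher_exact(k1, n1, k2, n2)$p_value
    )) |>
    select(dplyr::all_of(keys), "fisher_p")
  left_join(est, tests, by = keys)
}
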