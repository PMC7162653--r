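# Distance-matched bootstrap controls and smoothed log-ratio heatmaps.

#' Distance-matched bootstrap comparison of related vs control connectivity
#'
#' Connection probability depends on the distance between cells, so related
#' pairs are compared against controls matched on geometry: for each related
#' pair, eligible controls share the pre- and post-synaptic layers and lie
#' within `tol_um` on both the tangential and the vertical distance
#' (inclusive). The control pool is every tested pair with at least one
#' unlabeled cell (relations `"unrelated"` and `"control_any_unlabeled"`).
#' Related pairs with no eligible control are dropped.
#'
#' Each bootstrap iteration resamples the matchable related pairs with
#' replacement and draws one matched control, uniformly at random among the
#' eligible controls, for every selected related pair. The p-value inverts
#' the bootstrap interval of the difference in connection probability: the
#' observed mean difference is subtracted from all bootstrap differences and
#' p is the fraction of shifted differences at least as large in absolute
#' value as the observed mean difference (two-tailed).
#'
#' @param pairs a pair table with `tangential_um` and `vertical_um` columns.
#' @param tol_um matching tolerance in micrometres on each axis (default 20).
#' @param reps number of bootstrap iterations (default 1000).
#' @param seed optional integer seed.
#' @return an object of class `matched_bootstrap`: a list with
#'   `related_cp` and `matched_cp` (bootstrap distributions of length
#'   `reps`), `mean_difference`, `p_value`, `n_related` (matchable related
#'   pairs), `n_dropped`, and 95% coverage intervals for both distributions.
#' @export
distance_matched_bootstrap <- function(pairs, tol_um = 20, reps = 1000,
                                       seed = NULL) {
  validate_pair_table(pairs, c(pair_table_columns(),
                               "tangential_um", "vertical_um"))
  check_count(reps, "reps", min = 1)
  if (!is.null(seed)) set.seed(seed)
  related <- filter(as_tibble(pairs), .data$relation == "related")
  controls <- filter(as_tibble(pairs),
                     .data$relation %in% c("unrelated", "control_any_unlabeled"))
  if (nrow(related) == 0) abort("No related pairs in the table.")
  if (nrow(controls) == 0) abort("No control pairs (>=1 unlabeled cell) in the table.")

  match_sets <- map(seq_len(nrow(related)), function(i) {
    which(controls$pre_layer == related$pre_layer[i] &
            controls$post_layer == related$post_layer[i] &
            abs(controls$tangential_um - related$tangential_um[i]) <= tol_um &
            abs(controls$vertical_um - related$vertical_um[i]) <= tol_um)
  })
  keep <- lengths(match_sets) > 0
  if (!any(keep)) abort("No related pair has a distance-matched control.")
  related <- related[keep, ]
  match_sets <- match_sets[keep]
  n_rel <- nrow(related)

  rel_cp <- numeric(reps)
  ctl_cp <- numeric(reps)
  for (b in seq_len(reps)) {
    idx <- sample.int(n_rel, n_rel, replace = TRUE)
    rel_cp[b] <- mean(related$connected[idx])
    ctl_idx <- vapply(match_sets[idx], function(s) {
      if (length(s) == 1) s else sample(s, 1)
    }, integer(1))
    ctl_cp[b] <- mean(controls$connected[ctl_idx])
  }
  diffs <- rel_cp - ctl_cp
  mean_diff <- mean(diffs)
  shifted <- diffs - mean_diff
  p_value <- mean(abs(shifted) >= abs(mean_diff))

  structure(
    list(
      related_cp = rel_cp,
      matched_cp = ctl_cp,
      mean_difference = mean_diff,
      p_value = p_value,
      n_related = n_rel,
      n_dropped = sum(!keep),
      related_ci = unname(quantile(rel_cp, c(0.025, 0.975))),
      matched_ci = unname(quantile(ctl_cp, c(0.025, 0.975))),
      reps = reps
    ),
    class = "matched_bootstrap"
  )
}

#' @export
print.matched_bootstrap <- function(x, ...) {
  cat("Distance-matched bootstrap comparison\n")
  cat(sprintf("  related pairs used: %d (dropped unmatchable: %d)\n",
              x$n_related, x$n_dropped))
  cat(sprintf("  related CP %.4f [%.4f, %.4f]; matched control CP %.4f [%.4f, %.4f]\n",
              mean(x$related_cp), x$related_ci[1], x$related_ci[2],
              mean(x$matched_cp), x$matched_ci[1], x$matched_ci[2]))
  cat(sprintf("  mean difference %.4f, inverted-bootstrap p = %.3f (%d reps)\n",
              x$mean_difference, x$p_value, x$reps))
  invisible(x)
}

#' @export
glance.matched_bootstrap <- function(x, ...) {
  tibble(related_cp = mean(x$related_cp), matched_cp = mean(x$matched_cp),
         mean_difference = x$mean_difference, p_value = x$p_value,
         n_related = x$n_related, reps = x$reps)
}

#' Laplace-smoothed log2 ratio of two proportions
#'
#' `log2( ((A+1)/(B+1)) / ((C+1)/(D+1)) )` for A of B related and C of D
#' unrelated connections; the +1 smoothing removes zero divisions.
#'
#' @param a,b connected and tested counts, related pairs.
#' @param c,d connected and tested counts, unrelated pairs.
#' @param alpha_smooth additive smoothing constant (default 1).
#' @return signed log2 ratio.
#' @export
smoothed_log_ratio <- function(a, b, c, d, alpha_smooth = 1) {
  check_count(a, "a"); check_count(b, "b"); check_count(c, "c"); check_count(d, "d")
  log2(((a + alpha_smooth) / (b + alpha_smooth)) /
         ((c + alpha_smooth) / (d + alpha_smooth)))
}

#' Smoothed log-ratio table of related vs unrelated connectivity
#'
#' For each layer-defined connection type, the Laplace-smoothed log2 ratio of
#' the related and unrelated connection probabilities, with a bootstrap 95%
#' coverage interval: on each iteration `A_boot ~ Binomial(B, (A+1)/(B+1))`
#' and `C_boot ~ Binomial(D, (C+1)/(D+1))` are drawn and the smoothed
#' log-ratio recomputed.
#'
#' @param counts a data frame with columns `k_r`, `m_r`, `k_u`, `m_u` (and
#'   any identifying columns, carried through), e.g.
#'   [clonal_connection_counts()], or a pair table, which is first tallied by
#'   `(pre_layer, post_layer)`.
#' @param alpha_smooth additive smoothing constant (default 1).
#' @param reps bootstrap iterations (default 1000).
#' @param seed optional integer seed.
#' @return a tibble of class `log_ratio_table` with `log2_ratio`, `ci_low`,
#'   `ci_high` and a `significant` flag (interval excluding 0) per row.
#' @examples
#' log_ratio_table(clonal_connection_counts(), seed = 1)
#' @export
log_ratio_table <- function(counts, alpha_smooth = 1, reps = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_count(reps, "reps", min = 1)
  if (all(c("relation", "connected") %in% names(counts))) {
    counts <- tally_pair_counts(counts)
  }
  need <- c("k_r", "m_r", "k_u", "m_u")
  if (!all(need %in% names(counts))) {
    abort("`counts` needs columns k_r, m_r, k_u, m_u (or a pair table).")
  }
  out <- as_tibble(counts) |>
    mutate(log2_ratio = smoothed_log_ratio(.data$k_r, .data$m_r,
                                           .data$k_u, .data$m_u, alpha_smooth))
  ci <- pmap(list(out$k_r, out$m_r, out$k_u, out$m_u), function(a, b, c, d) {
    a_boot <- rbinom(reps, b, (a + alpha_smooth) / (b + alpha_smooth))
    c_boot <- rbinom(reps, d, (c + alpha_smooth) / (d + alpha_smooth))
    lr <- smoothed_log_ratio(a_boot, b, c_boot, d, alpha_smooth)
    quantile(lr, c(0.025, 0.975), names = FALSE)
  })
  out <- mutate(out,
                ci_low = map_dbl(ci, 1),
                ci_high = map_dbl(ci, 2),
                significant = .data$ci_low > 0 | .data$ci_high < 0)
  class(out) <- c("log_ratio_table", class(out))
  out
}

# tally a pair table into per-connection-type related/unrelated counts
tally_pair_counts <- function(pairs) {
  validate_pair_table(pairs)
  dat <- filter(as_tibble(pairs), .data$relation %in% c("related", "unrelated"))
  dat |>
    group_by(.data$pre_layer, .data$post_layer, .data$relation) |>
    summarise(k = sum(.data$connected), n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "relation", values_from = c("k", "n"),
                       values_fill = 0L) |>
    rename(k_r = "k_related", m_r = "n_related",
           k_u = "k_unrelated", m_u = "n_unrelated")
}
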