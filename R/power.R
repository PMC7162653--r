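# Lineage-pooling power analysis.
#
# A labeled clone pools N radial-glial (RGC) lineages. If only neurons
# sharing a single RGC are preferentially connected (fold change FC over the
# unrelated rate), pooling dilutes the effect. The pooled lateral rate among
# clone members is a mixture over same-RGC and different-RGC partners within
# a layer, excluding the cell itself from its own same-RGC pool.

#' Predicted pooled lateral connection probability under lineage pooling
#'
#' `P_rl = (P_ul * S/L * (N-1)/N + P_ul * FC * (S/(N L) - 1)) / (S/L - 1)`:
#' of the `S/L - 1` other clone members in the same layer, `S/(NL) - 1` share
#' the cell's RGC (connected at `FC * P_ul`) and the rest connect at the
#' unrelated rate `P_ul`. Assumes an equal distribution of each RGC lineage
#' across the `L` layers.
#'
#' @param p_ul unrelated lateral connection probability.
#' @param s clone size (default 60, the median clone size).
#' @param l number of layers occupied by the clone (default 4).
#' @param n_lineages number of RGC lineages pooled in the clone, `N`.
#' @param fc fold change in connectivity between same-RGC and unrelated
#'   neurons (>= 0).
#' @return predicted pooled lateral probability, clipped to \[0, 1\] with a
#'   warning when the raw value exceeds 1.
#' @examples
#' predicted_lateral_cp(51 / 626, n_lineages = 2, fc = 3.516)  # ~0.177
#' @export
predicted_lateral_cp <- function(p_ul, s = 60, l = 4, n_lineages, fc) {
  check_prob(p_ul, "p_ul")
  if (any(fc < 0)) abort("`fc` must be >= 0.")
  check_count(n_lineages, "n_lineages", min = 1)
  if (s / l <= 1) abort("`s / l` must exceed 1 (a cell needs same-layer clone mates).")
  raw <- (p_ul * s / l * (n_lineages - 1) / n_lineages +
            p_ul * fc * (s / (n_lineages * l) - 1)) / (s / l - 1)
  if (any(raw > 1)) {
    warn("Predicted lateral probability exceeded 1 and was clipped.")
  }
  pmin(pmax(raw, 0), 1)
}

#' Fold change implied by observed vertical connectivity under lineage pooling
#'
#' Inverts `P_rv = P_uv (N-1)/N + FC * P_uv / N`: among vertical partners in
#' the clone, a fraction `1/N` shares the cell's RGC. Returns the fold change
#' and the implied single-RGC vertical connection probability `FC * P_uv`.
#'
#' @param p_rv observed vertical connection probability among clone members.
#' @param p_uv observed vertical connection probability among unrelated pairs
#'   (> 0).
#' @param n_lineages number of RGC lineages per clone, `N`.
#' @return a tibble with columns `n_lineages`, `fc`, `p_single`
#'   (`= fc * p_uv`, the implied same-RGC vertical probability).
#' @examples
#' infer_fc_from_vertical(28 / 464, 19 / 711, n_lineages = 2)  # p_single ~0.094
#' @export
infer_fc_from_vertical <- function(p_rv, p_uv, n_lineages) {
  check_prob(p_rv, "p_rv"); check_prob(p_uv, "p_uv")
  if (any(p_uv == 0)) abort("`p_uv` must be positive to infer a fold change.")
  check_count(n_lineages, "n_lineages", min = 1)
  fc <- n_lineages * p_rv / p_uv - (n_lineages - 1)
  tibble(n_lineages = n_lineages, fc = fc, p_single = fc * p_uv)
}

#' Cohen's h effect size for two proportions
#'
#' `h = 2 asin(sqrt(p1)) - 2 asin(sqrt(p2))`, in radians; antisymmetric in
#' its arguments.
#'
#' @param p1,p2 proportions in \[0, 1\].
#' @return signed effect size.
#' @export
cohens_h <- function(p1, p2) {
  check_prob(p1, "p1"); check_prob(p2, "p2")
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Normal-approximation power of a two-proportion test with unequal n
#'
#' Power of the arcsine-transform two-proportion z test at effect size `h`
#' with group sizes `n1`, `n2` and effective size `ñ = n1 n2 / (n1 + n2)`.
#' Two-sided: `Φ(|h|√ñ − z_{1−α/2}) + Φ(−|h|√ñ − z_{1−α/2})`; at `h = 0` this
#' equals `α`.
#'
#' @param h Cohen's h effect size.
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level (default 0.05).
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @return power in \[0, 1\].
#' @examples
#' two_proportion_power(-0.289, 626, 248)  # ~0.97
#' @export
two_proportion_power <- function(h, n1, n2, alpha = 0.05,
                                 alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  check_count(n1, "n1", min = 2); check_count(n2, "n2", min = 2)
  if (any(alpha <= 0) || any(alpha >= 1)) abort("`alpha` must be in (0, 1).")
  n_eff <- n1 * n2 / (n1 + n2)
  if (alternative == "two.sided") {
    z <- qnorm(1 - alpha / 2)
    pnorm(abs(h) * sqrt(n_eff) - z) + pnorm(-abs(h) * sqrt(n_eff) - z)
  } else {
    z <- qnorm(1 - alpha)
    pnorm(abs(h) * sqrt(n_eff) - z)
  }
}

#' Power grid over lineage counts and fold changes
#'
#' For every combination of `N` (lineages per clone) and `FC` (same-RGC fold
#' change), predicts the pooled lateral probability, the Cohen's h effect
#' size against the unrelated lateral rate, and the two-sided power of the
#' lateral comparison.
#'
#' @param p_ul unrelated lateral connection probability (default 51/626).
#' @param s,l clone size and layer count (defaults 60 and 4).
#' @param n_lineages integer vector of lineage counts (default 1:20).
#' @param fc numeric vector of fold changes (default `seq(0, 30, by = 0.1)`).
#' @param n1,n2 lateral sample sizes (defaults 626 unrelated, 248 related).
#' @param alpha significance level (default 0.05).
#' @return a tibble of class `power_grid` with columns `n_lineages`, `fc`,
#'   `p_rl`, `h`, `power`.
#' @seealso [inferred_fc_trace()] for the trace pinned to the observed
#'   vertical rates.
#' @export
power_grid <- function(p_ul = 51 / 626, s = 60, l = 4,
                       n_lineages = 1:20, fc = seq(0, 30, by = 0.1),
                       n1 = 626, n2 = 248, alpha = 0.05) {
  grid <- tidyr::expand_grid(n_lineages = n_lineages, fc = fc) |>
    mutate(
      p_rl = suppressWarnings(
        predicted_lateral_cp(p_ul, s, l, .data$n_lineages, .data$fc)),
      h = cohens_h(p_ul, .data$p_rl),
      power = two_proportion_power(.data$h, n1, n2, alpha)
    )
  class(grid) <- c("power_grid", class(grid))
  attr(grid, "params") <- list(p_ul = p_ul, s = s, l = l,
                               n1 = n1, n2 = n2, alpha = alpha)
  grid
}

#' Inferred-fold-change power trace
#'
#' For each lineage count `N`, infers the fold change that explains the
#' observed vertical connectivity, propagates it to the predicted pooled
#' lateral probability, and evaluates the power of the lateral comparison —
#' the "red dot" trace through the power grid.
#'
#' @inheritParams power_grid
#' @param p_rv,p_uv observed related / unrelated vertical connection
#'   probabilities (defaults 28/464 and 19/711).
#' @return a tibble with columns `n_lineages`, `fc`, `p_single`, `p_rl`, `h`,
#'   `power`.
#' @examples
#' inferred_fc_trace(n_lineages = 1:5)
#' @export
inferred_fc_trace <- function(p_rv = 28 / 464, p_uv = 19 / 711,
                              p_ul = 51 / 626, s = 60, l = 4,
                              n_lineages = 1:20,
                              n1 = 626, n2 = 248, alpha = 0.05) {
  infer_fc_from_vertical(p_rv, p_uv, n_lineages) |>
    mutate(
      p_rl = suppressWarnings(
        predicted_lateral_cp(p_ul, s, l, .data$n_lineages, .data$fc)),
      h = cohens_h(p_ul, .data$p_rl),
      power = two_proportion_power(.data$h, n1, n2, alpha)
    )
}

#' Sample size for a two-proportion comparison at given power
#'
#' Per-group sample size for equal groups, consistent with
#' [two_proportion_power()]: with `n1 = n2 = n` the effective size is `n/2`,
#' so `n = 2 (z_{1-alpha/2} + z_{power})^2 / h^2` for the two-sided test.
#'
#' @param h Cohen's h effect size (nonzero).
#' @param power target power (default 0.9).
#' @inheritParams two_proportion_power
#' @return per-group sample size (not rounded; take the ceiling for a design).
#' @export
two_proportion_sample_size <- function(h, power = 0.9, alpha = 0.05,
                                       alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  if (any(h == 0)) abort("`h` must be nonzero.")
  z_a <- if (alternative == "two.sided") qnorm(1 - alpha / 2) else qnorm(1 - alpha)
  2 * ((z_a + qnorm(power)) / abs(h))^2
}
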