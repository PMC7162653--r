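# Binomial cortical-cylinder model of lineage-dependent synaptic input.
#
# A postsynaptic cell is assumed to receive potential inputs only from
# excitatory neurons within a tangential radius r. The number of realized
# inputs from each (layer, lineage) pool is binomial with the empirically
# measured connection probability, so the expected fraction of input coming
# from clonally related cells has a closed form in which the pool sizes
# cancel and only the related fraction q_r of the cylinder survives.

#' Cortical cylinder composition model
#'
#' Describes the local pool of potential presynaptic partners: all excitatory
#' neurons within a tangential radius of the postsynaptic cell, split across
#' layers, of which a clone of `clone_size` cells is clonally related.
#'
#' @param neurons_per_mm2 neuronal density under 1 mm^2 of cortical surface
#'   (default 100,000).
#' @param excitatory_fraction fraction of neurons that are excitatory
#'   (default 0.8).
#' @param radius_mm tangential connectivity radius in mm (default 0.087, half
#'   the 99% quantile of measured pairwise distances). The printed radius is
#'   rounded; see `n_total`.
#' @param layer_fractions named numeric vector of layer occupancy fractions,
#'   summing to 1 (defaults: L2/3 0.35, L4 0.15, L5 0.25, L6 0.25).
#' @param clone_size number of labeled (clonally related) neurons in the
#'   cylinder, `k` (default 60, the median clone size).
#' @param n_total optional override of the total excitatory count. By default
#'   `pi * radius_mm^2 * neurons_per_mm2 * excitatory_fraction` (about 1902
#'   under the defaults); pass 1908 to reproduce the rounded published count
#'   exactly.
#' @return an object of class `cylinder_model`.
#' @examples
#' m <- cylinder_model(n_total = 1908)
#' cylinder_counts(m)
#' @export
cylinder_model <- function(neurons_per_mm2 = 1e5,
                           excitatory_fraction = 0.8,
                           radius_mm = 0.087,
                           layer_fractions = c("L2/3" = 0.35, "L4" = 0.15,
                                               "L5" = 0.25, "L6" = 0.25),
                           clone_size = 60,
                           n_total = NULL) {
  if (neurons_per_mm2 <= 0 || excitatory_fraction <= 0 || radius_mm <= 0) {
    abort("Density, excitatory fraction and radius must be positive.")
  }
  if (abs(sum(layer_fractions) - 1) > 1e-9) {
    abort("`layer_fractions` must sum to 1.")
  }
  check_prob(layer_fractions, "layer_fractions")
  check_count(clone_size, "clone_size", min = 1)
  if (is.null(n_total)) {
    n_total <- pi * radius_mm^2 * neurons_per_mm2 * excitatory_fraction
  }
  if (clone_size >= n_total) {
    abort("`clone_size` must be smaller than the cylinder population.")
  }
  structure(
    list(
      neurons_per_mm2 = neurons_per_mm2,
      excitatory_fraction = excitatory_fraction,
      radius_mm = radius_mm,
      layer_fractions = layer_fractions,
      clone_size = clone_size,
      n_total = n_total,
      q_r = clone_size / n_total
    ),
    class = "cylinder_model"
  )
}

#' @export
print.cylinder_model <- function(x, ...) {
  cat("Cortical cylinder model\n")
  cat(sprintf("  radius: %.3f mm, excitatory neurons: %.0f\n",
              x$radius_mm, x$n_total))
  cat(sprintf("  clone size k = %d, related fraction q_r = %.4f\n",
              x$clone_size, x$q_r))
  invisible(x)
}

#' Per-layer excitatory counts in the cortical cylinder
#'
#' @param model a [cylinder_model()].
#' @return a tibble with one row per layer (`layer`, `fraction`, `n_cells`)
#'   and attributes `n_total` and `q_r`.
#' @export
cylinder_counts <- function(model) {
  stopifnot(inherits(model, "cylinder_model"))
  out <- tibble(
    layer = names(model$layer_fractions),
    fraction = unname(model$layer_fractions),
    n_cells = unname(model$layer_fractions) * model$n_total
  )
  attr(out, "n_total") <- model$n_total
  attr(out, "q_r") <- model$q_r
  out
}

#' Expected fraction of synaptic input from clonally related cells
#'
#' Closed form `e = p_r q / (p_r q + p_u (1 - q))`, where `p_r` and `p_u` are
#' the measured connection probabilities from related and unrelated
#' presynaptic cells and `q` is the fraction of the local pool that is
#' clonally related. Pool sizes cancel, so the layer composition of the
#' cylinder does not enter.
#'
#' @param p_r,p_u connection probabilities for related / unrelated
#'   presynaptic partners.
#' @param q_r related fraction of the cylinder (e.g. `cylinder_model()$q_r`).
#' @return numeric vector of input fractions in \[0, 1\].
#' @examples
#' related_input_fraction(7 / 62, 2 / 89, 60 / 1908)  # ~0.140
#' @export
related_input_fraction <- function(p_r, p_u, q_r) {
  check_prob(p_r, "p_r"); check_prob(p_u, "p_u"); check_prob(q_r, "q_r")
  if (any(p_r == 0 & p_u == 0)) {
    abort("`p_r` and `p_u` cannot both be zero: the input fraction is undefined.")
  }
  p_r * q_r / (p_r * q_r + p_u * (1 - q_r))
}

#' Delta-method standard error of the related input fraction
#'
#' First-order Taylor propagation of the binomial standard errors of the two
#' estimated connection probabilities, treated as independent:
#' `se = sqrt( q^2 (1-q)^2 [ p_u^2 p_r(1-p_r)/m_r + p_r^2 p_u(1-p_u)/m_u ]
#'             / (p_u (1-q) + p_r q)^4 )`.
#'
#' @inheritParams related_input_fraction
#' @param m_r,m_u numbers of tested connections behind `p_r` and `p_u`.
#' @return numeric vector of standard errors; exactly 0 when `q_r = 0`.
#' @examples
#' input_fraction_se(7 / 62, 2 / 89, 62, 89, 60 / 1908)  # ~0.095
#' @export
input_fraction_se <- function(p_r, p_u, m_r, m_u, q_r) {
  check_prob(p_r, "p_r"); check_prob(p_u, "p_u"); check_prob(q_r, "q_r")
  check_count(m_r, "m_r", min = 1); check_count(m_u, "m_u", min = 1)
  denom <- (p_u * (1 - q_r) + p_r * q_r)^4
  if (any(denom == 0)) {
    abort("`p_r` and `p_u` cannot both be zero: the standard error is undefined.")
  }
  num <- q_r^2 * (1 - q_r)^2 *
    (p_u^2 * p_r * (1 - p_r) / m_r + p_r^2 * p_u * (1 - p_u) / m_u)
  sqrt(num / denom)
}

#' Related input fractions for a table of connection counts
#'
#' Applies [related_input_fraction()] and [input_fraction_se()] row-wise to a
#' table of per-connection-type counts (connected/tested for related and
#' unrelated pairs), as printed in figure legends.
#'
#' @param counts a data frame with columns `k_r`, `m_r`, `k_u`, `m_u`
#'   (connected and tested counts for related and unrelated pairs); any other
#'   columns (e.g. `pre_layer`, `post_layer`) are carried through.
#' @param model a [cylinder_model()] supplying `q_r`.
#' @return the input tibble with `p_r`, `p_u`, `e`, `se` columns appended and,
#'   for display, `e_pct`/`se_pct` rounded half away from zero to one decimal.
#' @examples
#' related_input_table(clonal_connection_counts(), cylinder_model(n_total = 1908))
#' @export
related_input_table <- function(counts, model) {
  stopifnot(inherits(model, "cylinder_model"))
  need <- c("k_r", "m_r", "k_u", "m_u")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0) {
    abort(sprintf("`counts` is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  q <- model$q_r
  as_tibble(counts) |>
    mutate(
      p_r = .data$k_r / .data$m_r,
      p_u = .data$k_u / .data$m_u,
      e = related_input_fraction(.data$p_r, .data$p_u, q),
      se = input_fraction_se(.data$p_r, .data$p_u, .data$m_r, .data$m_u, q),
      e_pct = round_half_up(100 * .data$e, 1),
      se_pct = round_half_up(100 * .data$se, 1)
    )
}

# round half away from zero (matches the printed percentage convention;
# base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Expected presynaptic partner counts per layer and lineage
#'
#' Models the number of inputs from each (layer, lineage) pool as binomial
#' `B(n_i q_l, p)`: mean `n_i q_l p`, variance `n_i q_l p (1 - p)`, where
#' `n_i` is the layer's excitatory count and `q_l` is the related (`q_r`) or
#' unrelated (`1 - q_r`) fraction of the cylinder.
#'
#' @param model a [cylinder_model()].
#' @param probs a data frame with columns `layer`, `p_related`, `p_unrelated`
#'   giving connection probabilities from each input layer.
#' @return a tibble with one row per (layer, lineage): pool size, connection
#'   probability, expected count and variance, plus the implied related input
#'   fraction `e` per layer (equal to the closed form, since pools cancel).
#' @export
expected_inputs <- function(model, probs) {
  stopifnot(inherits(model, "cylinder_model"))
  need <- c("layer", "p_related", "p_unrelated")
  if (!all(need %in% names(probs))) {
    abort("`probs` needs columns layer, p_related, p_unrelated.")
  }
  counts <- cylinder_counts(model)
  long <- as_tibble(probs) |>
    left_join(counts, by = "layer") |>
    tidyr::pivot_longer(c("p_related", "p_unrelated"),
                        names_to = "lineage", values_to = "p",
                        names_prefix = "p_") |>
    mutate(
      pool_size = .data$n_cells *
        ifelse(.data$lineage == "related", model$q_r, 1 - model$q_r),
      expected = .data$pool_size * .data$p,
      variance = .data$pool_size * .data$p * (1 - .data$p)
    )
  e_by_layer <- long |>
    select("layer", "lineage", "expected") |>
    tidyr::pivot_wider(names_from = "lineage", values_from = "expected") |>
    mutate(e = .data$related / (.data$related + .data$unrelated)) |>
    select("layer", "e")
  long |>
    left_join(e_by_layer, by = "layer") |>
    select("layer", "lineage", "p", "pool_size", "expected", "variance", "e")
}

#' Published per-type connection counts for clonally related and unrelated pairs
#'
#' Connected/tested counts from paired whole-cell recordings between
#' excitatory neurons in translaminar clones, one row per layer-defined
#' connection type (columns `k_r`/`m_r`: related, `k_u`/`m_u`: unrelated).
#' Vertical types cross layers; lateral types stay within a layer. These are
#' the inputs to [related_input_table()] and to the lineage-pooling power
#' analysis.
#'
#' @return a tibble with columns `pre_layer`, `post_layer`, `class`,
#'   `k_r`, `m_r`, `k_u`, `m_u`.
#' @export
clonal_connection_counts <- function() {
  tribble(
    ~pre_layer, ~post_layer, ~class,     ~k_r, ~m_r, ~k_u, ~m_u,
    "L4",       "L2/3",      "vertical",  12L,  91L,  12L, 149L,
    "L4",       "L5",        "vertical",   7L,  62L,   2L,  89L,
    "L2/3",     "L5",        "vertical",   6L,  76L,   2L, 123L,
    "L2/3",     "L2/3",      "lateral",    2L, 105L,  20L, 342L,
    "L4",       "L4",        "lateral",   11L, 100L,  17L, 148L,
    "L5",       "L5",        "lateral",    1L,  43L,  14L, 136L
  )
}

#' Published pooled connection counts by connection class
#'
#' Pooled connected/tested counts across all vertical (translaminar) and all
#' lateral (within-layer) tested pairs, for related and unrelated neurons.
#'
#' @return a tibble with columns `class`, `k_r`, `m_r`, `k_u`, `m_u`.
#' @export
clonal_pooled_counts <- function() {
  tribble(
    ~class,     ~k_r, ~m_r, ~k_u, ~m_u,
    "vertical",  28L, 464L,  19L, 711L,
    "lateral",   14L, 248L,  51L, 626L
  )
}
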