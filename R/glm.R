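# Binomial GLM of connection probability.
#
# Each tested directed pair is a Bernoulli trial. Predictors: lineage L
# (1 related, 0 unrelated), connection type C (1 vertical, 0 lateral),
# Euclidean distance D (micrometres), rostrocaudal position R (1-5), plus
# all pairwise interactions; logit link, fitted by IRLS.

#' Binomial GLM of connection probability
#'
#' Fits `logit(P) = b0 + bL L + bC C + bD D + bR R + all pairwise
#' interactions` over tested directed pairs, with Wald standard errors. The
#' model has 11 parameters, so the residual degrees of freedom are
#' `n_pairs - 11`.
#'
#' @param pairs a pair table with `relation`, layers, `euclidean_um` and
#'   `rostrocaudal`; only `related`/`unrelated` rows enter the fit.
#' @return an object of class `connectivity_glm` wrapping the [stats::glm()]
#'   fit, with [tidy()] and [glance()] methods. Non-convergence or quasi-
#'   separation (fitted probabilities numerically at 0/1) is flagged in
#'   `$diagnostics` and raised as a warning, never silently ignored.
#' @examples
#' cfg <- sim_config(seed = 5)
#' pairs <- simulate_pair_tests(simulate_clone_population(cfg), cfg)
#' fit <- connectivity_glm(pairs)
#' tidy(fit)
#' @export
connectivity_glm <- function(pairs) {
  validate_pair_table(pairs, c(pair_table_columns(), "euclidean_um",
                               "rostrocaudal"))
  dat <- classify_connections(pairs) |>
    filter(.data$relation %in% c("related", "unrelated")) |>
    mutate(
      L = as.integer(.data$relation == "related"),
      C = as.integer(.data$class == "vertical"),
      D = .data$euclidean_um,
      R = as.integer(.data$rostrocaudal),
      y = as.integer(.data$connected)
    )
  if (nrow(dat) <= 11) abort("Need more tested pairs than model parameters (11).")
  fit <- suppressWarnings(
    glm(y ~ (L + C + D + R)^2, family = binomial("logit"), data = dat)
  )
  eps <- 1e-8
  separated <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  diagnostics <- list(converged = fit$converged, separation = separated,
                      n = nrow(dat), df_residual = fit$df.residual)
  if (!fit$converged) warn("Connectivity GLM did not converge; inspect $diagnostics.")
  if (separated) warn("Possible separation: fitted probabilities at 0/1; inspect $diagnostics.")
  structure(list(fit = fit, diagnostics = diagnostics),
            class = "connectivity_glm")
}

glm_term_labels <- function() {
  c("(Intercept)" = "Constant",
    "L" = "Lineage", "C" = "Connection type",
    "D" = "Euclidean distance", "R" = "Rostrocaudal position",
    "L:C" = "Lineage x Connection type",
    "L:D" = "Lineage x Euclidean distance",
    "L:R" = "Lineage x Rostrocaudal position",
    "C:D" = "Connection type x Euclidean distance",
    "C:R" = "Connection type x Rostrocaudal position",
    "D:R" = "Euclidean distance x Rostrocaudal position")
}

#' @describeIn connectivity_glm coefficient table: estimate, Wald SE,
#'   z statistic and two-sided p per term.
#' @param x a `connectivity_glm` object.
#' @param ... unused.
#' @export
tidy.connectivity_glm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  labels <- glm_term_labels()
  tibble(
    term = unname(labels[rownames(sm)]),
    raw_term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"]
  )
}

#' @describeIn connectivity_glm one-row model summary: null-vs-model
#'   chi-squared, its p-value, residual df, convergence/separation flags.
#' @export
glance.connectivity_glm <- function(x, ...) {
  f <- x$fit
  chisq <- f$null.deviance - f$deviance
  df <- f$df.null - f$df.residual
  tibble(
    chi_squared = chisq,
    df = df,
    p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
    df_residual = f$df.residual,
    n = x$diagnostics$n,
    converged = x$diagnostics$converged,
    separation = x$diagnostics$separation
  )
}

#' @export
print.connectivity_glm <- function(x, ...) {
  cat("Binomial GLM of connection probability (logit link)\n")
  g <- glance(x)
  cat(sprintf("  n = %d tested pairs, chi^2 = %.1f on %d df (p = %.3g), %d residual df\n",
              g$n, g$chi_squared, g$df, g$p_value, g$df_residual))
  print(tidy(x))
  invisible(x)
}
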