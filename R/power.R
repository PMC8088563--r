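#' Monte-Carlo power or type-1 error for a design and analysis method
#'
#' Simulates genes one at a time under the design (genes are generated
#' independently, so one single-gene dataset per replicate is equivalent to
#' one multi-gene dataset and embarrassingly parallel), applies the chosen
#' test, and reports the proportion of replicates rejected at `alpha`. When
#' the design carries no effect (fold change 1, or rho 0) the same loop
#' estimates the type-1 error; [estimate_type1()] is a convenience wrapper
#' that nullifies the effect and relabels the estimate. No multiple-testing
#' correction is applied: power is per-test at fixed `alpha`.
#'
#' Replicates whose fit does not converge (or returns no p-value) are never
#' counted as rejections and are tallied in `n_failed` — a conservative
#' convention that avoids biasing power upward. Each replicate derives its
#' own seed from `seed` by a fixed linear scheme, so estimates are
#' reproducible and extendable.
#'
#' @param design A [sim_design()]; its `fold_change`/`rho` is the effect at
#'   which power is evaluated.
#' @param model A `sim_model`.
#' @param method `"hurdle_mixed"`, `"hurdle_naive"` or `"pseudobulk"`.
#' @param alpha Significance level (default 0.05).
#' @param n_genes Number of simulated genes (Monte-Carlo replicates);
#'   the default 500 gives a binomial standard error of at most 0.023.
#' @param test_type `"lrt"` or `"wald"` for the hurdle methods.
#' @param seed Root seed; defaults to `design$seed`, else 1.
#' @param keep_pvalues Keep the per-gene p-values in the result.
#' @return A `power_estimate` object.
#' @export
estimate_power <- function(design, model,
                           method = c("hurdle_mixed", "hurdle_naive", "pseudobulk"),
                           alpha = 0.05, n_genes = 500, test_type = "lrt",
                           seed = NULL, keep_pvalues = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(design, "sim_design"), inherits(model, "sim_model"))
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  if (!is_count(n_genes)) abort("`n_genes` must be a positive integer.")
  seed <- seed %||% design$seed %||% 1L

  null_effect <- if (design$phenotype == "binary") design$fold_change == 1 else design$rho == 0
  d1 <- design
  d1$n_genes <- 1L
  d1$frac_de <- 1
  simulate_one <- if (design$phenotype == "binary") simulate_binary else simulate_continuous

  p <- numeric(n_genes)
  ok <- logical(n_genes)
  for (i in seq_len(n_genes)) {
    d1$seed <- derive_seed(seed, i)
    sim <- simulate_one(d1, model)
    res <- test_genes(sim, method = method, test_type = test_type)
    p[i] <- res$p[1]
    ok[i] <- isTRUE(res$converged[1]) && !is.na(res$p[1])
  }
  rejected <- ok & p <= alpha
  rate <- sum(rejected) / n_genes
  structure(list(
    role = if (null_effect) "type1" else "power",
    estimate = rate,
    mc_se = sqrt(rate * (1 - rate) / n_genes),
    n_genes = n_genes,
    n_rejected = sum(rejected),
    n_failed = sum(!ok),
    alpha = alpha, method = method, test_type = test_type,
    seed = seed, design = design,
    pvalues = if (keep_pvalues) p else NULL,
    converged = if (keep_pvalues) ok else NULL),
    class = "power_estimate")
}

#' @rdname estimate_power
#'
#' @details `estimate_type1()` runs the identical Monte-Carlo loop with the
#'   effect nullified (`fold_change = 1` or `rho = 0`), so the null genes
#'   share the code path of the power loop by construction.
#' @export
estimate_type1 <- function(design, model,
                           method = c("hurdle_mixed", "hurdle_naive", "pseudobulk"),
                           alpha = 0.05, n_genes = 500, test_type = "lrt",
                           seed = NULL, keep_pvalues = FALSE) {
  design$fold_change <- 1
  design$rho <- 0
  estimate_power(design, model, method = method, alpha = alpha,
                 n_genes = n_genes, test_type = test_type, seed = seed,
                 keep_pvalues = keep_pvalues)
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> %s = %.3f (MC se %.3f), %s at alpha = %g\n",
              x$role, x$estimate, x$mc_se, x$method, x$alpha))
  cat(sprintf("  %d/%d rejected, %d failed fits, seed %d\n",
              x$n_rejected, x$n_genes, x$n_failed, x$seed))
  invisible(x)
}

#' Tidy a power estimate
#'
#' @param x A `power_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the design, method and estimate.
#' @method tidy power_estimate
#' @export
tidy.power_estimate <- function(x, ...) {
  d <- x$design
  tibble(
    role = x$role, estimate = x$estimate, mc_se = x$mc_se,
    method = x$method, alpha = x$alpha,
    phenotype = d$phenotype,
    n_per_group = if (d$phenotype == "binary") d$n_per_group else NA_integer_,
    n_individuals = if (d$phenotype == "continuous") d$n_individuals else NA_integer_,
    cells_per_individual = d$cells_per_individual,
    cell_count_mode = d$cell_count_mode,
    fold_change = if (d$phenotype == "binary") d$fold_change else NA_real_,
    rho = if (d$phenotype == "continuous") d$rho else NA_real_,
    n_genes = x$n_genes, n_rejected = x$n_rejected, n_failed = x$n_failed,
    seed = x$seed)
}

#' @rdname tidy.power_estimate
#' @method glance power_estimate
#' @export
glance.power_estimate <- function(x, ...) {
  tibble(estimate = x$estimate, mc_se = x$mc_se, role = x$role,
         n_genes = x$n_genes, n_failed = x$n_failed)
}

#' Evaluate power over a grid of designs and methods
#'
#' Crosses a table of design parameters with a set of analysis methods and
#' runs [estimate_power()] on every combination under one root seed. The
#' result is a tidy table (one row per design-method pair) ready for
#' plotting power curves with [autoplot()].
#'
#' @param designs A data frame whose columns are [sim_design()] arguments
#'   (e.g. `n_per_group`, `cells_per_individual`, `fold_change`), one row
#'   per design; or a list of `sim_design` objects.
#' @param model A `sim_model`.
#' @param methods Character vector of analysis methods.
#' @param alpha Significance level.
#' @param n_genes Monte-Carlo replicates per cell of the grid.
#' @param seed Root seed; each grid row gets a derived, recorded seed.
#' @param ... Passed to [estimate_power()].
#' @return A `power_grid` tibble.
#' @export
power_grid <- function(designs, model, methods = "hurdle_mixed",
                       alpha = 0.05, n_genes = 500, seed = 1, ...) {
  if (is.data.frame(designs)) {
    designs <- purrr::pmap(designs, sim_design)
  }
  stopifnot(length(designs) >= 1, length(methods) >= 1)
  grid <- tidyr::expand_grid(design_idx = seq_along(designs), method = methods)
  rows <- purrr::pmap(grid, function(design_idx, method) {
    d <- designs[[design_idx]]
    row_seed <- derive_seed(seed, 104729 * (design_idx - 1) +
                              match(method, methods))
    est <- estimate_power(d, model, method = method, alpha = alpha,
                          n_genes = n_genes, seed = row_seed, ...)
    tidy(est)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_grid", class(out))
  out
}

#' Plot power curves from a grid
#'
#' @param object A `power_grid` tibble.
#' @param x Name of the design column for the x axis; defaults to the first
#'   design column that varies.
#' @param ... Unused.
#' @return A ggplot object: one line per method, with Monte-Carlo error
#'   bars.
#' @method autoplot power_grid
#' @export
autoplot.power_grid <- function(object, x = NULL, ...) {
  candidates <- c("n_per_group", "n_individuals", "cells_per_individual",
                  "fold_change", "rho")
  if (is.null(x)) {
    varying <- candidates[vapply(candidates, function(v) {
      col <- object[[v]]
      !is.null(col) && dplyr::n_distinct(col[!is.na(col)]) > 1
    }, logical(1))]
    x <- if (length(varying)) varying[1] else candidates[1]
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x]], y = .data$estimate,
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$estimate - .data$mc_se),
                                        ymax = pmin(1, .data$estimate + .data$mc_se)),
                           width = 0) +
    ggplot2::labs(y = unique(object$role), x = x, colour = "method") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
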