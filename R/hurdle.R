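#' Log(x + 1) transformation
#'
#' @param values Non-negative numeric vector or matrix.
#' @return Natural log of `values + 1`, elementwise.
#' @export
log1_transform <- function(values) {
  if (any(values < 0)) abort("`values` must be non-negative.")
  log1p(values)
}

#' Combine the two hurdle components into one chi-squared test
#'
#' The discrete (expressed / not expressed) and continuous (level given
#' expressed) components are tested separately; because the indicator and
#' the conditional level are defined conditionally independent, their
#' likelihood-ratio or Wald statistics can be summed and referred to a
#' chi-squared distribution whose degrees of freedom are the sum of the
#' component degrees of freedom. Zero total degrees of freedom (both
#' components degenerate) yields p = 1.
#'
#' @param stat_d,df_d Statistic and df of the discrete component.
#' @param stat_c,df_c Statistic and df of the continuous component.
#' @return A list with `stat`, `df` and `p`.
#' @export
combine_components <- function(stat_d, df_d, stat_c, df_c) {
  if (stat_d < 0 || stat_c < 0) abort("Component statistics must be non-negative.")
  if (df_d < 0 || df_c < 0) abort("Component degrees of freedom must be non-negative.")
  stat <- stat_d + stat_c
  df <- df_d + df_c
  p <- if (df == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  list(stat = stat, df = df, p = p)
}

# Fit one model quietly, collecting warnings. lme4's boundary (singular)
# message is expected and accepted; other convergence warnings mark the
# component as not converged.
quiet_fit <- function(expr) {
  warns <- character(0)
  fit <- withCallingHandlers(
    tryCatch(expr, error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  list(fit = fit, error = inherits(fit, "error"),
       converged = !any(grepl("failed to converge|convergence code",
                              warns, ignore.case = TRUE)))
}

# Wald chi-squared for all non-intercept fixed effects of a fitted model.
wald_stat <- function(fit) {
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  V <- as.matrix(vcov(fit))
  keep <- setdiff(seq_along(b), which(names(b) == "(Intercept)"))
  if (!length(keep)) return(list(stat = 0, df = 0L))
  b <- b[keep]
  V <- V[keep, keep, drop = FALSE]
  list(stat = as.numeric(t(b) %*% solve(V) %*% b), df = length(keep))
}

# One component's test: full vs null fit with LRT (Wald fallback when the
# null refit fails or when requested). Returns stat/df/converged/note.
component_test <- function(fit_full, fit_null_fun, test_type) {
  if (fit_full$error) {
    return(list(stat = 0, df = 0L, converged = FALSE, note = "fit_failed"))
  }
  note <- NA_character_
  if (test_type == "lrt") {
    qn <- quiet_fit(fit_null_fun())
    if (!qn$error) {
      ll1 <- logLik(fit_full$fit)
      ll0 <- logLik(qn$fit)
      stat <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
      df <- as.integer(attr(ll1, "df") - attr(ll0, "df"))
      return(list(stat = stat, df = df,
                  converged = fit_full$converged && qn$converged,
                  note = note))
    }
    note <- "wald_fallback"
  }
  w <- wald_stat(fit_full$fit)
  list(stat = w$stat, df = as.integer(w$df),
       converged = fit_full$converged,
       note = if (test_type == "lrt") note else NA_character_)
}

degenerate_component <- function(note) {
  list(stat = 0, df = 0L, converged = TRUE, note = note)
}

#' Fit the two-part hurdle test for one gene
#'
#' Models expression in two parts on `log(x + 1)`-transformed values: a
#' logistic regression of the expression indicator (value > 0) on the
#' predictor, and a Gaussian regression of the transformed level on the
#' predictor using only the expressing cells. With `random_effects = TRUE`
#' (the recommended analysis) both parts carry a normally distributed
#' random intercept per individual, absorbing the within-individual
#' correlation; with `FALSE` cells are treated as independent units (the
#' naive analysis whose power and type-1 error are inflated on nested
#' data). Component statistics and degrees of freedom are summed into a
#' single chi-squared test via [combine_components()].
#'
#' The mixed logistic part is fitted on per-individual binomial aggregates
#' whenever the predictor is constant within individuals (always true for
#' group labels and individual-level phenotypes), which is likelihood-
#' equivalent to the cell-level fit and much faster. Degenerate components
#' — an all-zero gene, an all-expressed gene (uninformative indicator), or
#' a conditional part with too few expressing cells or no predictor
#' contrast — contribute statistic 0 with 0 degrees of freedom and are
#' flagged. When a likelihood-ratio refit fails, the component falls back
#' to a Wald test and records it.
#'
#' @param gene_values Non-negative expression values, one per cell.
#' @param predictor Group label (factor/character with >= 2 levels) or
#'   numeric phenotype, one per cell.
#' @param individual_of_cell Individual id per cell.
#' @param random_effects Include a per-individual random intercept in both
#'   components (default `TRUE`).
#' @param test_type `"lrt"` (default) or `"wald"`.
#' @param nAGQ Quadrature points for the mixed logistic likelihood.
#' @param keep_fits Keep the fitted full-model objects of both components
#'   (for inspection or validation against an external likelihood).
#' @return A `hurdle_fit` object with component statistics, degrees of
#'   freedom, the combined statistic and p-value, convergence flags and
#'   notes.
#' @export
fit_hurdle <- function(gene_values, predictor, individual_of_cell,
                       random_effects = TRUE, test_type = c("lrt", "wald"),
                       nAGQ = 10, keep_fits = FALSE) {
  test_type <- match.arg(test_type)
  if (any(gene_values < 0)) abort("`gene_values` must be non-negative.")
  n <- length(gene_values)
  stopifnot(length(predictor) == n, length(individual_of_cell) == n)
  if (is.character(predictor) || is.logical(predictor)) {
    predictor <- factor(predictor)
  }
  if (is.factor(predictor)) {
    predictor <- droplevels(predictor)
    if (nlevels(predictor) < 2) abort("`predictor` needs at least 2 levels.")
  } else if (sd(predictor) == 0) {
    abort("`predictor` must not be constant.")
  }
  ind <- factor(individual_of_cell)
  if (random_effects && nlevels(ind) < 2) {
    abort("Random effects need at least 2 individuals.")
  }

  z <- gene_values > 0
  notes <- character(0)
  fit_d <- fit_c <- NULL

  if (!any(z)) {
    disc <- degenerate_component("all_zero")
    cont <- degenerate_component("all_zero")
  } else {
    # --- discrete part -----------------------------------------------------
    if (all(z)) {
      disc <- degenerate_component("all_expressed")
    } else {
      pred_by_ind <- tapply(as.numeric(unclass(predictor)), ind, function(v) v[1])
      constant_within <- all(tapply(as.numeric(unclass(predictor)), ind,
                                    function(v) length(unique(v)) == 1))
      if (random_effects && constant_within) {
        agg <- data.frame(
          ind = factor(names(pred_by_ind), levels = levels(ind)),
          nz = as.vector(tapply(z, ind, sum)),
          ntot = as.vector(tapply(z, ind, length)))
        agg$pred <- if (is.factor(predictor)) {
          factor(levels(predictor)[pred_by_ind], levels = levels(predictor))
        } else as.numeric(pred_by_ind)
        full <- quiet_fit(lme4::glmer(
          cbind(nz, ntot - nz) ~ pred + (1 | ind), data = agg,
          family = binomial(), nAGQ = nAGQ))
        if (!full$error) fit_d <- full$fit
        disc <- component_test(full, function() lme4::glmer(
          cbind(nz, ntot - nz) ~ 1 + (1 | ind), data = agg,
          family = binomial(), nAGQ = nAGQ), test_type)
      } else if (random_effects) {
        d <- data.frame(z = z, pred = predictor, ind = ind)
        full <- quiet_fit(lme4::glmer(z ~ pred + (1 | ind), data = d,
                                      family = binomial(), nAGQ = nAGQ))
        if (!full$error) fit_d <- full$fit
        disc <- component_test(full, function() lme4::glmer(
          z ~ 1 + (1 | ind), data = d, family = binomial(), nAGQ = nAGQ),
          test_type)
      } else {
        d <- data.frame(z = z, pred = predictor)
        full <- quiet_fit(glm(z ~ pred, data = d, family = binomial()))
        if (!full$error) fit_d <- full$fit
        disc <- component_test(full, function() glm(z ~ 1, data = d,
                                                    family = binomial()),
                               test_type)
      }
    }

    # --- continuous part ---------------------------------------------------
    dnz <- data.frame(ly = log1_transform(gene_values[z]),
                      pred = if (is.factor(predictor)) droplevels(predictor[z]) else predictor[z],
                      ind = droplevels(ind[z]))
    no_contrast <- if (is.factor(dnz$pred)) nlevels(dnz$pred) < 2 else sd(dnz$pred) == 0
    if (nrow(dnz) < 3 || no_contrast) {
      cont <- degenerate_component("conditional_degenerate")
    } else if (random_effects && nlevels(dnz$ind) >= 2) {
      full <- quiet_fit(lme4::lmer(ly ~ pred + (1 | ind), data = dnz,
                                   REML = FALSE))
      if (!full$error) fit_c <- full$fit
      cont <- component_test(full, function() lme4::lmer(
        ly ~ 1 + (1 | ind), data = dnz, REML = FALSE), test_type)
    } else {
      if (random_effects) notes <- c(notes, "continuous_single_individual_lm")
      full <- quiet_fit(lm(ly ~ pred, data = dnz))
      if (!full$error) fit_c <- full$fit
      cont <- component_test(full, function() lm(ly ~ 1, data = dnz),
                             test_type)
    }
  }

  comb <- combine_components(disc$stat, disc$df, cont$stat, cont$df)
  structure(list(
    stat_discrete = disc$stat, df_discrete = disc$df,
    stat_continuous = cont$stat, df_continuous = cont$df,
    stat_combined = comb$stat, df_combined = comb$df, p_value = comb$p,
    converged = c(discrete = disc$converged, continuous = cont$converged),
    notes = c(discrete = disc$note, continuous = cont$note,
              if (length(notes)) setNames(notes, rep("extra", length(notes)))),
    test_type = test_type, random_effects = random_effects,
    fits = if (keep_fits) list(discrete = fit_d, continuous = fit_c)),
    class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("<hurdle_fit> %s, %s random effects\n", toupper(x$test_type),
              if (x$random_effects) "with" else "without"))
  cat(sprintf("  discrete:   stat %.4g, df %d\n", x$stat_discrete, x$df_discrete))
  cat(sprintf("  continuous: stat %.4g, df %d\n", x$stat_continuous, x$df_continuous))
  cat(sprintf("  combined:   stat %.4g, df %d, p = %.4g\n",
              x$stat_combined, x$df_combined, x$p_value))
  invisible(x)
}

#' Tidy a hurdle fit
#'
#' @param x A `hurdle_fit`.
#' @param ... Unused.
#' @return `tidy()` gives one row per component plus the combined test;
#'   `glance()` a one-row summary.
#' @method tidy hurdle_fit
#' @export
tidy.hurdle_fit <- function(x, ...) {
  tibble(
    component = c("discrete", "continuous", "combined"),
    statistic = c(x$stat_discrete, x$stat_continuous, x$stat_combined),
    df = c(x$df_discrete, x$df_continuous, x$df_combined),
    p.value = c(NA_real_, NA_real_, x$p_value),
    converged = c(x$converged[["discrete"]], x$converged[["continuous"]],
                  all(x$converged))
  )
}

#' @rdname tidy.hurdle_fit
#' @method glance hurdle_fit
#' @export
glance.hurdle_fit <- function(x, ...) {
  tibble(statistic = x$stat_combined, df = x$df_combined,
         p.value = x$p_value, converged = all(x$converged),
         test_type = x$test_type, random_effects = x$random_effects)
}

#' Pseudo-bulk differential-expression test for one gene
#'
#' Collapses each individual's cells to a single aggregate of the
#' `log(x + 1)` values (by default their mean, zeros included) and tests at
#' the individual level: a Welch two-sample t-test for binary designs, a
#' Pearson correlation test against the phenotype for continuous designs.
#' Aggregating first makes the individual the unit of analysis, which is
#' why pseudo-bulk retains nominal type-1 error on nested data.
#'
#' @param gene_values Non-negative expression values, one per cell.
#' @param predictor Group label per cell (binary) or numeric phenotype per
#'   cell (continuous).
#' @param individual_of_cell Individual id per cell.
#' @param aggregate `"mean_log"` (mean of log1p values, default),
#'   `"log_mean"` (log1p of the mean count) or `"nonzero_mean"` (mean of
#'   log1p over expressing cells only).
#' @return A list with `statistic`, `p`, `df` where applicable, and the
#'   per-individual aggregates.
#' @export
pseudobulk_test <- function(gene_values, predictor, individual_of_cell,
                            aggregate = c("mean_log", "log_mean", "nonzero_mean")) {
  aggregate <- match.arg(aggregate)
  if (any(gene_values < 0)) abort("`gene_values` must be non-negative.")
  binary <- is.character(predictor) || is.factor(predictor) || is.logical(predictor)
  if (binary) predictor <- as.character(predictor)
  ind <- factor(individual_of_cell)
  agg_fun <- switch(aggregate,
    mean_log = function(v) mean(log1p(v)),
    log_mean = function(v) log1p(mean(v)),
    nonzero_mean = function(v) if (any(v > 0)) mean(log1p(v[v > 0])) else 0)
  agg <- as.vector(tapply(gene_values, ind, agg_fun))
  pred_ind <- tapply(predictor, ind, function(v) v[1])

  if (binary) {
    grp <- factor(as.vector(unlist(pred_ind)))
    if (nlevels(grp) != 2 || min(table(grp)) < 2) {
      abort("Binary pseudo-bulk needs two groups with >= 2 individuals each.")
    }
    a <- agg[grp == levels(grp)[1]]
    b <- agg[grp == levels(grp)[2]]
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) {
      # both groups constant: infinite t when means differ, no evidence when equal
      equal <- isTRUE(all.equal(mean(a), mean(b)))
      return(list(statistic = if (equal) 0 else Inf,
                  p = if (equal) 1 else 0, df = NA_real_,
                  aggregates = agg, method = "welch_t"))
    }
    list(statistic = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), aggregates = agg, method = "welch_t")
  } else {
    ph <- as.numeric(pred_ind)
    if (length(agg) < 3) abort("Continuous pseudo-bulk needs >= 3 individuals.")
    ct <- tryCatch(cor.test(agg, ph), error = function(e) NULL)
    if (is.null(ct)) {
      return(list(statistic = 0, p = 1, df = NA_real_,
                  aggregates = agg, method = "pearson_cor"))
    }
    list(statistic = unname(ct$statistic), p = ct$p.value,
         df = unname(ct$parameter), aggregates = agg, method = "pearson_cor")
  }
}

#' Test every gene of a simulated dataset
#'
#' Applies one of the three analyses gene by gene: the two-part hurdle with
#' per-individual random intercepts (`"hurdle_mixed"`, recommended), the
#' cells-as-independent hurdle (`"hurdle_naive"`), or individual-level
#' aggregation (`"pseudobulk"`).
#'
#' @param dataset A `sim_dataset`.
#' @param method Analysis method.
#' @param test_type `"lrt"` or `"wald"` (hurdle methods).
#' @return A tibble with one row per gene: component statistics and degrees
#'   of freedom (hurdle methods), the combined statistic, p-value and
#'   convergence flag.
#' @export
test_genes <- function(dataset,
                       method = c("hurdle_mixed", "hurdle_naive", "pseudobulk"),
                       test_type = "lrt") {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "sim_dataset"))
  pred <- unname(dataset$phenotype_of_individual[dataset$individual_of_cell])
  ind <- dataset$individual_of_cell
  g <- nrow(dataset$counts)
  rows <- vector("list", g)
  for (i in seq_len(g)) {
    v <- dataset$counts[i, ]
    if (method == "pseudobulk") {
      r <- pseudobulk_test(v, pred, ind)
      rows[[i]] <- tibble(gene_id = rownames(dataset$counts)[i],
                          stat_d = NA_real_, df_d = NA_integer_,
                          stat_c = NA_real_, df_c = NA_integer_,
                          stat = r$statistic, df = r$df, p = r$p,
                          converged = TRUE)
    } else {
      f <- fit_hurdle(v, pred, ind,
                      random_effects = method == "hurdle_mixed",
                      test_type = test_type)
      rows[[i]] <- tibble(gene_id = rownames(dataset$counts)[i],
                          stat_d = f$stat_discrete, df_d = f$df_discrete,
                          stat_c = f$stat_continuous, df_c = f$df_continuous,
                          stat = f$stat_combined, df = f$df_combined,
                          p = f$p_value, converged = all(f$converged))
    }
  }
  dplyr::bind_rows(rows)
}
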