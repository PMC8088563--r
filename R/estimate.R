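#' Prune a gene set down to mutually weakly-correlated genes
#'
#' Estimation of the generative model assumes independent genes, so pilot
#' data are first reduced to a subset in which no pair of genes has a
#' Spearman rank correlation above `threshold`. Genes are visited in a
#' seeded random order; each visited survivor removes every not-yet-visited
#' gene whose Spearman correlation with it exceeds the threshold. Ties are
#' handled with the midrank convention; genes with constant expression have
#' no defined rank correlation and are never removed on that account.
#'
#' @param x An [expr_matrix()] with at least two genes.
#' @param threshold Correlation cutoff in (0, 1]; the default 0.25 keeps the
#'   surviving set close to pairwise independence while retaining enough
#'   genes to fit the model trends.
#' @param seed Optional integer seed fixing the visiting order.
#' @return The surviving `expr_matrix`; the visit order seed and threshold
#'   are attached as attributes `prune_seed` and `prune_threshold`.
#' @export
prune_correlated_genes <- function(x, threshold = 0.25, seed = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is_number(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single number in (0, 1].")
  }
  g <- n_genes(x)
  if (g < 2) abort("Pruning needs at least two genes.")
  local_seed(seed)
  ord <- sample.int(g)
  rho <- suppressWarnings(cor(t(x$values), method = "spearman"))
  alive <- rep(TRUE, g)
  visited <- rep(FALSE, g)
  for (i in ord) {
    if (!alive[i]) next
    visited[i] <- TRUE
    victims <- which(alive & !visited & rho[i, ] > threshold)
    alive[victims] <- FALSE
  }
  out <- subset_genes(x, which(alive))
  attr(out, "prune_threshold") <- threshold
  attr(out, "prune_seed") <- seed
  out
}

#' Estimate per-gene grand means by one-cell-per-individual resampling
#'
#' The grand mean of a gene is its expected expression across individuals.
#' Averaging over all cells would weight individuals by their cell counts
#' and entangle the estimate with the within-individual correlation, so
#' instead one cell is sampled uniformly from each individual, the gene's
#' values are averaged across those cells, and the procedure is repeated;
#' the mean of the replicate means is returned. The same sampled cell
#' indices are reused across genes within a replicate.
#'
#' Note the resampled mean includes zeros, so for a gene subject to dropout
#' it estimates the *observed* mean, deflated by a factor of one minus the
#' dropout probability relative to the latent (pre-dropout) mean;
#' [estimate_gene_params()] applies that correction.
#'
#' @param x An [expr_matrix()].
#' @param n_resamples Number of resampling replicates (default 1000).
#' @param seed Optional integer seed.
#' @return Named numeric vector of per-gene grand means.
#' @export
estimate_grand_means <- function(x, n_resamples = 1000, seed = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!is_count(n_resamples)) abort("`n_resamples` must be a positive integer.")
  local_seed(seed)
  cells_by_ind <- split(seq_len(n_cells(x)), x$individual_of_cell)
  acc <- numeric(n_genes(x))
  for (r in seq_len(n_resamples)) {
    idx <- vapply(cells_by_ind,
                  function(ix) ix[sample.int(length(ix), 1L)], integer(1))
    acc <- acc + rowMeans(x$values[, idx, drop = FALSE])
  }
  setNames(acc / n_resamples, x$gene_ids)
}

# Per-individual summaries of the non-zero values of every gene: counts,
# means and (n-1)-denominator variances. Matrices are genes x individuals
# with NA where fewer than 1 (means) or 2 (variances) non-zero cells exist.
indiv_nonzero_stats <- function(x) {
  ids <- individuals(x)
  g <- n_genes(x)
  n_nz <- m_nz <- v_nz <- matrix(NA_real_, g, length(ids),
                                 dimnames = list(x$gene_ids, ids))
  for (j in seq_along(ids)) {
    sub <- x$values[, x$individual_of_cell == ids[j], drop = FALSE]
    n <- rowSums(sub > 0)
    s <- rowSums(sub)
    ss <- rowSums(sub^2)
    m <- ifelse(n > 0, s / n, NA_real_)
    v <- ifelse(n > 1, pmax(ss - n * m^2, 0) / (n - 1), NA_real_)
    n_nz[, j] <- n
    m_nz[, j] <- m
    v_nz[, j] <- v
  }
  list(n = n_nz, mean = m_nz, var = v_nz)
}

#' Estimate the inter-individual variance of each gene
#'
#' For each gene, the mean of the non-zero values is computed within each
#' individual, and the sample variance (denominator J' - 1) of those means
#' is taken over the J' individuals with at least one non-zero cell. Genes
#' with fewer than two qualifying individuals get `NA` and are excluded
#' from the mean-variance trend fit.
#'
#' @param x An [expr_matrix()].
#' @return Named numeric vector of per-gene variances (`NA` when undefined).
#' @export
estimate_inter_individual_variance <- function(x) {
  st <- indiv_nonzero_stats(x)
  m <- st$mean
  k <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- ifelse(k >= 2, ss / (k - 1), NA_real_)
  setNames(out, x$gene_ids)
}

#' Negative-binomial dispersion from within-individual moments
#'
#' Converts a within-individual mean and variance of non-zero expression
#' values into the negative-binomial size parameter by moment matching:
#' `size = mean^2 / (variance - mean)` when the variance exceeds the mean.
#' At or below the Poisson boundary (variance less than or equal to the mean)
#' there is no excess dispersion and the Poisson-limit cap `size_max` is
#' returned, with attribute `capped` flagging those entries.
#'
#' @param within_mean,within_var Positive numerics (vectorized), computed
#'   from non-zero values only.
#' @param size_max Cap representing the Poisson limit (default `1e6`).
#' @return Numeric vector of size parameters with logical attribute
#'   `capped`.
#' @export
estimate_dispersion <- function(within_mean, within_var, size_max = 1e6) {
  if (any(!is.finite(within_mean)) || any(!is.finite(within_var)) ||
      any(within_mean <= 0) || any(within_var <= 0)) {
    abort("`within_mean` and `within_var` must be positive and finite.")
  }
  capped <- within_var <= within_mean
  size <- ifelse(capped, size_max,
                 pmin(within_mean^2 / (within_var - within_mean), size_max))
  attr(size, "capped") <- capped
  size
}

#' Per-gene dropout rates
#'
#' The dropout rate of a gene is the proportion of cells in which it is
#' observed at exactly zero. In data generated under the package's model
#' this pools true dropout zeros with (typically rare) negative-binomial
#' zeros; the two are not distinguished.
#'
#' @param x An [expr_matrix()].
#' @return Named numeric vector in \[0, 1\].
#' @export
estimate_dropout_rates <- function(x) {
  setNames(rowMeans(x$values == 0), x$gene_ids)
}

#' Per-gene parameter table for model fitting
#'
#' Runs the per-gene estimators over an expression matrix and assembles the
#' table consumed by [fit_model()]: dropout rate, raw (observed-scale) and
#' dropout-corrected grand mean, inter-individual variance of non-zero
#' means, and a pooled within-individual negative-binomial dispersion.
#'
#' The dropout correction divides the resampled grand mean by one minus the
#' gene's dropout rate. Without it the grand-mean distribution and both
#' trend fits would describe the zero-inflated observed scale while the
#' simulator applies dropout on top of latent negative-binomial draws, and
#' the estimate-simulate loop would not be self-consistent.
#'
#' The inter-individual variance column is reported twice: `inter_indiv_var`
#' is the plain sample variance of the per-individual non-zero means, and
#' `inter_indiv_var_adj` subtracts the average sampling noise of those means
#' (the mean of `within_var_j / n_j` over qualifying individuals, the
#' standard one-way method-of-moments correction, floored at zero). The
#' plain variance systematically exceeds the latent between-individual
#' variance because each mean is estimated from finitely many cells; the
#' adjusted column is what [fit_model()] regresses on the grand mean, so
#' that the fitted `f1` trend describes the latent variance the simulator
#' consumes.
#'
#' The pooled dispersion combines evidence across individuals: with
#' per-individual non-zero moments, the excess variance satisfies
#' `E[var_j - mean_j] = mean_j^2 / size`, so the inverse size is estimated
#' as the weighted ratio `sum(w_j (var_j - mean_j)) / sum(w_j mean_j^2)`
#' with `w_j = n_j - 1`. The ratio-of-sums form keeps the estimator stable
#' where per-individual moment ratios would be wild.
#'
#' @param x An [expr_matrix()].
#' @param n_resamples Resampling replicates for the grand means.
#' @param seed Optional integer seed (grand-mean resampling only).
#' @param size_max Poisson-limit dispersion cap.
#' @return A tibble with one row per gene.
#' @export
estimate_gene_params <- function(x, n_resamples = 1000, seed = NULL,
                                 size_max = 1e6) {
  dropout <- estimate_dropout_rates(x)
  gm_raw <- estimate_grand_means(x, n_resamples = n_resamples, seed = seed)
  gm <- ifelse(dropout < 1, gm_raw / (1 - dropout), NA_real_)
  st <- indiv_nonzero_stats(x)
  iv <- estimate_inter_individual_variance(x)
  # average sampling variance of the per-individual means, over the
  # individuals where it is estimable
  noise <- rowMeans(st$var / st$n, na.rm = TRUE)
  iv_adj <- ifelse(is.na(iv), NA_real_,
                   pmax(0, iv - ifelse(is.finite(noise), noise, 0)))

  w <- pmax(st$n - 1, 0)
  w[is.na(st$var)] <- 0
  excess <- st$var - st$mean
  num <- rowSums(w * excess, na.rm = TRUE)
  den <- rowSums(w * st$mean^2, na.rm = TRUE)
  n_disp <- rowSums(w > 0)
  phi <- ifelse(den > 0, num / den, NA_real_)
  size <- ifelse(is.na(phi), NA_real_,
                 ifelse(phi > 1 / size_max, 1 / phi, size_max))

  tibble(
    gene_id = x$gene_ids,
    dropout_rate = unname(dropout),
    grand_mean_raw = unname(gm_raw),
    grand_mean = unname(gm),
    inter_indiv_var = unname(iv),
    inter_indiv_var_adj = unname(iv_adj),
    n_indiv_expressed = rowSums(!is.na(st$mean)),
    disp_size = unname(size),
    disp_capped = !is.na(size) & size >= size_max,
    n_indiv_disp = n_disp
  )
}

#' Per-gene, per-individual within-sample summaries
#'
#' Long-format companion to [estimate_gene_params()]: for every gene and
#' individual, the number of non-zero cells, the mean and variance of the
#' non-zero values, and the moment-matched dispersion where defined.
#'
#' @inheritParams estimate_gene_params
#' @return A tibble with one row per gene-individual pair.
#' @export
gene_within_stats <- function(x, size_max = 1e6) {
  st <- indiv_nonzero_stats(x)
  long <- tibble(
    gene_id = rep(rownames(st$mean), times = ncol(st$mean)),
    individual_id = rep(colnames(st$mean), each = nrow(st$mean)),
    n_nonzero = as.vector(st$n),
    within_mean = as.vector(st$mean),
    within_var = as.vector(st$var)
  )
  ok <- !is.na(long$within_mean) & !is.na(long$within_var) &
    long$within_mean > 0 & long$within_var > 0
  long$dispersion <- NA_real_
  if (any(ok)) {
    long$dispersion[ok] <- as.numeric(
      estimate_dispersion(long$within_mean[ok], long$within_var[ok],
                          size_max = size_max))
  }
  long
}

new_sim_model <- function(grand_mean_gamma, f1, f2, dropout_gamma,
                          size_min = 1e-4, size_max = 1e6,
                          provenance = list()) {
  m <- structure(
    list(grand_mean_gamma = c(shape = unname(grand_mean_gamma[1]),
                              rate = unname(grand_mean_gamma[2])),
         f1 = c(intercept = unname(f1[1]), slope = unname(f1[2])),
         f2 = c(intercept = unname(f2[1]), slope = unname(f2[2])),
         dropout_gamma = c(shape = unname(dropout_gamma[1]),
                           rate = unname(dropout_gamma[2])),
         size_min = size_min, size_max = size_max,
         provenance = provenance),
    class = "sim_model")
  if (any(!is.finite(m$grand_mean_gamma)) || any(m$grand_mean_gamma <= 0) ||
      any(!is.finite(m$dropout_gamma)) || any(m$dropout_gamma <= 0)) {
    abort("Gamma shapes and rates must be positive and finite.")
  }
  m
}

# Weighted linear fit of inter-individual variance on the grand mean with a
# correction for zero-truncation of the individual means. Individuals whose
# latent mean clamps at zero contribute only zero cells and silently leave
# the set of qualifying (non-zero-mean) individuals, so for low-expressed
# genes the observed quantities are those of a lower-truncated normal: the
# estimated grand mean converges to mu + sd * lambda(r) and the observed
# between-individual variance to sd^2 * (1 - r*lambda(r) - lambda(r)^2),
# with r = mu/sd and lambda the inverse Mills ratio. The fit alternates
# between (i) inverting the truncated-mean map per gene to recover the
# latent grand mean and (ii) refitting the weighted line on the
# de-truncated responses. Genes with very high dropout or r < 0.3 carry
# little reliable information about the latent variance and are excluded.
fit_f1_truncation <- function(mu_obs, iv, dropout, n_iter = 15) {
  q <- dropout <= 0.9
  if (sum(q) < 2 || length(unique(mu_obs[q])) < 2) q <- rep(TRUE, length(mu_obs))
  co <- coef(lm(iv[q] ~ mu_obs[q]))
  if (anyNA(co)) abort("Degenerate inputs: cannot fit the f1 trend.")
  for (it in seq_len(n_iter)) {
    mu <- mu_obs
    for (s in 1:25) {
      sdv <- sqrt(pmax(co[1] + co[2] * mu, 1e-8))
      r <- mu / sdv
      lam <- stats::dnorm(r) / stats::pnorm(r)
      mu <- pmax(mu_obs - sdv * lam, 1e-8)
    }
    sdv <- sqrt(pmax(co[1] + co[2] * mu, 1e-8))
    r <- mu / sdv
    lam <- stats::dnorm(r) / stats::pnorm(r)
    k <- pmax(1 - r * lam - lam^2, 0.05)
    keep <- q & r >= 0.3
    if (sum(keep) < 2 || length(unique(mu[keep])) < 2) keep <- q
    pred <- pmax(co[1] + co[2] * mu, 1)
    co <- coef(lm((iv / k)[keep] ~ mu[keep], weights = (1 / pred^2)[keep]))
    if (anyNA(co)) abort("Degenerate inputs: cannot fit the f1 trend.")
  }
  co
}

#' Fit the simulation model hyper-distributions
#'
#' Takes the per-gene parameter table and fits the four components that
#' drive simulation: a gamma distribution (maximum likelihood) for the
#' grand means; `f1`, a line relating inter-individual variance to the
#' grand mean; `f2`, a logarithmic trend for the negative-binomial size;
#' and a gamma distribution (maximum likelihood, samples truncated to
#' \[0, 1\] at simulation time) for the dropout rates. Genes with undefined
#' components are excluded per fit; Poisson-capped dispersions are excluded
#' from the `f2` regression so the cap does not distort the trend. Dropout
#' rates of exactly 0 or 1 are moved inward by 1e-6 for the gamma
#' likelihood.
#'
#' Two refinements keep the fits consistent with the generative model.
#' First, the default `f1` fit corrects for zero-truncation of the
#' individual means: because a gene whose latent individual mean clamps at
#' zero loses that individual from the non-zero summaries, the observed
#' between-individual variance of low-expressed genes is that of a
#' lower-truncated normal; a plain least-squares line is therefore biased
#' and the default iterative fit divides out the closed-form truncation
#' factor (set `f1_method = "ols"` for the uncorrected line). Second, `f2`
#' is fitted on the inverse-size (excess-dispersion) scale, where the
#' pooled per-gene estimator is nearly unbiased, using a Gamma generalized
#' linear model with the canonical inverse link, which is exactly the model
#' `1/size = 1/(a + b log(mu))`; fitting sizes directly would propagate the
#' inverse-estimator bias into the trend.
#'
#' @param params Tibble from [estimate_gene_params()] (at least 30 genes
#'   with defined positive grand means).
#' @param size_min,size_max Clamps applied to `f2` predictions at
#'   simulation time.
#' @param f1_method `"truncation_adjusted"` (default) or `"ols"`.
#' @param provenance Optional list describing the data source, pruning
#'   threshold and seeds; stored verbatim in the model.
#' @return A `sim_model` object.
#' @export
fit_model <- function(params, size_min = 1e-4, size_max = 1e6,
                      f1_method = c("truncation_adjusted", "ols"),
                      provenance = list()) {
  f1_method <- match.arg(f1_method)
  gm <- params$grand_mean
  ok_gm <- !is.na(gm) & gm > 0
  if (sum(ok_gm) < 30) {
    abort(sprintf("Need at least 30 genes with positive grand means; have %d.",
                  sum(ok_gm)))
  }
  if (sd(gm[ok_gm]) == 0) {
    abort("Grand means are constant; a gamma distribution cannot be fitted.")
  }
  gam <- fitdistrplus::fitdist(gm[ok_gm], "gamma", method = "mle",
                               lower = c(1e-8, 1e-8))$estimate

  iv <- params$inter_indiv_var_adj %||% params$inter_indiv_var
  ok_f1 <- ok_gm & !is.na(iv)
  if (length(unique(gm[ok_f1])) < 2) {
    abort("Fewer than 2 distinct grand means with defined inter-individual variance; cannot fit f1.")
  }
  f1_coef <- if (f1_method == "ols") {
    coef(lm(iv[ok_f1] ~ gm[ok_f1]))
  } else {
    fit_f1_truncation(gm[ok_f1], iv[ok_f1], params$dropout_rate[ok_f1])
  }

  ok_f2 <- ok_gm & !is.na(params$disp_size) & !params$disp_capped &
    params$disp_size > size_min
  if (length(unique(gm[ok_f2])) < 2) {
    abort("Fewer than 2 distinct grand means with defined dispersion; cannot fit f2.")
  }
  phi <- 1 / params$disp_size[ok_f2]
  logmu <- log(gm[ok_f2])
  f2_coef <- tryCatch(
    coef(suppressWarnings(glm(phi ~ logmu,
                              family = stats::Gamma(link = "inverse")))),
    error = function(e) coef(lm(params$disp_size[ok_f2] ~ logmu)))

  dr <- pmin(pmax(params$dropout_rate, 1e-6), 1 - 1e-6)
  drop_gam <- fitdistrplus::fitdist(dr, "gamma", method = "mle",
                                    lower = c(1e-8, 1e-8))$estimate

  provenance$n_genes_used <- list(
    gamma = sum(ok_gm), f1 = sum(ok_f1), f2 = sum(ok_f2),
    dropout = length(dr))
  new_sim_model(
    grand_mean_gamma = gam,
    f1 = f1_coef,
    f2 = f2_coef,
    dropout_gamma = drop_gam,
    size_min = size_min, size_max = size_max,
    provenance = provenance)
}

#' One-call estimation pipeline
#'
#' Convenience wrapper running [prune_correlated_genes()],
#' [estimate_gene_params()] and [fit_model()] in sequence on pilot data.
#'
#' @param x An [expr_matrix()] of pilot data.
#' @param prune Whether to prune correlated genes first (default `TRUE`).
#' @param threshold Spearman threshold for pruning.
#' @param n_resamples Grand-mean resampling replicates.
#' @param seed Integer seed covering the pruning order and the resampling.
#' @param ... Passed on to [fit_model()].
#' @return A `sim_model`.
#' @export
estimate_model <- function(x, prune = TRUE, threshold = 0.25,
                           n_resamples = 1000, seed = NULL, ...) {
  if (prune) x <- prune_correlated_genes(x, threshold = threshold, seed = seed)
  params <- estimate_gene_params(x, n_resamples = n_resamples, seed = seed)
  fit_model(params,
            provenance = list(source = "estimate_model",
                              prune_threshold = if (prune) threshold else NULL,
                              seed = seed),
            ...)
}

# --- model accessors used by the simulator ---------------------------------

#' Model-implied inter-individual variance and dispersion
#'
#' `model_indiv_variance()` evaluates the linear trend `f1` at a grand mean
#' and floors it at zero (a variance cannot be negative).
#' `model_dispersion_size()` evaluates the logarithmic trend `f2` and clamps
#' it to `[size_min, size_max]`.
#'
#' @param model A `sim_model`.
#' @param mu Non-negative grand mean(s).
#' @return Numeric vector.
#' @export
model_indiv_variance <- function(model, mu) {
  pmax(0, model$f1[["intercept"]] + model$f1[["slope"]] * mu)
}

#' @rdname model_indiv_variance
#' @export
model_dispersion_size <- function(model, mu) {
  s <- model$f2[["intercept"]] +
    model$f2[["slope"]] * log(pmax(mu, .Machine$double.xmin))
  pmin(pmax(s, model$size_min), model$size_max)
}

#' @export
print.sim_model <- function(x, ...) {
  cat("<sim_model>\n")
  cat(sprintf("  grand means ~ Gamma(shape = %.4g, rate = %.4g)\n",
              x$grand_mean_gamma[["shape"]], x$grand_mean_gamma[["rate"]]))
  cat(sprintf("  f1 (inter-individual variance): %.4g + %.4g * mu\n",
              x$f1[["intercept"]], x$f1[["slope"]]))
  cat(sprintf("  f2 (NB size): %.4g + %.4g * log(mu), clamped to [%g, %g]\n",
              x$f2[["intercept"]], x$f2[["slope"]], x$size_min, x$size_max))
  cat(sprintf("  dropout ~ Gamma(shape = %.4g, rate = %.4g) truncated to [0, 1]\n",
              x$dropout_gamma[["shape"]], x$dropout_gamma[["rate"]]))
  invisible(x)
}

#' Tidy a fitted simulation model
#'
#' @param x A `sim_model`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `term`, `estimate`.
#' @method tidy sim_model
#' @export
tidy.sim_model <- function(x, ...) {
  tibble(
    component = rep(c("grand_mean_gamma", "f1", "f2", "dropout_gamma"),
                    each = 2),
    term = c("shape", "rate", "intercept", "slope",
             "intercept", "slope", "shape", "rate"),
    estimate = unname(c(x$grand_mean_gamma, x$f1, x$f2, x$dropout_gamma))
  )
}

#' @rdname tidy.sim_model
#' @method glance sim_model
#' @export
glance.sim_model <- function(x, ...) {
  n <- x$provenance$n_genes_used
  tibble(
    mean_grand_mean = x$grand_mean_gamma[["shape"]] / x$grand_mean_gamma[["rate"]],
    mean_dropout = x$dropout_gamma[["shape"]] / x$dropout_gamma[["rate"]],
    size_min = x$size_min, size_max = x$size_max,
    n_genes_gamma = n$gamma %||% NA_integer_,
    n_genes_f1 = n$f1 %||% NA_integer_,
    n_genes_f2 = n$f2 %||% NA_integer_
  )
}

#' Serialize a simulation model to and from JSON
#'
#' @param model A `sim_model`.
#' @param path File path.
#' @return `write_model()` invisibly returns `path`; `read_model()` returns
#'   the `sim_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "sim_model"))
  jsonlite::write_json(
    list(grand_mean_gamma = as.list(model$grand_mean_gamma),
         f1 = as.list(model$f1),
         f2 = as.list(model$f2),
         dropout_gamma = as.list(model$dropout_gamma),
         size_min = model$size_min, size_max = model$size_max,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_sim_model(
    grand_mean_gamma = unlist(j$grand_mean_gamma),
    f1 = unlist(j$f1), f2 = unlist(j$f2),
    dropout_gamma = unlist(j$dropout_gamma),
    size_min = j$size_min, size_max = j$size_max,
    provenance = as.list(j$provenance))
}
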