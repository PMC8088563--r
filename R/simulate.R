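#' Describe a simulation design
#'
#' Bundles the user-facing knobs of a simulated experiment: how many genes,
#' what fraction carry an effect, the number of individuals (per group for a
#' binary phenotype), the expected number of cells per individual and how
#' that count varies, and the effect itself — a fold change for two-group
#' designs or a target correlation `rho` between a continuous phenotype and
#' individual-level expression.
#'
#' @param n_genes Number of genes to simulate.
#' @param frac_de Fraction of genes carrying the effect (default 1; power
#'   loops simulate genes one at a time).
#' @param phenotype `"binary"` or `"continuous"`.
#' @param n_per_group Individuals per group (binary designs).
#' @param n_individuals Total individuals (continuous designs).
#' @param cells_per_individual Expected cells per individual.
#' @param cell_count_mode `"fixed"`, `"poisson"` or `"negbin"` — constant
#'   cell counts, mild imbalance (Poisson with mean `cells_per_individual`),
#'   or strong imbalance (negative binomial with that mean and size 1).
#' @param fold_change Multiplicative effect on the grand mean in one group
#'   (binary; must be > 0; 1 means no effect).
#' @param rho Target correlation between phenotype and individual-level
#'   expression (continuous; in \[-1, 1\]).
#' @param phenotype_mean,phenotype_sd Continuous phenotype distribution
#'   (defaults 22 and 5, a plausible clinical measurement scale).
#' @param seed Integer root seed for the whole dataset.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_genes = 1000, frac_de = 1,
                       phenotype = c("binary", "continuous"),
                       n_per_group = 10, n_individuals = 20,
                       cells_per_individual = 100,
                       cell_count_mode = c("fixed", "poisson", "negbin"),
                       fold_change = 1, rho = 0,
                       phenotype_mean = 22, phenotype_sd = 5,
                       seed = NULL) {
  phenotype <- match.arg(phenotype)
  cell_count_mode <- match.arg(cell_count_mode)
  if (!is_count(n_genes)) abort("`n_genes` must be a positive integer.")
  stop_if_not_prob(frac_de, "frac_de")
  if (!is_number(fold_change) || fold_change <= 0) {
    abort("`fold_change` must be a single positive number.")
  }
  if (!is_number(rho) || abs(rho) > 1) abort("`rho` must lie in [-1, 1].")
  if (!is_count(cells_per_individual)) {
    abort("`cells_per_individual` must be a positive integer.")
  }
  if (phenotype == "binary" && !is_count(n_per_group)) {
    abort("`n_per_group` must be a positive integer.")
  }
  if (phenotype == "continuous") {
    if (!is_count(n_individuals)) abort("`n_individuals` must be a positive integer.")
    if (!is_number(phenotype_sd) || phenotype_sd <= 0) {
      abort("`phenotype_sd` must be positive.")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes), frac_de = frac_de, phenotype = phenotype,
    n_per_group = as.integer(n_per_group),
    n_individuals = as.integer(n_individuals),
    cells_per_individual = as.integer(cells_per_individual),
    cell_count_mode = cell_count_mode,
    fold_change = fold_change, rho = rho,
    phenotype_mean = phenotype_mean, phenotype_sd = phenotype_sd,
    seed = seed), class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  eff <- if (x$phenotype == "binary") {
    sprintf("fold change %.3g, %d individuals/group", x$fold_change, x$n_per_group)
  } else {
    sprintf("rho %.3g, %d individuals", x$rho, x$n_individuals)
  }
  cat(sprintf("<sim_design> %d genes (%.0f%% DE), %s phenotype, %s,\n  %d cells/individual (%s)\n",
              x$n_genes, 100 * x$frac_de, x$phenotype, eff,
              x$cells_per_individual, x$cell_count_mode))
  invisible(x)
}

#' Draw the number of cells per individual
#'
#' Three regimes: `fixed` gives every individual exactly `expected` cells;
#' `poisson` draws iid Poisson counts with mean `expected` (mild imbalance);
#' `negbin` draws iid negative-binomial counts with mean `expected` and
#' size 1 (strong imbalance). Draws of zero are redrawn — an individual
#' contributing no cells is unobservable and would break the mixed model.
#'
#' @param mode One of `"fixed"`, `"poisson"`, `"negbin"`.
#' @param expected Expected cells per individual (>= 1).
#' @param n_individuals Number of individuals.
#' @param seed Optional integer seed.
#' @return Integer vector of per-individual cell counts, all >= 1.
#' @export
draw_cells_per_individual <- function(mode = c("fixed", "poisson", "negbin"),
                                      expected, n_individuals, seed = NULL) {
  mode <- match.arg(mode)
  if (!is_count(expected)) abort("`expected` must be a positive integer.")
  if (!is_count(n_individuals)) abort("`n_individuals` must be a positive integer.")
  local_seed(seed)
  if (mode == "fixed") return(rep(as.integer(expected), n_individuals))
  draw <- function(n) {
    switch(mode,
           poisson = rpois(n, lambda = expected),
           negbin = rnbinom(n, mu = expected, size = 1))
  }
  out <- draw(n_individuals)
  while (any(out == 0)) out[out == 0] <- draw(sum(out == 0))
  as.integer(out)
}

#' Draw per-gene grand means from the fitted gamma distribution
#'
#' @param model A `sim_model`.
#' @param n_genes Number of genes.
#' @param seed Optional integer seed.
#' @return Positive numeric vector of grand means.
#' @export
draw_grand_means <- function(model, n_genes, seed = NULL) {
  local_seed(seed)
  rgamma(n_genes, shape = model$grand_mean_gamma[["shape"]],
         rate = model$grand_mean_gamma[["rate"]])
}

#' Apply a fold-change effect to grand means in a two-group design
#'
#' For each effect gene a Bernoulli(0.5) draw picks the group whose mean is
#' multiplied by `fold_change`; the other group keeps the unspiked mean, so
#' the direction of effect varies evenly between groups. Non-effect genes
#' have identical means in both groups.
#'
#' @param mu Per-gene grand means.
#' @param fold_change Positive multiplicative effect.
#' @param de_flags Logical vector marking effect genes.
#' @param seed Optional integer seed.
#' @return A list with `mean_group1`, `mean_group2`, `direction` (+1 when
#'   group 2 is spiked, -1 when group 1 is, 0 for non-effect genes) and
#'   `applied_effect` (the group-2 over group-1 mean ratio).
#' @export
apply_effect_binary <- function(mu, fold_change, de_flags, seed = NULL) {
  if (!is_number(fold_change) || fold_change <= 0) {
    abort("`fold_change` must be a single positive number.")
  }
  stopifnot(length(de_flags) == length(mu))
  local_seed(seed)
  direction <- integer(length(mu))
  direction[de_flags] <- ifelse(rbinom(sum(de_flags), 1, 0.5) == 1, 1L, -1L)
  m1 <- ifelse(de_flags & direction == -1L, mu * fold_change, mu)
  m2 <- ifelse(de_flags & direction == 1L, mu * fold_change, mu)
  list(mean_group1 = m1, mean_group2 = m2, direction = direction,
       applied_effect = ifelse(de_flags, fold_change^direction, 1))
}

#' Draw per-individual means around a grand mean
#'
#' A mean deviation is drawn for each individual from a normal distribution
#' with mean zero and variance `f1(mu)` (the model's inter-individual
#' variance trend evaluated at the grand mean, floored at zero) and added
#' to the grand mean. Results are truncated below at zero: a negative mean
#' cannot parameterize a count distribution.
#'
#' @param mu Grand mean (single value).
#' @param model A `sim_model`.
#' @param n_individuals Number of individuals.
#' @param seed Optional integer seed.
#' @return Numeric vector of non-negative individual means.
#' @export
draw_individual_means <- function(mu, model, n_individuals, seed = NULL) {
  local_seed(seed)
  v <- model_indiv_variance(model, mu)
  pmax(0, rnorm(n_individuals, mean = mu, sd = sqrt(v)))
}

#' Draw negative-binomial cell values
#'
#' Cell-level expression values for one gene in one individual: iid
#' negative-binomial draws with mean `mu_ij` and size `size`. A zero mean
#' yields all zeros.
#'
#' @param mu_ij Individual mean (>= 0).
#' @param size NB size parameter (> 0); at the Poisson-limit cap the draws
#'   are effectively Poisson.
#' @param n_cells Number of cells.
#' @param seed Optional integer seed.
#' @return Numeric vector of non-negative counts.
#' @export
draw_counts <- function(mu_ij, size, n_cells, seed = NULL) {
  stopifnot(mu_ij >= 0, size > 0)
  local_seed(seed)
  if (mu_ij == 0) return(numeric(n_cells))
  as.numeric(rnbinom(n_cells, mu = mu_ij, size = size))
}

#' Apply dropout to a count matrix
#'
#' Each entry is independently set to zero with its gene's dropout
#' probability; existing zeros are unchanged. Applied on top of the
#' negative-binomial sampling, so observed zeros are the union of NB zeros
#' and dropout zeros.
#'
#' @param counts Genes-by-cells numeric matrix.
#' @param dropout_rate Per-gene dropout probabilities in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Matrix of the same shape.
#' @export
apply_dropout <- function(counts, dropout_rate, seed = NULL) {
  counts <- as.matrix(counts)
  if (length(dropout_rate) == 1) dropout_rate <- rep(dropout_rate, nrow(counts))
  stopifnot(length(dropout_rate) == nrow(counts),
            all(dropout_rate >= 0), all(dropout_rate <= 1))
  local_seed(seed)
  # rbinom recycles the per-gene probabilities down each column
  keep <- matrix(rbinom(length(counts), 1L, 1 - dropout_rate),
                 nrow(counts), ncol(counts))
  counts * keep
}

# Rejection-sample per-gene dropout probabilities from the model's gamma,
# truncated to [0, 1].
draw_dropout_rates <- function(model, n, seed = NULL) {
  local_seed(seed)
  shape <- model$dropout_gamma[["shape"]]
  rate <- model$dropout_gamma[["rate"]]
  out <- numeric(0)
  for (tries in 1:1000) {
    s <- rgamma(n, shape = shape, rate = rate)
    out <- c(out, s[s <= 1])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  abort("Dropout gamma places almost no mass in [0, 1]; cannot sample rates.")
}

new_sim_dataset <- function(counts, individual_of_cell, phenotype_of_individual,
                            phenotype_type, de_flags, applied_effect, design) {
  structure(list(
    counts = counts,
    individual_of_cell = individual_of_cell,
    phenotype_of_individual = phenotype_of_individual,
    phenotype_type = phenotype_type,
    de_flags = de_flags,
    applied_effect = applied_effect,
    design = design), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genes x %d cells, %d individuals, %s phenotype, %d effect genes\n",
              nrow(x$counts), ncol(x$counts),
              length(x$phenotype_of_individual), x$phenotype_type,
              sum(x$de_flags)))
  invisible(x)
}

#' @export
cell_metadata.sim_dataset <- function(x) {
  tibble(cell_id = colnames(x$counts),
         individual_id = x$individual_of_cell,
         phenotype = unname(x$phenotype_of_individual[x$individual_of_cell]))
}

#' Per-gene ground truth of a simulated dataset
#'
#' @param x A `sim_dataset`.
#' @return A tibble with `gene_id`, `is_de` and `applied_effect` (the
#'   group-2/group-1 mean ratio for binary designs, the target correlation
#'   for continuous designs).
#' @export
gene_truth <- function(x) {
  tibble(gene_id = rownames(x$counts), is_de = x$de_flags,
         applied_effect = x$applied_effect)
}

#' Convert a simulated dataset to an expression matrix
#'
#' @param x A `sim_dataset`.
#' @return An [expr_matrix()] carrying the counts and individual labels.
#' @export
as_expr_matrix <- function(x) {
  stopifnot(inherits(x, "sim_dataset"))
  out <- expr_matrix(x$counts, x$individual_of_cell)
  out$phenotype_of_cell <- unname(x$phenotype_of_individual[x$individual_of_cell])
  out
}

# Shared scaffolding: cell counts, ids and column bookkeeping.
build_cells <- function(design, n_indiv, prefix = "ind") {
  ncells <- draw_cells_per_individual(design$cell_count_mode,
                                      design$cells_per_individual, n_indiv)
  ind_ids <- sprintf("%s%02d", prefix, seq_len(n_indiv))
  ind_of_cell <- rep(ind_ids, times = ncells)
  list(ncells = ncells, ind_ids = ind_ids, ind_of_cell = ind_of_cell,
       total = sum(ncells))
}

# Draw the count matrix given per-gene-by-individual means and per-gene,
# per-individual sizes, then mask with dropout. One column at a time keeps
# the memory bounded and the RNG order fixed.
draw_count_matrix <- function(mu_ind, size_by_ind, ncells) {
  g <- nrow(mu_ind)
  counts <- matrix(0, g, sum(ncells))
  col <- 0L
  for (j in seq_along(ncells)) {
    for (k in seq_len(ncells[j])) {
      col <- col + 1L
      counts[, col] <- rnbinom(g, mu = mu_ind[, j], size = size_by_ind[, j])
    }
  }
  counts
}

#' Simulate a hierarchical two-group single-cell experiment
#'
#' Composes the generative stages under one root seed: grand means are
#' drawn from the model's gamma; effect genes have one group's mean
#' multiplied by the fold change (direction Bernoulli(0.5)); individual
#' means are drawn around each group's mean with variance `f1` evaluated at
#' that (possibly spiked) mean; per-individual cell counts are drawn; cell
#' values come from a negative binomial with size `f2` evaluated at the
#' group mean; and a per-gene dropout mask is applied. All stages consume a
#' single RNG stream in fixed order, so a seed fully determines the dataset.
#'
#' @param design A [sim_design()] with `phenotype = "binary"`.
#' @param model A `sim_model`.
#' @param seed Root seed; defaults to `design$seed`.
#' @return A `sim_dataset`.
#' @export
simulate_binary <- function(design, model, seed = design$seed) {
  stopifnot(inherits(design, "sim_design"), inherits(model, "sim_model"))
  if (design$phenotype != "binary") abort("`design` must have a binary phenotype.")
  local_seed(seed)
  g <- design$n_genes
  n1 <- design$n_per_group
  J <- 2L * n1
  group_of_ind <- rep(c("group1", "group2"), each = n1)

  mu <- draw_grand_means(model, g)
  de <- seq_len(g) <= round(design$frac_de * g)
  eff <- apply_effect_binary(mu, design$fold_change, de)

  mean_by_ind <- cbind(matrix(eff$mean_group1, g, n1),
                       matrix(eff$mean_group2, g, n1))
  sd_by_ind <- sqrt(model_indiv_variance(model, mean_by_ind))
  mu_ind <- matrix(pmax(0, rnorm(g * J, mean = mean_by_ind, sd = sd_by_ind)), g, J)
  size_by_ind <- cbind(matrix(model_dispersion_size(model, eff$mean_group1), g, n1),
                       matrix(model_dispersion_size(model, eff$mean_group2), g, n1))

  cl <- build_cells(design, J)
  counts <- draw_count_matrix(mu_ind, size_by_ind, cl$ncells)
  drop_rate <- draw_dropout_rates(model, g)
  counts <- apply_dropout(counts, drop_rate)

  rownames(counts) <- paste0("gene", seq_len(g))
  colnames(counts) <- paste0("cell", seq_len(cl$total))
  new_sim_dataset(counts, cl$ind_of_cell,
                  setNames(group_of_ind, cl$ind_ids), "binary",
                  de, eff$applied_effect, design)
}

#' Simulate single-cell data correlated with a continuous phenotype
#'
#' Each individual receives a phenotype drawn from
#' `Normal(phenotype_mean, phenotype_sd^2)`. For effect genes the
#' individual-level mean deviation is built jointly with the standardized
#' phenotype: `deviation = sqrt(f1(mu)) * (rho * z + sqrt(1 - rho^2) * e)`
#' with `z` the standardized phenotype and `e` independent standard normal,
#' so the phenotype/individual-mean correlation targets `rho`. The
#' cell-level correlation is attenuated by within-individual noise; that is
#' a property of the data, not corrected for. Non-effect genes have zero
#' phenotype loading. Cells are then drawn and dropout applied as in
#' [simulate_binary()].
#'
#' @param design A [sim_design()] with `phenotype = "continuous"`.
#' @param model A `sim_model`.
#' @param seed Root seed; defaults to `design$seed`.
#' @return A `sim_dataset` with a numeric phenotype per individual.
#' @export
simulate_continuous <- function(design, model, seed = design$seed) {
  stopifnot(inherits(design, "sim_design"), inherits(model, "sim_model"))
  if (design$phenotype != "continuous") {
    abort("`design` must have a continuous phenotype.")
  }
  local_seed(seed)
  g <- design$n_genes
  J <- design$n_individuals

  pheno <- rnorm(J, design$phenotype_mean, design$phenotype_sd)
  z <- (pheno - design$phenotype_mean) / design$phenotype_sd

  mu <- draw_grand_means(model, g)
  de <- seq_len(g) <= round(design$frac_de * g)
  rho_g <- ifelse(de, design$rho, 0)

  sd_g <- sqrt(model_indiv_variance(model, mu))
  eps <- matrix(rnorm(g * J), g, J)
  zmat <- matrix(z, g, J, byrow = TRUE)
  dev <- sd_g * (rho_g * zmat + sqrt(1 - rho_g^2) * eps)
  mu_ind <- matrix(pmax(0, mu + dev), g, J)
  size_by_ind <- matrix(model_dispersion_size(model, mu), g, J)

  cl <- build_cells(design, J)
  counts <- draw_count_matrix(mu_ind, size_by_ind, cl$ncells)
  drop_rate <- draw_dropout_rates(model, g)
  counts <- apply_dropout(counts, drop_rate)

  rownames(counts) <- paste0("gene", seq_len(g))
  colnames(counts) <- paste0("cell", seq_len(cl$total))
  new_sim_dataset(counts, cl$ind_of_cell,
                  setNames(pheno, cl$ind_ids), "continuous",
                  de, rho_g, design)
}
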