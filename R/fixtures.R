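#' Default synthetic simulation model
#'
#' A fully specified `sim_model` with fixed constants chosen to
#' qualitatively mimic the structure of a moderately expressed gene panel
#' in plate-based (Smart-Seq2 style) single-cell TPM data from a
#' homogeneous cell population: right-skewed gene means (gamma with shape
#' 5, rate 0.05; mean 100 TPM, coefficient of variation 0.45 across genes),
#' inter-individual variance growing linearly with the mean (200 + 3 mu; a
#' between-individual coefficient of variation near 0.22 at 100 TPM),
#' negative-binomial size increasing with the log mean (-6 + 3 log(mu),
#' about 7.8 at 100 TPM; overdispersion decreasing with expression), and
#' per-gene dropout probabilities centred at 0.5 with standard deviation
#' about 0.18 (gamma with shape 8, rate 16, truncated to \[0, 1\]). These
#' are synthetic fixture constants, not estimates from any particular
#' dataset; every component is chosen to be identifiable from a pilot of a
#' few thousand genes and ten individuals, so the estimation pipeline can
#' be validated closed-loop against known ground truth.
#'
#' @return A `sim_model`.
#' @export
default_model <- function() {
  new_sim_model(
    grand_mean_gamma = c(shape = 5, rate = 0.05),
    f1 = c(intercept = 200, slope = 3),
    f2 = c(intercept = -6, slope = 3),
    dropout_gamma = c(shape = 8, rate = 16),
    provenance = list(source = "synthetic default (fixture constants)"))
}

#' Generate a pilot-like expression matrix with known ground truth
#'
#' Simulates a single-condition (no effect) hierarchical dataset under a
#' known `sim_model`, optionally appending blocks of rank-correlated genes
#' (scaled copies of a base gene, so their Spearman correlation is exactly
#' 1) to exercise [prune_correlated_genes()]. Because the generating model
#' is known, the full estimation pipeline can be validated closed-loop
#' against it.
#'
#' @param n_genes Number of independent genes.
#' @param n_individuals Number of individuals.
#' @param cells_per_individual Cells per individual (fixed).
#' @param model Generating `sim_model` (default [default_model()]).
#' @param n_correlated_blocks,block_size Optional duplicated-gene blocks:
#'   `n_correlated_blocks` base genes each appear in `block_size` scaled
#'   copies appended to the matrix.
#' @param seed Integer seed.
#' @return An [expr_matrix()].
#' @export
generate_pilot <- function(n_genes = 2000, n_individuals = 10,
                           cells_per_individual = 90,
                           model = default_model(),
                           n_correlated_blocks = 0, block_size = 0,
                           seed = NULL) {
  design <- sim_design(n_genes = n_genes, frac_de = 0,
                       phenotype = "continuous",
                       n_individuals = n_individuals,
                       cells_per_individual = cells_per_individual,
                       cell_count_mode = "fixed", rho = 0, seed = seed)
  sim <- simulate_continuous(design, model)
  x <- expr_matrix(sim$counts, sim$individual_of_cell)
  if (n_correlated_blocks > 0 && block_size > 1) {
    local_seed(if (is.null(seed)) NULL else seed + 1)
    base_idx <- sample.int(n_genes, n_correlated_blocks)
    extra <- list()
    for (b in seq_len(n_correlated_blocks)) {
      base <- x$values[base_idx[b], ]
      copies <- vapply(seq_len(block_size - 1),
                       function(k) base * (1 + k / 2), numeric(length(base)))
      block <- t(copies)
      rownames(block) <- sprintf("corr%d_copy%d", b, seq_len(block_size - 1))
      extra[[b]] <- block
    }
    values <- rbind(x$values, do.call(rbind, extra))
    x <- expr_matrix(values, x$individual_of_cell)
  }
  x
}

#' A hand-sized worked fixture with exact expected values
#'
#' Five genes by nine cells across three individuals (A, B, C; three cells
#' each), built so every per-gene estimator can be checked against hand
#' arithmetic. The returned `expected` list carries those hand-computed
#' values; they are frozen constants, never produced by the estimators
#' under test.
#'
#' The fixture values and the arithmetic behind each expectation:
#' \itemize{
#'   \item g1 `7 7 7 | 7 7 7 | 7 7 7`: no zeros; all non-zero means equal,
#'     so inter-individual variance 0; within-individual variance 0, so no
#'     dispersion is defined.
#'   \item g2 `0 2 4 | 0 3 9 | 6 0 12`: 3 zeros of 9 (dropout 1/3);
#'     non-zero means 3, 6, 9 with sample variance 9; per-individual cell
#'     means (zeros included) 2, 4, 6 so the exact one-cell-per-individual
#'     resampling expectation is 4; dispersion defined for B (mean 6,
#'     var 18, size 36/12 = 3) and C (mean 9, var 18, size 81/9 = 9), while
#'     A (mean 3, var 2) is at or below the Poisson boundary.
#'   \item g3 `1 2 3 | 2 4 6 | 3 6 9`: no zeros; non-zero means 2, 4, 6
#'     with variance 4; within variances 1, 4, 9; only C is overdispersed
#'     (size 36/3 = 12); resampling expectation (2 + 4 + 6)/3 = 4.
#'   \item g4 `0 0 5 | 0 5 5 | 5 5 5`: dropout 3/9; all non-zero means are
#'     5, so inter-individual variance 0; resampling expectation
#'     (5/3 + 10/3 + 5)/3 = 10/3.
#'   \item g5 `0 0 0 | 0 0 8 | 4 8 0`: dropout 6/9; only B (mean 8) and C
#'     (mean 6) qualify, variance of (8, 6) is 2; C's two non-zero cells
#'     give within variance 8 and size 36/(8 - 6) = 18; resampling
#'     expectation (0 + 8/3 + 4)/3 = 20/9.
#' }
#'
#' @return A list with `x` (the [expr_matrix()]) and `expected`
#'   (named lists of hand-computed values).
#' @export
tiny_worked_fixture <- function() {
  values <- rbind(
    g1 = c(7, 7, 7, 7, 7, 7, 7, 7, 7),
    g2 = c(0, 2, 4, 0, 3, 9, 6, 0, 12),
    g3 = c(1, 2, 3, 2, 4, 6, 3, 6, 9),
    g4 = c(0, 0, 5, 0, 5, 5, 5, 5, 5),
    g5 = c(0, 0, 0, 0, 0, 8, 4, 8, 0))
  colnames(values) <- paste0("c", 1:9)
  x <- expr_matrix(values, rep(c("A", "B", "C"), each = 3))
  expected <- list(
    dropout = c(g1 = 0, g2 = 3 / 9, g3 = 0, g4 = 3 / 9, g5 = 6 / 9),
    inter_indiv_var = c(g1 = 0, g2 = 9, g3 = 4, g4 = 0, g5 = 2),
    grand_mean_expectation = c(g1 = 7, g2 = 4, g3 = 4, g4 = 10 / 3,
                               g5 = 20 / 9),
    # per-individual non-zero moments where a dispersion is defined,
    # with the moment-matched size mu^2 / (var - mu)
    dispersion = tibble(
      gene_id = c("g2", "g2", "g3", "g5"),
      individual_id = c("B", "C", "C", "C"),
      within_mean = c(6, 9, 6, 6),
      within_var = c(18, 18, 9, 8),
      size = c(3, 9, 12, 18)))
  list(x = x, expected = expected)
}
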