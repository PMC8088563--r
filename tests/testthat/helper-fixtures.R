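# Small builders shared by the tests. Everything is generated in code; no
# fixture files are stored.

# Cell-level predictor of a simulated dataset (group label or phenotype).
predictor_of <- function(dataset) {
  unname(dataset$phenotype_of_individual[dataset$individual_of_cell])
}

# A model with essentially no dropout and optionally no between-individual
# variance; used to isolate single stages of the generative process.
plain_model <- function(f1_intercept = 200, f1_slope = 3, dropout = FALSE) {
  nestedpower:::new_sim_model(
    grand_mean_gamma = c(shape = 5, rate = 0.05),
    f1 = c(intercept = f1_intercept, slope = f1_slope),
    f2 = c(intercept = -6, slope = 3),
    dropout_gamma = if (dropout) c(shape = 8, rate = 16) else c(shape = 2, rate = 2e6))
}

# A parameter table whose columns are exact algebraic functions of the
# grand means, for testing single components of fit_model in isolation.
exact_param_table <- function(grand_mean,
                              iv_fun = function(m) 1 + 2 * m,
                              size_fun = function(m) 0.5 + log(m),
                              dropout = NULL) {
  n <- length(grand_mean)
  size <- size_fun(grand_mean)
  # default dropout varies across genes so the dropout-gamma fit is
  # well-posed
  if (is.null(dropout)) dropout <- seq(0.25, 0.65, length.out = n)
  tibble::tibble(
    gene_id = paste0("g", seq_len(n)),
    dropout_rate = rep_len(dropout, n),
    grand_mean_raw = grand_mean * (1 - dropout),
    grand_mean = grand_mean,
    inter_indiv_var = iv_fun(grand_mean),
    inter_indiv_var_adj = iv_fun(grand_mean),
    n_indiv_expressed = rep(10L, n),
    disp_size = size,
    disp_capped = !is.finite(size) | size <= 1e-4,
    n_indiv_disp = rep(10L, n))
}
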