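# Independent oracles used across the suite. These recompute quantities by
# brute force (enumeration, numerical integration, closed forms) and never
# call the code paths they check.

# Replay the sequential pruning rule from scratch: visit genes in `ord`;
# each surviving visited gene removes all not-yet-visited genes whose
# Spearman correlation with it exceeds `threshold`.
oracle_prune_survivors <- function(values, threshold, ord) {
  rho <- suppressWarnings(cor(t(values), method = "spearman"))
  g <- nrow(values)
  alive <- rep(TRUE, g)
  visited <- rep(FALSE, g)
  for (i in ord) {
    if (!alive[i]) next
    visited[i] <- TRUE
    for (j in seq_len(g)) {
      if (alive[j] && !visited[j] && !is.na(rho[i, j]) && rho[i, j] > threshold) {
        alive[j] <- FALSE
      }
    }
  }
  which(alive)
}

# Exact expectation of the one-cell-per-individual resampled mean for one
# gene, by exhaustive enumeration of every combination of cell choices.
oracle_grand_mean_enumeration <- function(gene_values, individual_of_cell) {
  idx_by_ind <- split(seq_along(gene_values), individual_of_cell)
  combos <- expand.grid(idx_by_ind)
  draws <- apply(combos, 1, function(ix) mean(gene_values[ix]))
  list(expectation = mean(draws), draw_var = var(draws))
}

# Marginal log-likelihood of a binomial-logit model with a normal random
# intercept per individual, by adaptive numerical integration.
# agg: data.frame with nz, ntot, x (numeric covariate; model eta = b0 + b1*x)
oracle_binom_glmm_loglik <- function(agg, b0, b1, sigma_b) {
  ll <- 0
  for (j in seq_len(nrow(agg))) {
    eta0 <- b0 + b1 * agg$x[j]
    f <- function(b) {
      p <- stats::plogis(eta0 + b)
      stats::dbinom(agg$nz[j], agg$ntot[j], p) * stats::dnorm(b, 0, sigma_b)
    }
    if (sigma_b < 1e-8) {
      contrib <- stats::dbinom(agg$nz[j], agg$ntot[j], stats::plogis(eta0))
    } else {
      contrib <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value
    }
    ll <- ll + log(contrib)
  }
  ll
}

# Closed-form marginal log-likelihood of a Gaussian linear mixed model with
# one random intercept per individual: y_j ~ N(X_j beta, sigma_e^2 I +
# sigma_b^2 J). Uses the per-block matrix identities for determinant and
# inverse.
oracle_lmm_loglik <- function(y, X, individual, beta, sigma_b, sigma_e) {
  ll <- 0
  for (id in unique(individual)) {
    sel <- individual == id
    r <- y[sel] - X[sel, , drop = FALSE] %*% beta
    n <- sum(sel)
    s2 <- sigma_e^2
    t2 <- sigma_b^2
    # log|Sigma| = (n-1) log s2 + log(s2 + n t2)
    logdet <- (n - 1) * log(s2) + log(s2 + n * t2)
    # Sigma^-1 = I/s2 - (t2/(s2*(s2 + n t2))) J
    quad <- sum(r^2) / s2 - (t2 / (s2 * (s2 + n * t2))) * sum(r)^2
    ll <- ll - 0.5 * (n * log(2 * pi) + logdet + quad)
  }
  ll
}
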