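test_that("pruning removes exactly one of a perfectly correlated pair and spares independent genes", {
  set.seed(31)
  base <- matrix(rgamma(6 * 200, shape = 25, rate = 2.5), nrow = 6)
  vals <- rbind(base, base[1, ] * 2)
  rownames(vals) <- c(paste0("gene", 1:6), "dup")
  x <- expr_matrix(vals, rep(c("a", "b"), each = 100))
  pruned <- prune_correlated_genes(x, threshold = 0.25, seed = 1)
  # gene1 and its scaled duplicate (Spearman exactly 1): one survives
  expect_equal(sum(c("gene1", "dup") %in% pruned$gene_ids), 1)
  # the independent genes all survive (checked against the realized
  # correlations, which stay below the threshold at 200 cells)
  expect_true(all(paste0("gene", 2:6) %in% pruned$gene_ids))
  expect_equal(n_genes(pruned), 6)
})

test_that("pruned sets match a brute-force replay and contain no correlated pair", {
  set.seed(77)
  g <- 6
  base <- matrix(rnorm(g * 60, 20, 5), nrow = g)
  # plant a correlation structure: 2 tracks 1, 4 tracks 3 weakly, 5 tracks 1
  base[2, ] <- base[1, ] + rnorm(60, 0, 1)
  base[5, ] <- base[1, ] + rnorm(60, 0, 3)
  base[4, ] <- base[3, ] + rnorm(60, 0, 8)
  x <- expr_matrix(base, rep(c("a", "b", "c"), each = 20))
  for (seed in 1:5) {
    pruned <- prune_correlated_genes(x, threshold = 0.25, seed = seed)
    ord <- withr::with_seed(seed, sample.int(g))
    expect_equal(pruned$gene_ids, x$gene_ids[oracle_prune_survivors(x$values, 0.25, ord)],
                 info = paste("seed", seed))
    rho <- cor(t(pruned$values), method = "spearman")
    expect_true(all(rho[upper.tri(rho)] <= 0.25))
  }
  expect_error(prune_correlated_genes(x, threshold = 0), "0, 1")
  expect_error(prune_correlated_genes(x, threshold = 1.2), "0, 1")
})

test_that("grand-mean resampling is exact in degenerate cases and matches exhaustive enumeration", {
  # constant gene: any resample averages to the constant
  x <- expr_matrix(matrix(7, 2, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(estimate_grand_means(x, n_resamples = 5, seed = 1)),
               c(7, 7))

  # within-individual constant {1,1} and {3,3}: always (1 + 3)/2
  x2 <- expr_matrix(matrix(c(1, 1, 3, 3), 1), c("a", "a", "b", "b"))
  expect_equal(unname(estimate_grand_means(x2, n_resamples = 3, seed = 1)), 2)

  # one cell per individual: the estimate is the plain mean across
  # individuals, exactly, whatever the number of replicates
  x3 <- expr_matrix(matrix(c(2, 5, 11), 1), c("a", "b", "c"))
  for (r in c(1, 7)) {
    expect_equal(unname(estimate_grand_means(x3, n_resamples = r, seed = r)),
                 6)
  }

  # unequal cells: compare to the exhaustive enumeration oracle
  vals <- c(0, 6, 3, 9, 2, 4, 10)
  ind <- c("a", "a", "b", "b", "b", "c", "c")
  x4 <- expr_matrix(matrix(vals, 1), ind)
  oracle <- oracle_grand_mean_enumeration(vals, ind)
  n_res <- 4000
  est <- unname(estimate_grand_means(x4, n_resamples = n_res, seed = 9))
  mc_se <- sqrt(oracle$draw_var / n_res)
  expect_lt(abs(est - oracle$expectation), 3 * mc_se)
})

test_that("inter-individual variance uses non-zero means with a J'-1 denominator", {
  # identical non-zero means across individuals: variance 0
  x <- expr_matrix(matrix(c(5, 0, 5, 5, 0, 5), 1), c("a", "a", "b", "b", "c", "c"))
  expect_equal(unname(estimate_inter_individual_variance(x)), 0)

  # two individuals with non-zero means 2 and 4: sample variance 2
  x2 <- expr_matrix(matrix(c(1, 3, 4, 0), 1), c("a", "a", "b", "b"))
  expect_equal(unname(estimate_inter_individual_variance(x2)), 2)

  # zeros interleaved with non-zeros: equals the oracle that drops zeros
  set.seed(4)
  vals <- rpois(12, 6) * rbinom(12, 1, 0.7)
  ind <- rep(c("a", "b", "c"), each = 4)
  x3 <- expr_matrix(matrix(vals, 1), ind)
  means <- vapply(split(vals, ind),
                  function(v) if (any(v > 0)) mean(v[v > 0]) else NA_real_,
                  numeric(1))
  expect_equal(unname(estimate_inter_individual_variance(x3)),
               var(means[!is.na(means)]))

  # fewer than two qualifying individuals: undefined
  x4 <- expr_matrix(matrix(c(2, 2, 0, 0), 1), c("a", "a", "b", "b"))
  expect_true(is.na(estimate_inter_individual_variance(x4)))
})

test_that("moment-matched dispersion handles over-, under- and Poisson-dispersed inputs", {
  # mean 4, variance 8: size 16/(8-4) = 4; check by simulating that NB and
  # recovering the variance
  s <- estimate_dispersion(4, 8)
  expect_equal(as.numeric(s), 4)
  expect_false(attr(s, "capped"))
  set.seed(12)
  draws <- rnbinom(2e5, mu = 4, size = 4)
  expect_lt(abs(var(draws) - 8) / 8, 0.05)

  # Poisson boundary (mean = variance): no excess dispersion, cap returned
  s2 <- estimate_dispersion(3, 3, size_max = 1e6)
  expect_equal(as.numeric(s2), 1e6)
  expect_true(attr(s2, "capped"))

  # underdispersed: cap, flagged
  s3 <- estimate_dispersion(10, 5)
  expect_true(attr(s3, "capped"))

  expect_error(estimate_dispersion(0, 1), "positive")
  expect_error(estimate_dispersion(1, -1), "positive")
})

test_that("dropout rates are exact zero fractions", {
  vals <- rbind(rep(1, 10),
                rep(0, 10),
                c(rep(0, 3), rep(2, 7)))
  x <- expr_matrix(vals, rep(c("a", "b"), each = 5))
  expect_equal(unname(estimate_dropout_rates(x)), c(0, 1, 0.3))
})

test_that("fit_model recovers exact trends and a known gamma", {
  # f2 from exact logarithmic points: coefficients to near machine accuracy
  gm <- seq(5, 120, length.out = 60)
  params <- exact_param_table(gm, size_fun = function(m) 0.5 + 1.0 * log(m))
  m <- fit_model(params)
  expect_equal(unname(m$f2), c(0.5, 1.0), tolerance = 1e-6)

  # f1 from exact linear points in the truncation-free regime
  params2 <- exact_param_table(seq(100, 300, length.out = 60),
                               iv_fun = function(m) 1 + 2 * m)
  m2 <- fit_model(params2)
  expect_equal(unname(m2$f1), c(1, 2), tolerance = 1e-3)

  # the plain least-squares option reproduces a hand-checkable line,
  # including at small means where the default fit applies corrections
  params3 <- exact_param_table(rep(c(1, 2, 3), 12),
                               iv_fun = function(m) 1 + 2 * m,
                               size_fun = function(m) rep(5, length(m)))
  m3 <- fit_model(params3, f1_method = "ols")
  expect_equal(unname(m3$f1), c(1, 2), tolerance = 1e-6)

  # gamma MLE consistency at 10,000 draws from gamma(2, 1)
  set.seed(8)
  gm4 <- rgamma(1e4, shape = 2, rate = 1)
  params4 <- exact_param_table(gm4, size_fun = function(m) 2 + log(m))
  m4 <- fit_model(params4)
  expect_lt(abs(m4$grand_mean_gamma[["shape"]] - 2), 0.1)

  # degenerate inputs rejected
  expect_error(fit_model(exact_param_table(seq(2, 10, length.out = 10))),
               "at least 30")
  expect_error(fit_model(exact_param_table(rep(5, 40))), "constant")
})

test_that("models serialize to JSON and back unchanged", {
  m <- default_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$grand_mean_gamma, m$grand_mean_gamma)
  expect_equal(m2$f1, m$f1)
  expect_equal(m2$f2, m$f2)
  expect_equal(m2$dropout_gamma, m$dropout_gamma)
  expect_equal(m2$size_min, m$size_min)

  td <- tidy(m)
  expect_equal(nrow(td), 8)
  expect_equal(glance(m)$mean_dropout, 0.5)
})
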