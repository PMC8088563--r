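# nestedpower

Power analysis for tests of differential expression in single-cell RNA-seq
experiments with multiple individuals.

Cells sampled from the same individual share genetic background and state,
so their expression values are correlated: single-cell data are
hierarchical, with cells nested inside individuals, and the individual —
not the cell — is the independent experimental unit. Power calculators
that simulate cells as independent replicates therefore overstate the
power of a planned study, sometimes dramatically. `nestedpower` simulates
single-cell expression data with an explicit nested correlation structure
and estimates power and type-1 error by Monte Carlo for analysis methods
that do, and do not, respect that structure. It is aimed at researchers
designing multi-subject single-cell experiments who need to trade off
individuals against cells per individual.

## The model

For gene *i*, individual *j* and cell *k*, expression values (TPM-like
units) are generated as:

- grand mean: mu_i ~ Gamma(shape, rate);
- individual mean: mu_ij = max(0, mu_i + N(0, f1(mu_i))), with
  f1(mu) = a1 + b1 * mu the inter-individual variance trend;
- cell value: Y_ijk ~ NB(mean = mu_ij, size = f2(mu_i)), with
  f2(mu) = a2 + b2 * log(mu) the dispersion trend (size clamped to
  [1e-4, 1e6]; the upper cap is the Poisson limit);
- dropout: each value is independently zeroed with a per-gene
  probability drawn from a gamma distribution truncated to [0, 1].

All hyper-parameters can be estimated from pilot data
(`estimate_model()`): genes are pruned to a mutually uncorrelated subset
(Spearman > 0.25 removed), grand means are estimated by repeatedly
sampling one cell per individual, between- and within-individual moments
are computed from non-zero values, and the four components are fitted by
maximum likelihood / weighted regression. `default_model()` supplies a
fully synthetic default.

Differential expression is tested per gene with a two-part hurdle model
on log(x+1) values — a logistic part for whether a gene is expressed and
a Gaussian part for its level when expressed, each with a per-individual
random intercept, tested by likelihood ratio (or Wald) and combined by
summing the chi-squared statistics and their degrees of freedom. The
naive variant drops the random intercepts (cells as independent units),
and a pseudo-bulk comparator aggregates each individual to one value
before testing.

## Worked example

How much does ignoring the nested structure overstate power for a 1.3
fold change with 10 individuals per group and 50 cells per individual?

```r
library(nestedpower)

model <- default_model()
design <- sim_design(n_genes = 1, phenotype = "binary", n_per_group = 10,
                     cells_per_individual = 50, fold_change = 1.3)

estimate_power(design, model, method = "hurdle_mixed", n_genes = 100, seed = 1)
#> <power_estimate> power = 0.700 (MC se 0.046), hurdle_mixed at alpha = 0.05
#>   70/100 rejected, 0 failed fits, seed 1

estimate_power(design, model, method = "hurdle_naive", n_genes = 100, seed = 1)
#> <power_estimate> power = 0.960 (MC se 0.020), hurdle_naive at alpha = 0.05
#>   96/100 rejected, 0 failed fits, seed 1
```

The cells-as-independent analysis reports 0.96 where the analysis that
accounts for within-individual correlation has power 0.70 — the naive
number is not extra power, it is an inflated type-1 error in disguise
(`estimate_type1()` on the same null design returns about 0.43 for the
naive hurdle and about 0.05 for the mixed one).

Simulated datasets are first-class objects, and per-gene testing returns
a tidy table:

```r
ds <- simulate_binary(sim_design(n_genes = 3, frac_de = 1, phenotype = "binary",
                                 n_per_group = 4, cells_per_individual = 25,
                                 fold_change = 2, seed = 7), model)
test_genes(ds, method = "hurdle_mixed")
#> # A tibble: 3 × 9
#>   gene_id stat_d  df_d stat_c  df_c  stat    df        p converged
#>   <chr>    <dbl> <int>  <dbl> <int> <dbl> <int>    <dbl> <lgl>
#> 1 gene1   4.35       1   11.8     1  16.2     2 0.000306 TRUE
#> 2 gene2   0.347      1   16.2     1  16.6     2 0.000253 TRUE
#> 3 gene3   0.0868     1   10.7     1  10.8     2 0.00449  TRUE
```

`power_grid()` evaluates a table of designs crossed with methods and
returns a tidy tibble; `autoplot()` draws the power curves. Pilot data
can be read from dense CSV/TSV or MatrixMarket files with
`read_expression()`, and simulated datasets written back out with
`write_simulated()`.

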