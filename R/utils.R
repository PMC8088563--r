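# Internal helpers shared across modules.

# Set the RNG seed for the duration of the *calling* function only, restoring
# the caller's RNG state afterwards. A NULL seed means "consume the ambient
# RNG stream", which is how composite operations feed one root seed through
# their stages in a fixed order.
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}

# Deterministic substream derivation: maps a root seed and an index to a new
# seed in [1, 2^31 - 20]. Linear-congruential style; documented in the
# methods vignette so grids are reproducible under partial re-runs.
derive_seed <- function(root_seed, index) {
  m <- 2147483629
  s <- (as.double(root_seed) %% m + (1103515245 * (as.double(index) %% m)) %% m) %% m
  as.integer(s + 1)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop_if_not_prob <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], not %s.",
                  name, deparse(substitute(x))))
  }
}
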