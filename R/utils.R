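# internal helpers shared across modules

.withSeed <- function(seed, fun) {
  if (is.null(seed) || is.na(seed)) fun() else withr::with_seed(seed, fun())
}

# Gaussian counting noise with user CV, truncated at zero (counts can't be
# negative); cv = 0 returns the expectation untouched
.noisyCounts <- function(mu, cv) {
  if (cv == 0) return(mu)
  pmax(0, stats::rnorm(length(mu), mean = mu, sd = cv * mu))
}

.assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number", call. = FALSE)
  if (positive && x <= 0) stop(name, " must be > 0", call. = FALSE)
  if (nonneg && x < 0) stop(name, " must be >= 0", call. = FALSE)
  invisible(x)
}
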