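# Internal helpers shared across modules.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream;
# a NULL seed uses the ambient stream (lets the pipeline seed once globally).
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Two-tailed permutation rank p with ties split evenly between the tails.
two_tailed_rank_p <- function(observed, null) {
  n <- length(null)
  r <- sum(null < observed) + 0.5 * sum(null == observed)
  min(1, 2 * min(r + 1, n + 1 - r) / (n + 1))
}

# Population (divide-by-n) standard deviation; the null-distribution default.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

null_sd_fun <- function(sd_type) {
  switch(sd_type, population = pop_sd, sample = stats::sd,
         stop("unknown sd_type: ", sd_type))
}

# Half-up rounding for printed percentages (base round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}
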