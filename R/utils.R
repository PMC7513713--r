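#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Stochastic stages (per-stratum null simulations, per-stage synthetic data
#' generation) each receive their own RNG seed derived deterministically from
#' the master seed and a string label. This makes results independent of the
#' order in which strata are processed and lets parts of a study be
#' regenerated in isolation.
#'
#' @param seed master seed (single integer).
#' @param label character label identifying the stream (e.g. an
#'   enclosure-year id, or `"genotypes"`).
#' @return a single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; exact in double arithmetic
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) + h) %% m)
}

# column standard deviations of a matrix without apply() overhead
.col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to compute a standard deviation")
  mu <- colMeans(x)
  sqrt(pmax(colSums(x * x) - n * mu * mu, 0) / (n - 1))
}

.is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# stop() with sprintf-style formatting, no call in message
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
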