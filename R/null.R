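#' @rdname simulate_null
#' @export
new_null_distribution <- function(draws, statistic) {
  stopifnot(is.numeric(draws), length(draws) >= 1L)
  structure(
    list(statistic = statistic,
         draws = draws,
         n_sims = length(draws),
         expected = mean(draws),
         ci_low = unname(stats::quantile(draws, 0.025)),
         ci_high = unname(stats::quantile(draws, 0.975)),
         sim_min = min(draws),
         sim_max = max(draws)),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Null distribution of the %s of pair similarity (%d draws)\n",
              x$statistic, x$n_sims))
  cat(sprintf("  expected %.4f, 95%% CI [%.4f, %.4f], range [%.4f, %.4f]\n",
              x$expected, x$ci_low, x$ci_high, x$sim_min, x$sim_max))
  invisible(x)
}

# draw matrix of d_ab values: k rows x n_sims columns, each column a draw of
# k distinct pairs. null_mode "match_degrees" rejection-samples until the
# sorted per-female and per-male pair-count sequences match the observed ones.
.null_draw_matrix <- function(sims, k, n_sims, null_mode = "uniform_pairs",
                              observed = NULL, max_tries = 10000L) {
  n <- nrow(sims)
  d <- sims$d_ab
  if (k > n) .fail("k = %d exceeds the %d available pairs", k, n)
  if (null_mode == "uniform_pairs") {
    idx <- vapply(seq_len(n_sims), function(i) sample.int(n, k), integer(k))
    return(matrix(d[idx], nrow = k))
  }
  if (null_mode != "match_degrees") .fail("unknown null_mode '%s'", null_mode)
  if (is.null(observed)) .fail("null_mode 'match_degrees' needs the observed pairs")
  deg_sig <- function(f, m) paste(c(sort(table(f)), "|", sort(table(m))), collapse = ",")
  target <- deg_sig(observed$female_id, observed$male_id)
  out <- matrix(NA_real_, k, n_sims)
  for (s in seq_len(n_sims)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      idx <- sample.int(n, k)
      if (deg_sig(sims$female_id[idx], sims$male_id[idx]) == target) { ok <- TRUE; break }
    }
    if (!ok) .fail("match_degrees: no draw matching the observed degree counts in %d tries",
                   max_tries)
    out[, s] <- d[idx]
  }
  out
}

.draw_statistic <- function(mat, statistic) {
  if (statistic == "mean") return(colMeans(mat))
  if (statistic == "sd") {
    if (nrow(mat) < 2L) .fail("the SD statistic needs at least 2 pairs per draw")
    return(.col_sds(mat))
  }
  .fail("unknown statistic '%s'", statistic)
}

#' Structured randomization null for a pairing statistic
#'
#' Simulates random mating within one enclosure-year: each draw selects the
#' observed number of successful pairings, `k`, uniformly without replacement
#' from the set of all possible opposite-sex pairs of the enclosure-year, and
#' records the mean (or SD) of their similarity values. An individual can
#' appear in several selected pairs, mirroring the polygamy observed in
#' group housing. The default 100,000 repetitions give a stable percentile
#' interval for the expected statistic under random mating.
#'
#' With `null_mode = "match_degrees"` each draw is additionally constrained
#' to reproduce the observed pairing graph's degree counts (how many females
#' bred with 1, 2, ... males and vice versa), a stricter null for strongly
#' polygamous observed configurations.
#'
#' @param sims a [similarity_matrix()] table (all possible pairs of the
#'   enclosure-year).
#' @param observed the observed successful pairs: a `data.frame` with
#'   `female_id` and `male_id` columns, or a single integer `k`.
#' @param statistic `"mean"` (advantage-of-dissimilar-mates test) or `"sd"`
#'   (optimum-genetic-distance test).
#' @param n_sims number of Monte-Carlo draws.
#' @param seed RNG seed (required; draws are reproducible given the seed).
#' @param null_mode `"uniform_pairs"` (default) or `"match_degrees"`.
#' @return an object of class `null_distribution`: the full draw vector plus
#'   its mean (`expected`), 2.5/97.5 percentile bounds (`ci_low`,
#'   `ci_high`) and extremes (`sim_min`, `sim_max`).
#' @export
simulate_null <- function(sims, observed, statistic = c("mean", "sd"),
                          n_sims = 100000L, seed,
                          null_mode = c("uniform_pairs", "match_degrees")) {
  statistic <- match.arg(statistic)
  null_mode <- match.arg(null_mode)
  if (missing(seed)) .fail("a seed is required for the randomization null")
  stopifnot(.is_count(n_sims), n_sims >= 1)
  obs_df <- NULL
  if (is.data.frame(observed)) {
    obs_df <- observed
    k <- nrow(observed)
  } else {
    k <- as.integer(observed)
  }
  if (k < 1L) .fail("k must be >= 1")
  if (statistic == "sd" && k < 2L)
    .fail("the SD statistic is undefined for a single pair; enclosure-years with one successful pair are excluded from this test")
  set.seed(seed)
  mat <- .null_draw_matrix(sims, k, n_sims, null_mode, obs_df)
  new_null_distribution(.draw_statistic(mat, statistic), statistic)
}

#' Exact null distribution by exhaustive enumeration
#'
#' Enumerates every k-subset of the possible pairs and computes the
#' statistic for each, giving the exact randomization distribution that
#' [simulate_null()] approximates. Intended for validating the Monte-Carlo
#' machinery on small enclosures; refuses when the number of combinations
#' exceeds `cap`.
#'
#' @inheritParams simulate_null
#' @param k number of pairs per draw.
#' @param cap maximum number of combinations to enumerate.
#' @return a `null_distribution` whose `draws` hold all `choose(n, k)`
#'   outcomes, each with equal weight.
#' @export
enumerate_null_exact <- function(sims, k, statistic = c("mean", "sd"), cap = 1e6) {
  statistic <- match.arg(statistic)
  n <- nrow(sims)
  k <- as.integer(k)
  if (k < 1L || k > n) .fail("k must be between 1 and the number of pairs (%d)", n)
  if (statistic == "sd" && k < 2L) .fail("the SD statistic needs k >= 2")
  n_comb <- choose(n, k)
  if (n_comb > cap)
    .fail("choose(%d, %d) = %.0f exceeds the enumeration cap (%g)", n, k, n_comb, cap)
  mat <- utils::combn(sims$d_ab, k)
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = k)
  new_null_distribution(.draw_statistic(mat, statistic), statistic)
}
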