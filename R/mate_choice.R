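#' Mate-choice hypothesis test for one enclosure-year
#'
#' Compares the observed mean (hypothesis `"dissimilar_mates"`) or standard
#' deviation (hypothesis `"optimum_distance"`) of the similarity of the
#' successful breeding pairs against the structured randomization null of
#' [simulate_null()]. Under "advantage of dissimilar mates", the observed
#' mean similarity is predicted to fall below the null 95% CI; under
#' "optimum genetic distance", the observed SD is predicted to fall below
#' the null 95% CI (successful pairs converge on an intermediate distance).
#'
#' Observed pairs without a defined similarity (e.g. an unsequenced parent)
#' are dropped with a warning and `k` reduced accordingly.
#'
#' The per-enclosure RNG stream is derived from `seed` and the
#' enclosure-year id with [derive_seed()], so results do not depend on the
#' order in which enclosures are analysed.
#'
#' @param sims a [similarity_matrix()] table for the enclosure-year.
#' @param observed `data.frame` of observed successful pairs (`female_id`,
#'   `male_id`).
#' @param hypothesis `"dissimilar_mates"` (mean) or `"optimum_distance"` (SD).
#' @param n_sims,seed,null_mode passed to [simulate_null()]; `seed` is the
#'   master seed.
#' @return an object of class `mate_choice_test`.
#' @export
mc_test_enclosure <- function(sims, observed,
                              hypothesis = c("dissimilar_mates", "optimum_distance"),
                              n_sims = 100000L, seed,
                              null_mode = c("uniform_pairs", "match_degrees")) {
  hypothesis <- match.arg(hypothesis)
  null_mode <- match.arg(null_mode)
  if (missing(seed)) .fail("a seed is required")
  ey <- attr(sims, "enclosure_year")
  if (is.null(ey)) ey <- "enclosure"
  obs <- .match_observed(sims, observed, ey)
  statistic <- if (hypothesis == "dissimilar_mates") "mean" else "sd"
  if (statistic == "sd" && nrow(obs) < 2L)
    .fail("%s: only %d successful pair(s); the optimum-distance test needs at least 2",
          ey, nrow(obs))
  observed_stat <- if (statistic == "mean") mean(obs$d_ab) else stats::sd(obs$d_ab)
  null <- simulate_null(sims, obs, statistic, n_sims,
                        seed = derive_seed(seed, ey), null_mode = null_mode)
  .mc_result(scope = ey, panel_id = sims$panel_id[1L], hypothesis = hypothesis,
             observed_stat = observed_stat, k = nrow(obs), null = null,
             n_sims = n_sims, seed = seed, null_mode = null_mode)
}

#' Pooled mate-choice hypothesis test across enclosure-years
#'
#' Pools the per-enclosure-year randomizations while respecting their
#' structure: each draw independently selects \eqn{k_e} pairs within every
#' enclosure-year \eqn{e} (exactly as [simulate_null()] does), concatenates
#' the selected similarity values across strata, and computes the pooled
#' statistic. The observed pooled statistic is computed over all observed
#' pairs' similarities. Per-stratum RNG streams are derived from the master
#' seed and the stratum id, so stratum processing order is irrelevant.
#'
#' @param sims_list named list of [similarity_matrix()] tables, one per
#'   enclosure-year.
#' @param observed_list named list of observed-pair `data.frame`s, parallel
#'   to `sims_list`.
#' @inheritParams mc_test_enclosure
#' @return an object of class `mate_choice_test` with scope `"pooled"`.
#' @export
mc_test_pooled <- function(sims_list, observed_list,
                           hypothesis = c("dissimilar_mates", "optimum_distance"),
                           n_sims = 100000L, seed,
                           null_mode = c("uniform_pairs", "match_degrees")) {
  hypothesis <- match.arg(hypothesis)
  null_mode <- match.arg(null_mode)
  if (missing(seed)) .fail("a seed is required")
  stopifnot(is.list(sims_list), is.list(observed_list),
            length(sims_list) == length(observed_list))
  eys <- names(sims_list)
  if (is.null(eys))
    eys <- vapply(sims_list, function(s) attr(s, "enclosure_year"), character(1L))
  statistic <- if (hypothesis == "dissimilar_mates") "mean" else "sd"

  mats <- list(); obs_d <- numeric(0)
  for (i in seq_along(sims_list)) {
    sims <- sims_list[[i]]
    obs <- .match_observed(sims, observed_list[[i]], eys[i])
    if (nrow(obs) == 0L) {
      warning(sprintf("%s: no observed pair with defined similarity; stratum dropped", eys[i]),
              call. = FALSE)
      next
    }
    obs_d <- c(obs_d, obs$d_ab)
    set.seed(derive_seed(seed, eys[i]))
    mats[[length(mats) + 1L]] <- .null_draw_matrix(sims, nrow(obs), n_sims,
                                                   null_mode, obs)
  }
  if (!length(mats)) .fail("no stratum with observed pairs")
  k <- length(obs_d)
  if (statistic == "sd" && k < 2L) .fail("the pooled SD test needs at least 2 observed pairs")
  stacked <- do.call(rbind, mats)
  null <- new_null_distribution(.draw_statistic(stacked, statistic), statistic)
  observed_stat <- if (statistic == "mean") mean(obs_d) else stats::sd(obs_d)
  .mc_result(scope = "pooled", panel_id = sims_list[[1L]]$panel_id[1L],
             hypothesis = hypothesis, observed_stat = observed_stat, k = k,
             null = null, n_sims = n_sims, seed = seed, null_mode = null_mode)
}

# join observed pairs against the similarity table; drop unmatched with warning
.match_observed <- function(sims, observed, ey) {
  stopifnot(is.data.frame(observed),
            all(c("female_id", "male_id") %in% colnames(observed)))
  key <- paste(sims$female_id, sims$male_id, sep = "\r")
  okey <- paste(observed$female_id, observed$male_id, sep = "\r")
  dup <- duplicated(okey)
  if (any(dup)) {
    warning(sprintf("%s: duplicate observed pair(s) counted once", ey), call. = FALSE)
    observed <- observed[!dup, , drop = FALSE]
    okey <- okey[!dup]
  }
  hit <- match(okey, key)
  if (anyNA(hit)) {
    warning(sprintf("%s: %d observed pair(s) without defined similarity dropped",
                    ey, sum(is.na(hit))), call. = FALSE)
    hit <- hit[!is.na(hit)]
  }
  sims[hit, c("female_id", "male_id", "d_ab"), drop = FALSE]
}

.mc_result <- function(scope, panel_id, hypothesis, observed_stat, k, null,
                       n_sims, seed, null_mode) {
  outcome <- if (observed_stat < null$ci_low) "below_ci"
             else if (observed_stat > null$ci_high) "above_ci"
             else "within_ci"
  # one-sided lower-tail p with add-one correction, never exactly zero
  empirical_p <- (1 + sum(null$draws <= observed_stat)) / (1 + null$n_sims)
  structure(
    list(scope = scope, panel_id = panel_id, hypothesis = hypothesis,
         observed = observed_stat, k = k, null = null, outcome = outcome,
         empirical_p = empirical_p, n_sims = n_sims, seed = seed,
         null_mode = null_mode),
    class = "mate_choice_test")
}

#' @export
print.mate_choice_test <- function(x, ...) {
  lab <- c(dissimilar_mates = "advantage of dissimilar mates (mean pair similarity)",
           optimum_distance = "optimum genetic distance (SD of pair similarity)")
  cat(sprintf("Mate-choice test: %s\n", lab[[x$hypothesis]]))
  cat(sprintf("  scope %s, panel %s, k = %d successful pairs, %d randomizations\n",
              x$scope, x$panel_id, x$k, x$n_sims))
  cat(sprintf("  observed %.4f vs expected %.4f, 95%% CI [%.4f, %.4f] -> %s (p = %.4g)\n",
              x$observed, x$null$expected, x$null$ci_low, x$null$ci_high,
              x$outcome, x$empirical_p))
  invisible(x)
}

#' @export
as.data.frame.mate_choice_test <- function(x, ...) {
  data.frame(scope = x$scope, panel_id = x$panel_id, hypothesis = x$hypothesis,
             k = x$k, observed = x$observed, expected = x$null$expected,
             ci_low = x$null$ci_low, ci_high = x$null$ci_high,
             sim_min = x$null$sim_min, sim_max = x$null$sim_max,
             outcome = x$outcome, empirical_p = x$empirical_p,
             n_sims = x$n_sims, seed = x$seed, null_mode = x$null_mode,
             stringsAsFactors = FALSE)
}

#' Run both mate-choice hypothesis tests across all enclosure-years
#'
#' Convenience scanner: computes the all-pairs similarity table of every
#' enclosure-year, tests each enclosure-year and the pooled data for both
#' hypotheses, and collects the results. Enclosure-years with a single
#' successful pair are excluded from the per-enclosure optimum-distance
#' test (no SD can be computed) but still contribute to the pooled tests.
#'
#' @param panel a [genotype_panel()].
#' @param roster a roster (see [read_roster()]).
#' @param pairs observed successful pairs (see [read_pairs()]).
#' @param hypotheses which hypotheses to test.
#' @inheritParams mc_test_enclosure
#' @param min_shared_loci passed to [similarity_matrix()].
#' @return an object of class `mate_choice_scan`: a list with the per-test
#'   objects (`tests`) and the similarity tables (`similarities`); use
#'   [as.data.frame()] for the results table and [plot()] for an
#'   observed-vs-expected figure.
#' @export
run_mate_choice <- function(panel, roster, pairs,
                            hypotheses = c("dissimilar_mates", "optimum_distance"),
                            n_sims = 100000L, seed,
                            null_mode = c("uniform_pairs", "match_degrees"),
                            min_shared_loci = 1L) {
  null_mode <- match.arg(null_mode)
  if (missing(seed)) .fail("a seed is required")
  eys <- unique(roster$enclosure_year)
  sims_list <- list(); obs_list <- list()
  for (ey in eys) {
    obs <- pairs[pairs$enclosure_year == ey, , drop = FALSE]
    if (nrow(obs) == 0L) next
    sims_list[[ey]] <- similarity_matrix(panel, roster[roster$enclosure_year == ey, ,
                                                       drop = FALSE],
                                         min_shared_loci = min_shared_loci)
    obs_list[[ey]] <- obs
  }
  if (!length(sims_list)) .fail("no enclosure-year with observed successful pairs")
  tests <- list()
  for (hyp in hypotheses) {
    for (ey in names(sims_list)) {
      if (hyp == "optimum_distance" && nrow(obs_list[[ey]]) < 2L) {
        message(sprintf("%s: single successful pair; excluded from the optimum-distance test", ey))
        next
      }
      tests[[paste(hyp, ey, sep = ".")]] <-
        mc_test_enclosure(sims_list[[ey]], obs_list[[ey]], hyp,
                          n_sims = n_sims, seed = seed, null_mode = null_mode)
    }
    tests[[paste(hyp, "pooled", sep = ".")]] <-
      mc_test_pooled(sims_list, obs_list, hyp,
                     n_sims = n_sims, seed = seed, null_mode = null_mode)
  }
  structure(list(tests = tests, similarities = sims_list,
                 panel_id = panel$panel_id, seed = seed, n_sims = n_sims),
            class = "mate_choice_scan")
}

#' @export
as.data.frame.mate_choice_scan <- function(x, ...) {
  out <- do.call(rbind, lapply(unname(x$tests), as.data.frame))
  rownames(out) <- NULL
  out
}

#' @export
print.mate_choice_scan <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Mate-choice scan: panel %s, %d tests (%d randomizations each)\n\n",
              x$panel_id, nrow(df), x$n_sims))
  print(format(df[, c("scope", "hypothesis", "k", "observed", "expected",
                      "ci_low", "ci_high", "outcome", "empirical_p")],
               digits = 4), row.names = FALSE)
  invisible(x)
}

#' Observed-versus-expected plot of a mate-choice scan
#'
#' One panel per hypothesis: for each scope (enclosure-year and pooled), the
#' expected statistic under random mating (black circle) with its 95%
#' percentile CI (black segment) and the simulated minimum/maximum beyond
#' the CI (grey segment), and the observed statistic (red triangle).
#'
#' @param x a `mate_choice_scan`.
#' @param hypothesis which hypothesis to plot (default: all present).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mate_choice_scan <- function(x, hypothesis = NULL, ...) {
  df <- as.data.frame(x)
  hyps <- if (is.null(hypothesis)) unique(df$hypothesis) else hypothesis
  old <- graphics::par(mfrow = c(length(hyps), 1), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  ylab <- c(dissimilar_mates = "mean pair similarity",
            optimum_distance = "SD of pair similarity")
  for (hyp in hyps) {
    d <- df[df$hypothesis == hyp, , drop = FALSE]
    n <- nrow(d)
    ylim <- range(d$sim_min, d$sim_max, d$observed)
    graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = ylim, xaxt = "n",
                   xlab = "", ylab = ylab[[hyp]], main = hyp, ...)
    graphics::axis(1, at = seq_len(n), labels = d$scope, las = 2, cex.axis = 0.8)
    graphics::segments(seq_len(n), d$sim_min, y1 = d$sim_max, col = "grey60", lwd = 2)
    graphics::segments(seq_len(n), d$ci_low, y1 = d$ci_high, col = "black", lwd = 3)
    graphics::points(seq_len(n), d$expected, pch = 16)
    graphics::points(seq_len(n), d$observed, pch = 17, col = "red")
  }
  invisible(x)
}
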