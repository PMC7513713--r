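#' Rejection rate of the pooled mate-choice tests over replicate studies
#'
#' Repeatedly generates a synthetic study from `config`, runs the pooled
#' randomization test(s) on the genome-wide panel, and tallies the outcome
#' categories. With `mechanism = "random"` this measures the calibration of
#' the one-sided percentile test (the below-CI rate should be close to
#' 2.5%); with a preference mechanism it measures power.
#'
#' Replicates without at least `min_strata` enclosure-years containing a
#' successful pair are skipped (and counted in `n_skipped`).
#'
#' @param config a [sim_config()] describing the study conditions.
#' @param n_reps number of replicate studies.
#' @param hypotheses hypotheses to test on each replicate.
#' @param n_sims randomizations per null distribution.
#' @param seed master seed; every replicate derives its own streams.
#' @param min_strata minimum usable enclosure-years per replicate.
#' @return a list with `n_used`, `n_skipped`, and per-hypothesis tables of
#'   outcome counts plus `below_ci_rate`.
#' @export
mc_rejection_rate <- function(config, n_reps,
                              hypotheses = c("dissimilar_mates", "optimum_distance"),
                              n_sims = 2000L, seed, min_strata = 2L) {
  if (missing(seed)) .fail("a seed is required")
  counts <- lapply(hypotheses, function(h)
    c(below_ci = 0L, within_ci = 0L, above_ci = 0L))
  names(counts) <- hypotheses
  used <- skipped <- 0L
  for (r in seq_len(n_reps)) {
    st <- simulate_study(config, derive_seed(seed, paste0("study", r)))
    eys <- unique(st$pairs$enclosure_year)
    if (length(eys) < min_strata) { skipped <- skipped + 1L; next }
    sims_list <- obs_list <- list()
    for (ey in eys) {
      ro <- st$roster[st$roster$enclosure_year == ey, , drop = FALSE]
      sims_list[[ey]] <- suppressMessages(similarity_matrix(st$gw, ro))
      obs_list[[ey]] <- st$pairs[st$pairs$enclosure_year == ey, , drop = FALSE]
    }
    used <- used + 1L
    for (h in hypotheses) {
      t <- mc_test_pooled(sims_list, obs_list, h, n_sims = n_sims,
                          seed = derive_seed(seed, paste0("test", r)))
      counts[[h]][t$outcome] <- counts[[h]][t$outcome] + 1L
    }
  }
  out <- list(n_used = used, n_skipped = skipped)
  for (h in hypotheses)
    out[[h]] <- list(counts = counts[[h]],
                     below_ci_rate = unname(counts[[h]]["below_ci"]) / used)
  out
}
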