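#' Configuration for a full pipeline run
#'
#' @param genotypes_gw,genotypes_mhc paths to the genome-wide and MHC
#'   genotype files (either may be `NULL` to skip that panel).
#' @param format_gw,format_mhc input formats (see [read_genotypes()]).
#' @param roster,pairs paths to the roster and breeding-pair CSVs.
#' @param analyses subset of `"overall"` (breeding-success and
#'   offspring-count model averaging), `"h1"` (within-enclosure relative
#'   predictors), `"h2"` (advantage of dissimilar mates), `"h3"` (optimum
#'   genetic distance).
#' @param n_sims randomizations per null distribution.
#' @param seed master seed; required whenever a stochastic analysis
#'   (`h2`/`h3`) is requested.
#' @param null_mode,min_shared_loci see [mc_test_enclosure()] and
#'   [similarity_matrix()].
#' @param delta_aicc AICc window for the top model set.
#' @param out_dir directory for result files.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(genotypes_gw = NULL, genotypes_mhc = NULL,
                       format_gw = "vcf", format_mhc = "two_col_csv",
                       roster, pairs = NULL,
                       analyses = c("overall", "h1", "h2", "h3"),
                       n_sims = 100000L, seed = NULL,
                       null_mode = "uniform_pairs", min_shared_loci = 1L,
                       delta_aicc = 2, out_dir) {
  if (!length(analyses)) .fail("no analyses requested")
  bad <- setdiff(analyses, c("overall", "h1", "h2", "h3"))
  if (length(bad)) .fail("unknown analysis: %s", paste(bad, collapse = ", "))
  if (any(c("h2", "h3") %in% analyses)) {
    if (is.null(seed)) .fail("a seed is required for the randomization tests (h2/h3)")
    if (is.null(pairs)) .fail("h2/h3 need the breeding-pair table")
  }
  if (is.null(genotypes_gw) && is.null(genotypes_mhc))
    .fail("at least one genotype panel is required")
  structure(
    list(genotypes_gw = genotypes_gw, genotypes_mhc = genotypes_mhc,
         format_gw = format_gw, format_mhc = format_mhc,
         roster = roster, pairs = pairs, analyses = analyses,
         n_sims = as.integer(n_sims), seed = seed, null_mode = null_mode,
         min_shared_loci = as.integer(min_shared_loci),
         delta_aicc = delta_aicc, out_dir = out_dir),
    class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the requested analyses in a fixed order — heterozygosity,
#' similarity, randomization tests, regression models — and writes one CSV
#' per result table plus a `manifest.json` recording the configuration,
#' seed, package version and MD5 of every output, sufficient to reproduce
#' the run. All stochastic stages derive their streams from the master
#' seed, so an identical configuration reproduces identical files.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory results:
#'   `heterozygosity`, `mate_choice` (per panel), `models`, `unmatched`,
#'   and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .fail("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  roster <- stage("read_roster", read_roster(config$roster))
  pairs <- if (!is.null(config$pairs)) stage("read_pairs", read_pairs(config$pairs))
  panels <- list()
  if (!is.null(config$genotypes_gw))
    panels$GW <- stage("read_genotypes",
                       read_genotypes(config$genotypes_gw, config$format_gw, "GW"))
  if (!is.null(config$genotypes_mhc))
    panels$MHC <- stage("read_genotypes",
                        read_genotypes(config$genotypes_mhc, config$format_mhc, "MHC"))

  unmatched <- lapply(panels, function(p) unmatched_ids(roster, p))
  for (pid in names(unmatched))
    if (length(unmatched[[pid]]))
      message(sprintf("panel %s: %d roster individual(s) without genotypes: %s",
                      pid, length(unmatched[[pid]]),
                      paste(unmatched[[pid]], collapse = ", ")))

  # heterozygosity (always computed; feeds the models)
  het <- stage("heterozygosity", do.call(rbind, lapply(panels, smlh)))
  rownames(het) <- NULL
  f <- file.path(config$out_dir, "heterozygosity.csv")
  utils::write.csv(het, f, row.names = FALSE)
  files <- c(files, f)

  # attach per-individual heterozygosity to the roster
  model_data <- as.data.frame(roster)
  for (pid in names(panels)) {
    h <- het[het$panel_id == panels[[pid]]$panel_id, ]
    col <- if (pid == "GW") "h_gw" else "h_mhc"
    model_data[[col]] <- h$h_std[match(model_data$individual_id, h$individual_id)]
  }

  mc <- list()
  if (any(c("h2", "h3") %in% config$analyses)) {
    hyps <- c(if ("h2" %in% config$analyses) "dissimilar_mates",
              if ("h3" %in% config$analyses) "optimum_distance")
    for (pid in names(panels)) {
      scan <- stage(paste0("mate_choice_", pid),
                    run_mate_choice(panels[[pid]], roster, pairs,
                                    hypotheses = hyps, n_sims = config$n_sims,
                                    seed = config$seed,
                                    null_mode = config$null_mode,
                                    min_shared_loci = config$min_shared_loci))
      mc[[pid]] <- scan
      df <- as.data.frame(scan)
      f <- file.path(config$out_dir, sprintf("mate_choice_%s.csv", pid))
      utils::write.csv(df, f, row.names = FALSE)
      files <- c(files, f)
      sim_all <- do.call(rbind, lapply(scan$similarities, as.data.frame))
      sim_all <- data.frame(
        enclosure_year = rep(names(scan$similarities),
                             vapply(scan$similarities, nrow, integer(1L))),
        sim_all, row.names = NULL)
      f <- file.path(config$out_dir, sprintf("similarity_%s.csv", pid))
      utils::write.csv(sim_all, f, row.names = FALSE)
      files <- c(files, f)
    }
  }

  models <- list()
  genetic_preds <- intersect(c("h_gw", "h_mhc"), colnames(model_data))
  if ("overall" %in% config$analyses)
    models <- c(models, stage("overall_models",
      .pipeline_models(model_data, genetic_preds, relative = FALSE,
                       delta = config$delta_aicc)))
  if ("h1" %in% config$analyses)
    models <- c(models, stage("h1_models",
      .pipeline_models(model_data, genetic_preds, relative = TRUE,
                       delta = config$delta_aicc)))
  if (length(models)) {
    tabs <- lapply(names(models), function(nm) {
      if (is.null(models[[nm]])) return(NULL)
      data.frame(analysis = nm, models[[nm]]$table, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    f <- file.path(config$out_dir, "model_averaging.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }

  manifest <- list(
    package = "matechoice",
    version = as.character(utils::packageVersion("matechoice")),
    config = config[setdiff(names(config), "out_dir")],
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files))))
  f <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  files <- c(files, f)

  invisible(list(heterozygosity = het, mate_choice = mc, models = models,
                 unmatched = unmatched, files = files))
}

# the four per-sex analyses of one predictor scale (absolute or relative)
.pipeline_models <- function(model_data, genetic_preds, relative, delta) {
  preds <- c("age", "weight", genetic_preds)
  out <- list()
  for (sex in c("F", "M")) {
    d <- model_data[model_data$sex == sex, , drop = FALSE]
    if (relative) {
      d <- standardize_within_group(model_data, vars = preds)
      d <- d[d$sex == sex, , drop = FALSE]
      use <- paste0("z.", preds)
    } else {
      use <- preds
    }
    random_success <- if (sex == "F") "enclosure_year" else "individual_id"
    key <- function(kind) sprintf("%s_%s_%s", if (relative) "h1" else "overall",
                                  kind, tolower(sex))
    out[[key("success")]] <- .try_average(d, "binomial", use,
                                          random = random_success,
                                          delta = delta, std = !relative)
    br <- d[d$bred == 1L, , drop = FALSE]
    fam <- if (sex == "F") "binomial_out_of_4" else "poisson"
    random_off <- if (sex == "F") "enclosure_year" else NULL
    out[[key("offspring")]] <- .try_average(br, fam, use, random = random_off,
                                            delta = delta, std = !relative)
  }
  out
}

# model averaging with graceful degradation: drop the random intercept, then
# give up with a warning, rather than aborting the whole pipeline
.try_average <- function(data, family, predictors, random, delta, std) {
  res <- tryCatch(
    model_average(data, family, predictors, random = random, delta = delta,
                  standardize = std),
    error = function(e) NULL)
  if (is.null(res) && !is.null(random)) {
    message(sprintf("%s model with (1|%s) failed; refitting without the random intercept",
                    family, random))
    res <- tryCatch(
      model_average(data, family, predictors, random = NULL, delta = delta,
                    standardize = std),
      error = function(e) {
        warning(sprintf("%s model could not be fitted: %s", family,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
  }
  res
}
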