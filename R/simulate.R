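#' Configuration for a synthetic group-housed breeding study
#'
#' Describes a study of the kind the analysis pipeline targets: a small
#' number of large free-range enclosures followed over several breeding
#' seasons, each holding up to 21 adults in a roughly even sex ratio, with
#' genotypes at a large biallelic SNP panel and a small multi-allelic
#' (microsatellite) panel, high reproductive skew (roughly 60% of
#' individuals failing to breed), litters of 1--4, and a configurable
#' mate-choice mechanism.
#'
#' Mechanisms: `"random"` (uniform mate choice), `"dissimilarity_preference"`
#' (a successful female chooses a male with weight proportional to
#' `exp(beta_dis * (1 - D_AB))`), `"optimum_distance"` (weight proportional
#' to `exp(-(D_AB - d_opt)^2 / (2 sigma_opt^2))`) and `"het_advantage"`
#' (a female's success probability gains `beta_het` per 2-SD of her
#' genome-wide heterozygosity; mate choice is uniform). Age/weight effect
#' sizes and `beta_het` are on the 2-SD standardized scale, the same scale
#' on which the regression models report estimates, so recovery tests
#' compare like with like.
#'
#' @param n_enclosures,n_years study layout; strata are enclosure x year.
#' @param adults_per_ey adults per enclosure-year (at most 21).
#' @param carryover probability an adult is retained into the next year of
#'   the same enclosure (individuals age, retire after the maximum age and
#'   after 3 appearances).
#' @param age_range,entrant_ages adult ages (years) and ages of new entrants.
#' @param weight_mean,weight_sd named (`F`, `M`) means/SDs of adult weight in
#'   kg; `weight_jitter` is the SD of the year-to-year measurement scatter.
#' @param n_snp_loci,n_msat_loci panel sizes.
#' @param maf_range SNP minor-allele-frequency range (uniform draw).
#' @param msat_allele_range alleles per microsatellite locus (uniform draw,
#'   Dirichlet(1) frequencies).
#' @param missing_rate per-call missing probability.
#' @param alpha baseline log-odds of female breeding success; the default
#'   `qlogis(0.4)` reproduces the ~60% failure rate of group-housed devils.
#' @param beta_age,beta_weight,beta_het female success effects (2-SD scale).
#' @param mechanism mate-choice mechanism, see above.
#' @param beta_dis,d_opt,sigma_opt mechanism parameters; `d_opt = NULL`
#'   defaults to the enclosure mean similarity at simulation time.
#' @param litter_probs probabilities of litter sizes 1--4.
#' @param mechanism_panel panel on which choice operates (`"GW"` or `"MHC"`).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_enclosures = 2L, n_years = 5L, adults_per_ey = 20L,
                       carryover = 0.5,
                       age_range = 2:5, entrant_ages = 2:4,
                       weight_mean = c(F = 7.5, M = 9.5),
                       weight_sd = c(F = 0.8, M = 1.0),
                       weight_jitter = 0.3,
                       n_snp_loci = 1948L, n_msat_loci = 12L,
                       maf_range = c(0.05, 0.5),
                       msat_allele_range = 2:10,
                       missing_rate = 0.02,
                       alpha = stats::qlogis(0.4),
                       beta_age = -1.05, beta_weight = 0, beta_het = 0,
                       mechanism = c("random", "dissimilarity_preference",
                                     "optimum_distance", "het_advantage"),
                       beta_dis = 0, d_opt = NULL, sigma_opt = 0.05,
                       litter_probs = c(0.20, 0.35, 0.30, 0.15),
                       mechanism_panel = c("GW", "MHC")) {
  mechanism <- match.arg(mechanism)
  mechanism_panel <- match.arg(mechanism_panel)
  stopifnot(.is_count(n_enclosures), n_enclosures >= 1,
            .is_count(n_years), n_years >= 1,
            .is_count(adults_per_ey), adults_per_ey >= 2, adults_per_ey <= 21,
            carryover >= 0, carryover <= 1,
            all(age_range >= 1), all(entrant_ages %in% age_range),
            all(weight_mean > 0), all(weight_sd > 0), weight_jitter >= 0,
            .is_count(n_snp_loci), n_snp_loci >= 1,
            .is_count(n_msat_loci), n_msat_loci >= 0,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            all(msat_allele_range >= 2),
            missing_rate >= 0, missing_rate < 1,
            is.finite(alpha), is.finite(beta_age), is.finite(beta_weight),
            is.finite(beta_het), is.finite(beta_dis), sigma_opt > 0,
            length(litter_probs) == 4L, all(litter_probs >= 0),
            sum(litter_probs) > 0)
  structure(
    list(n_enclosures = as.integer(n_enclosures), n_years = as.integer(n_years),
         adults_per_ey = as.integer(adults_per_ey), carryover = carryover,
         age_range = as.integer(age_range), entrant_ages = as.integer(entrant_ages),
         weight_mean = weight_mean, weight_sd = weight_sd,
         weight_jitter = weight_jitter,
         n_snp_loci = as.integer(n_snp_loci), n_msat_loci = as.integer(n_msat_loci),
         maf_range = maf_range, msat_allele_range = as.integer(msat_allele_range),
         missing_rate = missing_rate,
         alpha = alpha, beta_age = beta_age, beta_weight = beta_weight,
         beta_het = beta_het, mechanism = mechanism, beta_dis = beta_dis,
         d_opt = d_opt, sigma_opt = sigma_opt,
         litter_probs = litter_probs / sum(litter_probs),
         mechanism_panel = mechanism_panel),
    class = "sim_config")
}

#' Simulate the roster of a synthetic study
#'
#' Populates each enclosure-year with `adults_per_ey` adults in a roughly
#' even sex ratio. Adults carry over between consecutive years of an
#' enclosure with probability `carryover`, ageing one year, and retire once
#' they pass the maximum age or have appeared three times; vacancies are
#' filled with new entrants. Weights are an individual baseline plus
#' year-to-year scatter. `bred`/`n_offspring` are initialized to 0 and
#' filled in by [simulate_breeding()].
#'
#' @param config a [sim_config()].
#' @param seed RNG seed for this stage.
#' @return a roster `data.frame` (class `roster`).
#' @export
simulate_roster <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  max_age <- max(config$age_range)
  pool <- new.env()
  pool$n <- 0L
  pool$sex <- character(0); pool$base_weight <- numeric(0)
  new_individual <- function(sex, age) {
    pool$n <- pool$n + 1L
    id <- sprintf("D%04d", pool$n)
    pool$sex[id] <- sex
    pool$base_weight[id] <- stats::rnorm(1, config$weight_mean[[sex]],
                                         config$weight_sd[[sex]])
    list(id = id, sex = sex, age = age)
  }
  rows <- list()
  for (e in seq_len(config$n_enclosures)) {
    current <- list()  # list of (id, sex, age); appearances tracked separately
    appearances <- integer(0)
    for (y in seq_len(config$n_years)) {
      ey <- sprintf("E%d_Y%d", e, y)
      if (y > 1L) {
        kept <- list()
        for (ind in current) {
          age2 <- ind$age + 1L
          if (age2 <= max_age && appearances[ind$id] < 3L &&
              stats::runif(1) < config$carryover)
            kept[[length(kept) + 1L]] <- list(id = ind$id, sex = ind$sex, age = age2)
        }
        current <- kept
      }
      # top up, keeping the sex ratio as even as possible
      while (length(current) < config$adults_per_ey) {
        sexes <- vapply(current, function(i) i$sex, character(1L))
        sex <- if (sum(sexes == "F") <= sum(sexes == "M")) "F" else "M"
        age <- sample(config$entrant_ages, 1L)
        current[[length(current) + 1L]] <- new_individual(sex, age)
      }
      for (ind in current) {
        appearances[ind$id] <- if (ind$id %in% names(appearances))
          appearances[[ind$id]] + 1L else 1L
        w <- pool$base_weight[[ind$id]] + stats::rnorm(1, 0, config$weight_jitter)
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = ind$id, enclosure_year = ey, sex = ind$sex,
          age = ind$age, weight = max(w, 2), bred = 0L, n_offspring = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  as_roster(do.call(rbind, rows), where = "simulated roster")
}

#' Simulate genotype panels under Hardy--Weinberg equilibrium
#'
#' SNP panel: per-locus minor (ALT) allele frequencies drawn uniformly from
#' `maf_range` (the lower bound mirroring a MAF > 5% marker filter), REF/ALT
#' nucleotides drawn per locus, genotypes by independent allele draws.
#' Microsatellite panel: 2--10 alleles per locus with Dirichlet(1)
#' frequencies, allele labels as fragment sizes. Calls are then masked as
#' missing at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param ids individual ids to genotype.
#' @param seed RNG seed for this stage.
#' @return list with elements `gw` and `mhc` ([genotype_panel()]s; `mhc` is
#'   `NULL` when `n_msat_loci = 0`) and `snp_freqs` (the true ALT
#'   frequencies, kept for ground-truth checks).
#' @export
simulate_genotypes <- function(config, ids, seed) {
  stopifnot(inherits(config, "sim_config"), length(ids) >= 2L)
  set.seed(seed)
  n <- length(ids)

  nl <- config$n_snp_loci
  loci <- sprintf("snp%04d", seq_len(nl))
  p <- stats::runif(nl, config$maf_range[1], config$maf_range[2])
  refalt <- t(vapply(seq_len(nl), function(i) sample(c("A", "C", "G", "T"), 2L),
                     character(2L)))
  draw <- function() matrix(refalt[cbind(rep(seq_len(nl), each = n),
                                         1L + (stats::runif(n * nl) < rep(p, each = n)))],
                            nrow = n, dimnames = list(ids, loci))
  a1 <- draw(); a2 <- draw()
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * nl) < config$missing_rate, n, nl)
    a1[miss] <- NA_character_; a2[miss] <- NA_character_
  }
  gw <- genotype_panel(a1, a2, "GW")

  mhc <- NULL
  if (config$n_msat_loci > 0L) {
    ml <- config$n_msat_loci
    mloci <- sprintf("mhc%02d", seq_len(ml))
    m1 <- m2 <- matrix(NA_character_, n, ml, dimnames = list(ids, mloci))
    for (j in seq_len(ml)) {
      n_all <- sample(config$msat_allele_range, 1L)
      freqs <- stats::rgamma(n_all, 1)
      freqs <- freqs / sum(freqs)
      labels <- as.character(100L + 2L * seq_len(n_all))
      m1[, j] <- sample(labels, n, replace = TRUE, prob = freqs)
      m2[, j] <- sample(labels, n, replace = TRUE, prob = freqs)
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * ml) < config$missing_rate, n, ml)
      m1[miss] <- NA_character_; m2[miss] <- NA_character_
    }
    mhc <- genotype_panel(m1, m2, "MHC")
  }
  list(gw = gw, mhc = mhc, snp_freqs = stats::setNames(p, loci))
}

#' Simulate breeding outcomes under a mate-choice mechanism
#'
#' Within each enclosure-year, each female breeds with probability
#' `plogis(alpha + beta_age * z_age + beta_weight * z_weight
#' [+ beta_het * z_het])`, where z-values are 2-SD standardized over all
#' females of the study (the scale the regression models estimate on). A
#' successful female's mate is drawn from the enclosure's males with
#' weights set by the configured mechanism, and her litter size from
#' `litter_probs`. The roster's `bred`/`n_offspring` columns are filled in
#' (a male is credited all offspring of his pairings in that
#' enclosure-year).
#'
#' Each enclosure-year uses an independent RNG stream derived from `seed`
#' and the enclosure-year id, so studies can be partially regenerated.
#'
#' @param panels list with `gw` and `mhc` panels (see
#'   [simulate_genotypes()]).
#' @param roster a simulated roster.
#' @param config a [sim_config()].
#' @param seed RNG seed for this stage.
#' @return list: `pairs` (a `breeding_pairs` table) and `roster` (with
#'   outcomes filled in).
#' @export
simulate_breeding <- function(panels, roster, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  panel <- if (config$mechanism_panel == "GW") panels$gw else panels$mhc
  if (is.null(panel)) .fail("mechanism panel '%s' not simulated", config$mechanism_panel)

  fem <- roster$sex == "F"
  z_age <- rep(NA_real_, nrow(roster))
  z_wt <- rep(NA_real_, nrow(roster))
  z_age[fem] <- as.numeric(standardize_2sd(roster$age[fem], "age"))
  z_wt[fem] <- as.numeric(standardize_2sd(roster$weight[fem], "weight"))
  z_het <- rep(0, nrow(roster))
  if (config$mechanism == "het_advantage") {
    h <- smlh(panels$gw)
    hv <- h$h_std[match(roster$individual_id, h$individual_id)]
    z_het[fem] <- as.numeric(standardize_2sd(hv[fem], "h_gw"))
  }
  eta <- config$alpha + config$beta_age * z_age + config$beta_weight * z_wt +
    config$beta_het * z_het

  pair_rows <- list()
  for (ey in unique(roster$enclosure_year)) {
    set.seed(derive_seed(seed, ey))
    in_ey <- roster$enclosure_year == ey
    females <- which(in_ey & fem)
    males <- roster$individual_id[in_ey & !fem]
    if (!length(males)) .fail("%s: no males in enclosure", ey)
    for (i in females) {
      if (stats::runif(1) >= stats::plogis(eta[i])) next
      fid <- roster$individual_id[i]
      w <- .mate_weights(panel, fid, males, config)
      mid <- if (length(males) == 1L) males else sample(males, 1L, prob = w)
      litter <- sample(1:4, 1L, prob = config$litter_probs)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        enclosure_year = ey, female_id = fid, male_id = mid,
        n_offspring = litter, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows)
           else data.frame(enclosure_year = character(0), female_id = character(0),
                           male_id = character(0), n_offspring = integer(0),
                           stringsAsFactors = FALSE)
  class(pairs) <- c("breeding_pairs", "data.frame")

  roster$bred <- 0L
  roster$n_offspring <- 0L
  if (nrow(pairs)) {
    fkey <- paste(pairs$female_id, pairs$enclosure_year)
    rkey <- paste(roster$individual_id, roster$enclosure_year)
    hit <- match(rkey, fkey)
    roster$n_offspring[!is.na(hit)] <- pairs$n_offspring[hit[!is.na(hit)]]
    moff <- tapply(pairs$n_offspring, paste(pairs$male_id, pairs$enclosure_year), sum)
    mhit <- match(rkey, names(moff))
    roster$n_offspring[!is.na(mhit)] <- as.integer(moff[mhit[!is.na(mhit)]])
    roster$bred <- as.integer(roster$n_offspring >= 1L)
  }
  list(pairs = pairs, roster = as_roster(as.data.frame(roster), "simulated roster"))
}

# mechanism-specific mate weights for one female over the enclosure males
.mate_weights <- function(panel, female_id, males, config) {
  if (config$mechanism %in% c("random", "het_advantage") ||
      (config$mechanism == "dissimilarity_preference" && config$beta_dis == 0))
    return(rep(1, length(males)))
  d <- vapply(males, function(m) {
    s <- .dab_core(panel$a1[female_id, ], panel$a2[female_id, ],
                   panel$a1[m, ], panel$a2[m, ])
    if (s$n == 0L) NA_real_ else 2 * s$fab / (s$fa + s$fb)
  }, numeric(1L))
  d[is.na(d)] <- mean(d, na.rm = TRUE)
  if (config$mechanism == "dissimilarity_preference") {
    w <- exp(config$beta_dis * (1 - d))
  } else {
    d_opt <- if (is.null(config$d_opt)) mean(d) else config$d_opt
    w <- exp(-(d - d_opt)^2 / (2 * config$sigma_opt^2))
  }
  w <- w / sum(w)
  if (any(!is.finite(w))) w <- as.numeric(d == min(d))  # beta_dis -> Inf limit
  w
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_roster()], [simulate_genotypes()] and
#' [simulate_breeding()] with per-stage RNG streams derived from the master
#' seed, and bundles the results with the ground-truth parameters.
#'
#' @param config a [sim_config()].
#' @param seed master seed.
#' @return an object of class `synthetic_study`: `gw`, `mhc`, `roster`,
#'   `pairs`, `truth` (config plus master seed and true SNP frequencies).
#' @export
simulate_study <- function(config = sim_config(), seed) {
  if (missing(seed)) .fail("a master seed is required")
  roster <- simulate_roster(config, derive_seed(seed, "roster"))
  ids <- unique(roster$individual_id)
  geno <- simulate_genotypes(config, ids, derive_seed(seed, "genotypes"))
  bred <- simulate_breeding(geno, roster, config, derive_seed(seed, "breeding"))
  structure(
    list(gw = geno$gw, mhc = geno$mhc, roster = bred$roster, pairs = bred$pairs,
         truth = c(unclass(config), list(seed = seed, snp_freqs = geno$snp_freqs))),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d roster entries (%d individuals) across %d enclosure-years\n",
              nrow(x$roster), length(unique(x$roster$individual_id)),
              length(unique(x$roster$enclosure_year))))
  cat(sprintf("  panels: GW %d loci, MHC %s loci; mechanism: %s\n",
              length(x$gw$loci),
              if (is.null(x$mhc)) "0" else length(x$mhc$loci),
              x$truth$mechanism))
  cat(sprintf("  %d successful pairs; %.0f%% of individuals failed to breed\n",
              nrow(x$pairs), 100 * mean(x$roster$bred == 0L)))
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits `gw.vcf` (biallelic SNPs, GT field), `mhc.csv` (two columns per
#' locus), `roster.csv`, `pairs.csv` and a `truth.json` sidecar holding the
#' full generating configuration. [read_study()] reads the files back; the
#' round trip is exact, and regenerating with the same seed reproduces the
#' files byte-for-byte.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_vcf(study$gw, file.path(dir, "gw.vcf"))
  if (!is.null(study$mhc)) .write_two_col(study$mhc, file.path(dir, "mhc.csv"))
  utils::write.csv(study$roster, file.path(dir, "roster.csv"), row.names = FALSE)
  utils::write.csv(study$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  truth <- study$truth
  truth$d_opt <- if (is.null(truth$d_opt)) NA else truth$d_opt
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a study written by [write_study()]
#'
#' @param dir directory containing the study files.
#' @return an object of class `synthetic_study`.
#' @export
read_study <- function(dir) {
  gw <- read_genotypes(file.path(dir, "gw.vcf"), "vcf", panel_id = "GW")
  mhc_path <- file.path(dir, "mhc.csv")
  mhc <- if (file.exists(mhc_path)) read_genotypes(mhc_path, "two_col_csv", "MHC") else NULL
  roster <- read_roster(file.path(dir, "roster.csv"))
  pairs <- read_pairs(file.path(dir, "pairs.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  structure(list(gw = gw, mhc = mhc, roster = roster, pairs = pairs, truth = truth),
            class = "synthetic_study")
}

.write_vcf <- function(panel, path) {
  n_loc <- length(panel$loci)
  ref <- alt <- character(n_loc)
  gt <- matrix("./.", length(panel$individuals), n_loc)
  for (j in seq_len(n_loc)) {
    als <- sort(unique(c(panel$a1[, j], panel$a2[, j])))
    als <- als[!is.na(als)]
    if (length(als) > 2L)
      .fail("locus %s has %d alleles; VCF output supports biallelic loci only",
            panel$loci[j], length(als))
    ref[j] <- if (length(als)) als[1L] else "N"
    alt[j] <- if (length(als) == 2L) als[2L] else "."
    code <- function(a) ifelse(is.na(a), ".", ifelse(a == ref[j], "0", "1"))
    gt[, j] <- paste0(code(panel$a1[, j]), "/", code(panel$a2[, j]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$individuals), collapse = "\t")),
             con)
  body <- paste("1", seq_len(n_loc), panel$loci, ref, alt, ".", "PASS", ".", "GT",
                sep = "\t")
  for (j in seq_len(n_loc))
    body[j] <- paste(c(body[j], gt[, j]), collapse = "\t")
  writeLines(body, con)
}

.write_two_col <- function(panel, path) {
  out <- data.frame(individual_id = panel$individuals, stringsAsFactors = FALSE)
  for (j in seq_along(panel$loci)) {
    out[[paste0(panel$loci[j], ".1")]] <- ifelse(is.na(panel$a1[, j]), "0", panel$a1[, j])
    out[[paste0(panel$loci[j], ".2")]] <- ifelse(is.na(panel$a2[, j]), "0", panel$a2[, j])
  }
  utils::write.csv(out, path, row.names = FALSE)
}
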