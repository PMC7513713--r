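#' Construct a genotype panel
#'
#' A genotype panel holds diploid allele calls for a set of individuals at a
#' named set of loci. Alleles are arbitrary labels (nucleotides for SNPs,
#' fragment sizes for microsatellites); a missing call is represented by `NA`
#' in both allele slots. Half-calls (one allele known) are demoted to missing,
#' since partial genotypes carry no usable information for the similarity and
#' heterozygosity statistics computed downstream.
#'
#' @param a1,a2 character matrices (individuals x loci) holding the two
#'   allele labels of each call; dimnames give individual and locus ids.
#' @param panel_id label for the panel, e.g. `"GW"` or `"MHC"`.
#' @return an object of class `genotype_panel` with elements `panel_id`,
#'   `individuals`, `loci`, `a1`, `a2`. Calls are stored with `a1 <= a2`
#'   (lexicographic) so that panels equal as sets of alleles are identical
#'   objects.
#' @export
genotype_panel <- function(a1, a2, panel_id) {
  if (!is.matrix(a1) || !is.matrix(a2) || !identical(dim(a1), dim(a2)))
    .fail("a1 and a2 must be matrices of identical dimension")
  storage.mode(a1) <- "character"
  storage.mode(a2) <- "character"
  ind <- rownames(a1)
  loci <- colnames(a1)
  if (is.null(ind) || is.null(loci))
    .fail("allele matrices need individual ids as rownames and locus ids as colnames")
  if (anyDuplicated(ind))
    .fail("duplicate individual id: %s", ind[duplicated(ind)][1L])
  if (anyDuplicated(loci))
    .fail("duplicate locus id: %s", loci[duplicated(loci)][1L])
  if (nrow(a1) < 2L) .fail("a genotype panel needs at least 2 individuals")
  if (ncol(a1) < 1L) .fail("a genotype panel needs at least 1 locus")

  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    a1[half] <- NA_character_
    a2[half] <- NA_character_
    warning(sprintf("%d half-call(s) treated as missing", sum(half)), call. = FALSE)
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  structure(
    list(panel_id = as.character(panel_id), individuals = ind, loci = loci,
         a1 = a1, a2 = a2),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("Genotype panel '%s': %d individuals x %d loci (%.1f%% missing calls)\n",
              x$panel_id, length(x$individuals), length(x$loci), 100 * miss))
  invisible(x)
}

#' Subset a genotype panel by individuals and/or loci
#'
#' @param x a [genotype_panel()].
#' @param individuals,loci character vectors of ids to keep (default all).
#' @param ... unused.
#' @export
subset.genotype_panel <- function(x, individuals = x$individuals, loci = x$loci, ...) {
  bad <- setdiff(individuals, x$individuals)
  if (length(bad)) .fail("unknown individual id(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(loci, x$loci)
  if (length(bad)) .fail("unknown locus id(s): %s", paste(bad, collapse = ", "))
  genotype_panel(x$a1[individuals, loci, drop = FALSE],
                 x$a2[individuals, loci, drop = FALSE], x$panel_id)
}

#' Read a genotype panel from file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`wide_csv`}{rows are individuals (first column `individual_id`),
#'     remaining columns are loci; a call is two allele labels separated by
#'     `/` (e.g. `"A/G"`, `"212/216"`) or two concatenated single characters
#'     (`"AG"`); empty, `"."`, `".."` or `"./."` is missing.}
#'   \item{`two_col_csv`}{GenAlEx-style: first column `individual_id`, then
#'     two adjacent columns per locus holding the two alleles; the locus id
#'     is the first column's header stripped of a trailing `.1`/`_1`/`_a`
#'     suffix. `0`, empty or `NA` is missing.}
#'   \item{`vcf`}{biallelic SNP records read with the vcfR package; `GT`
#'     codes are translated to REF/ALT allele labels; records with more than
#'     one ALT allele are rejected.}
#' }
#'
#' @param path file to read.
#' @param format one of `"wide_csv"`, `"two_col_csv"`, `"vcf"`.
#' @param panel_id label for the returned panel; defaults to the file name
#'   without extension.
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("wide_csv", "two_col_csv", "vcf"),
                           panel_id = sub("\\.[^.]*$", "", basename(path))) {
  format <- match.arg(format)
  if (!file.exists(path)) .fail("file not found: %s", path)
  switch(format,
         wide_csv    = .read_wide_csv(path, panel_id),
         two_col_csv = .read_two_col_csv(path, panel_id),
         vcf         = .read_vcf(path, panel_id))
}

.split_call <- function(x, path, line) {
  if (is.na(x) || x %in% c("", ".", "..", "./.", ".|.", "NA"))
    return(c(NA_character_, NA_character_))
  if (grepl("[/|]", x)) {
    parts <- strsplit(x, "[/|]")[[1L]]
  } else if (nchar(x) == 2L) {
    parts <- c(substr(x, 1L, 1L), substr(x, 2L, 2L))
  } else {
    .fail("%s: line %d: cannot parse genotype call '%s'", path, line, x)
  }
  if (length(parts) != 2L)
    .fail("%s: line %d: call '%s' does not have exactly 2 alleles", path, line, x)
  parts[parts %in% c(".", "")] <- NA_character_
  parts
}

.read_wide_csv <- function(path, panel_id) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) .fail("%s: expected an id column plus at least 1 locus column", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) .fail("%s: duplicate individual id '%s'", path, ids[duplicated(ids)][1L])
  loci <- colnames(df)[-1L]
  n <- length(ids)
  a1 <- a2 <- matrix(NA_character_, n, length(loci), dimnames = list(ids, loci))
  for (j in seq_along(loci)) {
    col <- df[[j + 1L]]
    for (i in seq_len(n)) {
      al <- .split_call(col[i], path, i + 1L)
      a1[i, j] <- al[1L]
      a2[i, j] <- al[2L]
    }
  }
  genotype_panel(a1, a2, panel_id)
}

.read_two_col_csv <- function(path, panel_id) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3L || (ncol(df) - 1L) %% 2L != 0L)
    .fail("%s: expected an id column plus an even number of allele columns", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) .fail("%s: duplicate individual id '%s'", path, ids[duplicated(ids)][1L])
  first <- seq(2L, ncol(df), by = 2L)
  loci <- sub("([._][1ab])$", "", colnames(df)[first])
  clean <- function(x) {
    x[x %in% c("", "0", ".", "NA") | is.na(x)] <- NA_character_
    x
  }
  a1 <- sapply(first, function(j) clean(df[[j]]))
  a2 <- sapply(first + 1L, function(j) clean(df[[j]]))
  if (length(ids) == 1L) { a1 <- rbind(a1); a2 <- rbind(a2) }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  genotype_panel(a1, a2, panel_id)
}

.read_vcf <- function(path, panel_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    .fail("%s: multi-allelic record(s) at %s — only biallelic SNPs are supported",
          path, paste(utils::head(fix[multi, "ID"], 3L), collapse = ", "))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  rownames(gt) <- ids
  samples <- colnames(gt)
  if (anyDuplicated(samples))
    .fail("%s: duplicate individual id '%s'", path, samples[duplicated(samples)][1L])
  ref <- fix[, "REF"]
  code_allele <- function(code, l) {
    out <- rep(NA_character_, length(code))
    out[code == "0"] <- ref[l][code == "0"]
    out[code == "1"] <- alt[l][code == "1"]
    out
  }
  g1 <- sub("[/|].*$", "", gt)
  g2 <- sub("^.*[/|]", "", gt)
  g1[is.na(gt)] <- "."
  g2[is.na(gt)] <- "."
  n_loc <- length(ids)
  lidx <- rep(seq_len(n_loc), times = length(samples))
  a1 <- matrix(code_allele(as.vector(g1), lidx), nrow = n_loc)
  a2 <- matrix(code_allele(as.vector(g2), lidx), nrow = n_loc)
  dimnames(a1) <- dimnames(a2) <- list(ids, samples)
  genotype_panel(t(a1), t(a2), panel_id)
}

#' Read a roster table
#'
#' One row per individual per enclosure-year, with the columns
#' `individual_id`, `enclosure_year`, `sex` (`F`/`M`), `age` (integer years,
#' >= 1), `weight` (kg, may be empty), `bred` (0/1) and `n_offspring`
#' (surviving offspring credited to the individual in that enclosure-year).
#' Rows are validated: `bred` must equal 1 exactly when `n_offspring >= 1`,
#' and a female cannot be credited more than 4 offspring (pouch capacity).
#'
#' @param path CSV file.
#' @return a `data.frame` of class `roster`.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) .fail("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sex = "character"))
  as_roster(df, where = path)
}

#' Validate a roster data.frame
#'
#' @param df data.frame with the columns documented in [read_roster()].
#' @param where label used in error messages.
#' @return `df` with class `c("roster", "data.frame")`.
#' @export
as_roster <- function(df, where = "roster") {
  need <- c("individual_id", "enclosure_year", "sex", "age", "bred", "n_offspring")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) .fail("%s: missing column(s): %s", where, paste(miss, collapse = ", "))
  if (!"weight" %in% colnames(df)) df$weight <- NA_real_
  df$individual_id <- as.character(df$individual_id)
  df$enclosure_year <- as.character(df$enclosure_year)
  df$sex <- as.character(df$sex)
  bad <- !df$sex %in% c("F", "M")
  if (any(bad)) .fail("%s: row %d: unknown sex code '%s'", where, which(bad)[1L], df$sex[bad][1L])
  df$age <- as.numeric(df$age)
  bad <- !is.finite(df$age) | df$age < 1 | df$age != round(df$age)
  if (any(bad)) .fail("%s: row %d: age must be an integer >= 1", where, which(bad)[1L])
  df$weight <- as.numeric(df$weight)
  bad <- !is.na(df$weight) & df$weight <= 0
  if (any(bad)) .fail("%s: row %d: weight must be positive", where, which(bad)[1L])
  df$bred <- as.integer(df$bred)
  df$n_offspring <- as.integer(df$n_offspring)
  bad <- is.na(df$bred) | !df$bred %in% c(0L, 1L)
  if (any(bad)) .fail("%s: row %d: bred must be 0 or 1", where, which(bad)[1L])
  bad <- is.na(df$n_offspring) | df$n_offspring < 0L
  if (any(bad)) .fail("%s: row %d: n_offspring must be an integer >= 0", where, which(bad)[1L])
  bad <- df$bred != as.integer(df$n_offspring >= 1L)
  if (any(bad))
    .fail("%s: row %d: bred = %d inconsistent with n_offspring = %d",
          where, which(bad)[1L], df$bred[bad][1L], df$n_offspring[bad][1L])
  bad <- df$sex == "F" & df$n_offspring > 4L
  if (any(bad))
    .fail("%s: row %d: a female cannot have more than 4 offspring", where, which(bad)[1L])
  dup <- duplicated(df[c("individual_id", "enclosure_year")])
  if (any(dup))
    .fail("%s: duplicate roster entry for individual '%s' in '%s'",
          where, df$individual_id[dup][1L], df$enclosure_year[dup][1L])
  class(df) <- c("roster", "data.frame")
  df
}

#' Read a breeding-pair table
#'
#' One row per successful breeding pair per enclosure-year:
#' `enclosure_year`, `female_id`, `male_id`, `n_offspring` (>= 1).
#'
#' @param path CSV file.
#' @return a `data.frame` of class `breeding_pairs`.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) .fail("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("enclosure_year", "female_id", "male_id", "n_offspring")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) .fail("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  df$enclosure_year <- as.character(df$enclosure_year)
  df$female_id <- as.character(df$female_id)
  df$male_id <- as.character(df$male_id)
  df$n_offspring <- as.integer(df$n_offspring)
  if (any(is.na(df$n_offspring) | df$n_offspring < 1L))
    .fail("%s: n_offspring must be an integer >= 1 for a successful pair", path)
  dup <- duplicated(df[c("enclosure_year", "female_id", "male_id")])
  if (any(dup)) .fail("%s: duplicate pair record", path)
  class(df) <- c("breeding_pairs", "data.frame")
  df
}

#' Report roster ids with no genotype in a panel
#'
#' Studies routinely include animals that could not be sequenced; downstream
#' similarity and heterozygosity-based analyses silently lose them, so this
#' reports the mismatch explicitly.
#'
#' @param roster a roster (see [read_roster()]).
#' @param panel a [genotype_panel()].
#' @return character vector of individual ids present in the roster but
#'   absent from the panel (possibly empty).
#' @export
unmatched_ids <- function(roster, panel) {
  setdiff(unique(roster$individual_id), panel$individuals)
}
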