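#' Allele-sharing similarity between a pair of individuals
#'
#' The band-sharing-style similarity
#' \deqn{D_{AB} = \frac{2 F_{AB}}{F_A + F_B}}
#' where, summing over the loci genotyped in both individuals, \eqn{F_A} and
#' \eqn{F_B} are the total numbers of distinct alleles carried by A and B
#' (1 per homozygous locus, 2 per heterozygous locus) and \eqn{F_{AB}} the
#' total number of distinct alleles they share. \eqn{D_{AB} = 1} when the
#' allele sets are identical at every shared locus and 0 when no allele is
#' shared anywhere. Loci missing in either individual contribute to no sum.
#'
#' @param panel a [genotype_panel()].
#' @param id_a,id_b individual ids (by convention female first).
#' @param min_shared_loci minimum number of jointly typed loci for the
#'   similarity to be considered defined (default 1).
#' @return one-row `data.frame`: `female_id`, `male_id`, `panel_id`,
#'   `n_shared_loci`, `d_ab`.
#' @examples
#' a1 <- matrix(c("a","a","c","c"), 2, 2, dimnames = list(c("A","B"), c("L1","L2")))
#' a2 <- matrix(c("b","c","c","d"), 2, 2, dimnames = list(c("A","B"), c("L1","L2")))
#' pair_similarity(genotype_panel(a1, a2, "demo"), "A", "B")  # d_ab = 4/7
#' @export
pair_similarity <- function(panel, id_a, id_b, min_shared_loci = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  for (id in c(id_a, id_b))
    if (!id %in% panel$individuals) .fail("individual '%s' not in panel '%s'", id, panel$panel_id)
  s <- .dab_core(panel$a1[id_a, ], panel$a2[id_a, ], panel$a1[id_b, ], panel$a2[id_b, ])
  if (s$n < min_shared_loci)
    .fail("similarity undefined for pair (%s, %s): %d shared typed loci (min %d)",
          id_a, id_b, s$n, min_shared_loci)
  data.frame(female_id = id_a, male_id = id_b, panel_id = panel$panel_id,
             n_shared_loci = s$n, d_ab = 2 * s$fab / (s$fa + s$fb),
             stringsAsFactors = FALSE)
}

# allele-set arithmetic over shared loci, vectorized across loci.
# Calls are stored with a1 <= a2, so a1 != a2 identifies heterozygotes and
# the shared-allele count per locus is
#   [a1A in {a1B, a2B}] + [a2A distinct from a1A][a2A in {a1B, a2B}].
.dab_core <- function(a1A, a2A, a1B, a2B) {
  sh <- !is.na(a1A) & !is.na(a1B)
  n <- sum(sh)
  if (n == 0L) return(list(n = 0L, fa = 0L, fb = 0L, fab = 0L))
  a1A <- a1A[sh]; a2A <- a2A[sh]; a1B <- a1B[sh]; a2B <- a2B[sh]
  fa <- n + sum(a1A != a2A)
  fb <- n + sum(a1B != a2B)
  fab <- sum((a1A == a1B | a1A == a2B) +
             ((a2A != a1A) & (a2A == a1B | a2A == a2B)))
  list(n = n, fa = fa, fb = fb, fab = fab)
}

#' Similarity between every opposite-sex pair of one enclosure-year
#'
#' Computes [pair_similarity()] for each female x male combination of the
#' supplied roster rows that have genotypes in the panel. Individuals without
#' a genotype, and pairs with fewer than `min_shared_loci` jointly typed
#' loci, are skipped; their counts are attached as attributes.
#'
#' @param panel a [genotype_panel()].
#' @param roster roster rows for a single enclosure-year.
#' @param min_shared_loci see [pair_similarity()].
#' @return a `data.frame` of class `pair_similarity_table` with columns
#'   `female_id`, `male_id`, `panel_id`, `n_shared_loci`, `d_ab`, and
#'   attributes `enclosure_year`, `n_skipped_pairs`, `ungenotyped`.
#' @export
similarity_matrix <- function(panel, roster, min_shared_loci = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  ey <- unique(roster$enclosure_year)
  if (length(ey) != 1L) .fail("roster rows must belong to a single enclosure-year")
  females <- roster$individual_id[roster$sex == "F"]
  males <- roster$individual_id[roster$sex == "M"]
  drop <- setdiff(c(females, males), panel$individuals)
  if (length(drop))
    message(sprintf("%s/%s: %d roster individual(s) without genotypes skipped: %s",
                    ey, panel$panel_id, length(drop), paste(drop, collapse = ", ")))
  females <- intersect(females, panel$individuals)
  males <- intersect(males, panel$individuals)
  if (!length(females) || !length(males))
    .fail("%s: no opposite-sex pair with genotypes in panel '%s'", ey, panel$panel_id)

  combos <- expand.grid(female_id = females, male_id = males,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(combos)
  nsh <- integer(n); dab <- numeric(n)
  for (i in seq_len(n)) {
    s <- .dab_core(panel$a1[combos$female_id[i], ], panel$a2[combos$female_id[i], ],
                   panel$a1[combos$male_id[i], ], panel$a2[combos$male_id[i], ])
    nsh[i] <- s$n
    dab[i] <- if (s$n > 0L) 2 * s$fab / (s$fa + s$fb) else NA_real_
  }
  keep <- nsh >= min_shared_loci & !is.na(dab)
  skipped <- sum(!keep)
  if (skipped > 0L)
    message(sprintf("%s/%s: %d pair(s) with undefined similarity skipped",
                    ey, panel$panel_id, skipped))
  out <- data.frame(combos[keep, , drop = FALSE],
                    panel_id = panel$panel_id,
                    n_shared_loci = nsh[keep], d_ab = dab[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    .fail("%s: no valid opposite-sex pair in panel '%s'", ey, panel$panel_id)
  attr(out, "enclosure_year") <- ey
  attr(out, "n_skipped_pairs") <- skipped
  attr(out, "ungenotyped") <- drop
  class(out) <- c("pair_similarity_table", "data.frame")
  out
}
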