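#' Standardized multilocus heterozygosity (sMLH)
#'
#' For individual \eqn{i}, standardized heterozygosity is the number of loci
#' at which \eqn{i} is heterozygous divided by the sum, over the loci at
#' which \eqn{i} was genotyped, of the mean observed heterozygosity of each
#' locus across all genotyped individuals:
#' \deqn{H_i = \frac{h_i}{\sum_{l \in typed(i)} \bar{H}_l}}
#' Standardizing by the typed loci only makes the metric robust to missing
#' data: with complete data the population mean of \eqn{H_i} is exactly 1.
#'
#' Loci typed in no individual are dropped with a warning. An individual
#' typed at no locus (or whose typed loci are all monomorphic for
#' heterozygosity, giving a zero denominator) gets `h_std = NA` and is
#' flagged for exclusion downstream.
#'
#' @param panel a [genotype_panel()].
#' @return a `data.frame` with one row per individual: `individual_id`,
#'   `panel_id`, `n_typed`, `h_raw`, `h_std`.
#' @examples
#' a1 <- matrix(c("A","A","A","C"), 2, 2, dimnames = list(c("i1","i2"), c("L1","L2")))
#' a2 <- matrix(c("G","A","T","C"), 2, 2, dimnames = list(c("i1","i2"), c("L1","L2")))
#' smlh(genotype_panel(a1, a2, "demo"))  # h_std = 2 and 0
#' @export
smlh <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  het <- panel$a1 != panel$a2          # NA where call missing
  typed_per_locus <- colSums(!is.na(het))
  if (any(typed_per_locus == 0L)) {
    warning(sprintf("%d locus/loci typed in no individual dropped from sMLH",
                    sum(typed_per_locus == 0L)), call. = FALSE)
    keep <- typed_per_locus > 0L
    het <- het[, keep, drop = FALSE]
  }
  hbar <- colMeans(het, na.rm = TRUE)
  typed <- !is.na(het)
  h_raw <- rowSums(het, na.rm = TRUE)
  denom <- as.vector(typed %*% hbar)
  h_std <- ifelse(denom > 0, h_raw / denom, NA_real_)
  n_typed <- rowSums(typed)
  if (any(n_typed == 0L))
    warning(sprintf("individual(s) with no typed locus: %s",
                    paste(panel$individuals[n_typed == 0L], collapse = ", ")),
            call. = FALSE)
  data.frame(individual_id = panel$individuals,
             panel_id = panel$panel_id,
             n_typed = n_typed,
             h_raw = as.integer(h_raw),
             h_std = h_std,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
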