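#' Standardize a predictor by two standard deviations
#'
#' Gelman-style input scaling: \eqn{(x - \bar{x}) / (2 s)} with \eqn{s} the
#' sample standard deviation. Dividing by 2 SD (rather than 1) puts
#' continuous predictors on the same footing as binary ones, so averaged
#' coefficient magnitudes are directly comparable.
#'
#' @param x numeric vector with at least 2 distinct non-missing values.
#' @param name predictor name used in error messages.
#' @return the standardized vector, with attributes `center` (mean) and
#'   `scale` (2 SD) recording the constants for later back-transformation.
#' @export
standardize_2sd <- function(x, name = deparse(substitute(x))) {
  v <- x[!is.na(x)]
  if (length(v) < 2L) .fail("predictor '%s': need at least 2 values", name)
  s <- stats::sd(v)
  if (s == 0) .fail("predictor '%s' is constant (zero SD)", name)
  out <- (x - mean(v)) / (2 * s)
  attr(out, "center") <- mean(v)
  attr(out, "scale") <- 2 * s
  out
}

#' Within-group relative standardization of roster predictors
#'
#' For testing whether an individual's standing *relative to its
#' competitors* predicts breeding success, each predictor is converted to a
#' within-group z-score on the 2-SD scale: the difference from the group
#' mean divided by twice the group SD, where a group is one enclosure-year
#' x sex combination (the set of same-sex animals an individual competes
#' with). A predictor that is constant within a group is set to 0 for that
#' group with a warning (no relative information).
#'
#' @param roster a roster `data.frame` (see [read_roster()]), optionally
#'   carrying extra numeric predictor columns such as `h_gw`, `h_mhc`.
#' @param vars predictor columns to standardize (defaults to those of
#'   `age`, `weight`, `h_gw`, `h_mhc` present in `roster`).
#' @param group columns defining the competitive group.
#' @return `roster` with added columns `z.<var>`.
#' @export
standardize_within_group <- function(roster, vars = NULL,
                                     group = c("enclosure_year", "sex")) {
  if (is.null(vars)) vars <- intersect(c("age", "weight", "h_gw", "h_mhc"),
                                       colnames(roster))
  if (!length(vars)) .fail("no predictor columns to standardize")
  gid <- interaction(roster[group], drop = TRUE)
  if (any(table(gid) < 2L))
    .fail("every %s group needs at least 2 members", paste(group, collapse = " x "))
  zero_sd <- character(0)
  for (v in vars) {
    x <- roster[[v]]
    z <- rep(NA_real_, length(x))
    for (g in levels(gid)) {
      i <- which(gid == g)
      xi <- x[i]
      m <- mean(xi, na.rm = TRUE)
      s <- stats::sd(xi[!is.na(xi)])
      if (is.na(s) || s == 0) {
        z[i] <- ifelse(is.na(xi), NA_real_, 0)
        zero_sd <- c(zero_sd, sprintf("%s/%s", v, g))
      } else {
        z[i] <- (xi - m) / (2 * s)
      }
    }
    roster[[paste0("z.", v)]] <- z
  }
  if (length(zero_sd))
    warning(sprintf("zero within-group SD, relative value set to 0: %s",
                    paste(zero_sd, collapse = ", ")), call. = FALSE)
  roster
}
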