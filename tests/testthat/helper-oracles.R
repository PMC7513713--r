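# Independent oracles and fixture builders. Everything here is deliberately
# naive (per-locus loops, set arithmetic, grid search) so it cannot share a
# bug with the vectorized implementations it checks.

# allele-set similarity, one locus at a time
oracle_dab <- function(panel, ida, idb) {
  fa <- fb <- fab <- 0L
  n <- 0L
  for (l in panel$loci) {
    ca <- c(panel$a1[ida, l], panel$a2[ida, l])
    cb <- c(panel$a1[idb, l], panel$a2[idb, l])
    if (anyNA(ca) || anyNA(cb)) next
    ua <- unique(ca); ub <- unique(cb)
    n <- n + 1L
    fa <- fa + length(ua)
    fb <- fb + length(ub)
    fab <- fab + length(intersect(ua, ub))
  }
  if (n == 0L) return(NULL)
  list(n = n, d_ab = 2 * fab / (fa + fb))
}

# naive sMLH: double loop over individuals and loci
oracle_smlh <- function(panel) {
  het <- panel$a1 != panel$a2
  hbar <- colMeans(het, na.rm = TRUE)
  out <- numeric(length(panel$individuals))
  for (i in seq_along(panel$individuals)) {
    num <- denom <- 0
    for (l in seq_along(panel$loci)) {
      if (is.na(het[i, l])) next
      num <- num + het[i, l]
      denom <- denom + hbar[l]
    }
    out[i] <- if (denom > 0) num / denom else NA_real_
  }
  out
}

random_panel <- function(n_ind, n_loci, alleles = c("a", "b", "c", "d"),
                         missing_rate = 0.1, panel_id = "rnd") {
  ids <- sprintf("i%03d", seq_len(n_ind))
  loci <- sprintf("L%03d", seq_len(n_loci))
  draw <- function() matrix(sample(alleles, n_ind * n_loci, replace = TRUE),
                            n_ind, n_loci, dimnames = list(ids, loci))
  a1 <- draw(); a2 <- draw()
  if (missing_rate > 0) {
    miss <- matrix(runif(n_ind * n_loci) < missing_rate, n_ind, n_loci)
    a1[miss] <- NA_character_
    a2[miss] <- NA_character_
  }
  genotype_panel(a1, a2, panel_id)
}

# small panel from explicit genotype strings like "a/b", "." for missing
panel_from_strings <- function(calls, panel_id = "toy") {
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("L%d", seq_len(ncol(calls)))
  split1 <- function(x) if (x == ".") NA_character_ else strsplit(x, "/")[[1]][1]
  split2 <- function(x) if (x == ".") NA_character_ else strsplit(x, "/")[[1]][2]
  a1 <- apply(calls, c(1, 2), split1)
  a2 <- apply(calls, c(1, 2), split2)
  genotype_panel(a1, a2, panel_id)
}

# similarity table for synthetic per-enclosure tests, bypassing genotypes
make_sims_table <- function(d, n_females = NULL, ey = "E1", panel_id = "GW") {
  n <- length(d)
  if (is.null(n_females)) n_females <- max(1L, floor(sqrt(n)))
  stopifnot(n %% n_females == 0L)
  n_males <- n %/% n_females
  out <- expand.grid(female_id = sprintf("F%02d", seq_len(n_females)),
                     male_id = sprintf("M%02d", seq_len(n_males)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$panel_id <- panel_id
  out$n_shared_loci <- 10L
  out$d_ab <- d
  attr(out, "enclosure_year") <- ey
  class(out) <- c("pair_similarity_table", "data.frame")
  out
}

# iteratively refined grid search for the ML solution of a GLM with
# canonical link; independent of IRLS
grid_mle <- function(X, y, family = c("binomial", "poisson"), size = NULL,
                     iters = 10, span = 5) {
  family <- match.arg(family)
  p <- ncol(X)
  ll <- function(beta) {
    eta <- drop(X %*% beta)
    switch(family,
           binomial = if (is.null(size)) sum(dbinom(y, 1, plogis(eta), log = TRUE))
                      else sum(dbinom(y, size, plogis(eta), log = TRUE)),
           poisson = sum(dpois(y, exp(eta), log = TRUE)))
  }
  center <- rep(0, p)
  width <- span
  for (it in seq_len(iters)) {
    grids <- lapply(seq_len(p), function(j)
      seq(center[j] - width, center[j] + width, length.out = 11))
    gr <- as.matrix(expand.grid(grids))
    vals <- apply(gr, 1, ll)
    center <- gr[which.max(vals), ]
    width <- width * 0.3
  }
  unname(center)
}
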