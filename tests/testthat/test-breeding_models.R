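test_that("2-SD standardization matches hand arithmetic", {
  # values (2,2,4,4): mean 3, sample SD sqrt(4/3); (x-3)/(2*sqrt(4/3))
  z <- standardize_2sd(c(2, 2, 4, 4))
  expect_equal(as.numeric(z), c(-1, -1, 1, 1) / (2 * sqrt(4 / 3)))
  expect_equal(as.numeric(z), c(-0.4330127, -0.4330127, 0.4330127, 0.4330127),
               tolerance = 1e-6)
  expect_equal(attr(z, "center"), 3)
  expect_equal(attr(z, "scale"), 2 * sqrt(4 / 3))
})

test_that("a variable with mean 0 and SD 0.5 is a fixed point of 2-SD standardization", {
  x <- c(-0.5, 0, 0.5) / sqrt(1 / 2) / 2  # mean 0, sd 0.5 after scaling
  x <- x / (2 * sd(x)) * 1                # force sd exactly 0.5
  x <- (x - mean(x)) / (2 * sd(x))        # now mean 0, sd 0.5
  expect_equal(sd(x), 0.5)
  expect_equal(as.numeric(standardize_2sd(x)), x)
})

test_that("constant predictors are rejected by name", {
  expect_error(standardize_2sd(rep(3, 5), name = "age"), "age.*constant|constant.*age")
})

test_that("within-group standardization centres each group and handles degenerate groups", {
  roster <- data.frame(
    individual_id = sprintf("d%d", 1:8),
    enclosure_year = rep(c("E1", "E2"), each = 4),
    sex = rep(c("F", "F", "M", "M"), 2),
    age = c(2L, 4L, 3L, 3L, 2L, 3L, 4L, 5L),
    weight = c(7, 8, 9, 10, 7.5, 6.5, 9.5, 10.5),
    bred = 0L, n_offspring = 0L)
  expect_warning(z <- standardize_within_group(roster, vars = c("age", "weight")),
                 "zero within-group SD")
  # E1 females, ages (2,4): mean 3, SD sqrt(2), so z = +/- 1/(2*sqrt(2))
  expect_equal(z$z.age[1:2], c(-1, 1) / (2 * sqrt(2)))
  expect_equal(z$z.age[1:2], c(-0.3535534, 0.3535534), tolerance = 1e-6)
  # E1 males have identical ages: relative age 0 with warning
  expect_equal(z$z.age[3:4], c(0, 0))
  # group-wise means of every standardized predictor are 0
  g <- interaction(z$enclosure_year, z$sex)
  expect_true(all(abs(tapply(z$z.weight, g, mean)) < 1e-12))
  expect_true(all(abs(tapply(z$z.age, g, mean)) < 1e-12))
})

test_that("intercept-only fits recover closed-form estimates", {
  d <- data.frame(bred = rep(c(1L, 0L), each = 10), n_offspring = 0L)
  f <- fit_breeding_glm(d, "binomial")
  expect_equal(unname(coef(f)), 0, tolerance = 1e-8)

  counts <- c(1L, 2L, 3L, 2L, 4L, 3L, 1L, 2L)
  d <- data.frame(bred = 1L, n_offspring = counts)
  f <- fit_breeding_glm(d, "poisson")
  expect_equal(unname(coef(f)), log(mean(counts)), tolerance = 1e-8)
})

test_that("the AICc identity holds on every fit", {
  set.seed(31)
  d <- data.frame(age = rnorm(60), weight = rnorm(60))
  d$bred <- rbinom(60, 1, plogis(0.3 - d$age))
  d$n_offspring <- ifelse(d$bred == 1L, sample(1:4, 60, TRUE), 0L)
  for (preds in list(character(0), "age", c("age", "weight"))) {
    f <- fit_breeding_glm(d, "binomial", preds)
    expect_equal(f$aicc,
                 -2 * f$loglik + 2 * f$k + 2 * f$k * (f$k + 1) / (f$n - f$k - 1))
    expect_equal(f$k, length(preds) + 1L)
  }
})

test_that("fixed-effects fits match the brute-force likelihood-grid oracle to 1e-4", {
  set.seed(32)
  n <- 80
  d <- data.frame(age = rnorm(n))
  d$bred <- rbinom(n, 1, plogis(0.4 - 1.2 * d$age))
  f <- fit_breeding_glm(d, "binomial", "age")
  o <- grid_mle(cbind(1, d$age), d$bred, "binomial")
  expect_equal(unname(coef(f)), o, tolerance = 1e-4)

  d$n_offspring <- rpois(n, exp(0.5 + 0.4 * d$age))
  d$bred <- 1L
  f <- fit_breeding_glm(d, "poisson", "age")
  o <- grid_mle(cbind(1, d$age), d$n_offspring, "poisson")
  expect_equal(unname(coef(f)), o, tolerance = 1e-4)

  # binomial out of 4 for female offspring counts
  d$n_offspring <- rbinom(n, 4, plogis(0.2 + 0.8 * d$age))
  d <- d[d$n_offspring >= 1, ]
  d$bred <- 1L
  f <- fit_breeding_glm(d, "binomial_out_of_4", "age")
  o <- grid_mle(cbind(1, d$age), d$n_offspring, "binomial", size = 4)
  expect_equal(unname(coef(f)), o, tolerance = 1e-4)
})

test_that("random-intercept variance is recovered: zero when absent, close when present", {
  set.seed(33)
  make_grouped <- function(tau, n_grp = 24, per_grp = 15) {
    g <- rep(sprintf("g%02d", seq_len(n_grp)), each = per_grp)
    u <- rnorm(n_grp, 0, tau)[as.integer(factor(g))]
    data.frame(grp = g, bred = rbinom(n_grp * per_grp, 1, plogis(0.2 + u)),
               n_offspring = 0L)
  }
  v0 <- replicate(8, fit_breeding_glm(make_grouped(0), "binomial",
                                      random = "grp")$ranef_var)
  expect_lt(median(v0), 0.05)
  v1 <- replicate(16, fit_breeding_glm(make_grouped(1), "binomial",
                                       random = "grp")$ranef_var)
  expect_lt(abs(median(v1) - 1), 0.3)
  # k counts the variance parameter
  f <- fit_breeding_glm(make_grouped(1), "binomial", random = "grp")
  expect_equal(f$k, 2L)
  expect_equal(f$aicc, aicc(f$loglik, f$k, f$n))
})

test_that("model averaging: forced single-predictor case and weight normalization", {
  set.seed(34)
  n <- 400
  d <- data.frame(age = sample(2:5, n, TRUE))
  za <- (d$age - mean(d$age)) / (2 * sd(d$age))
  d$bred <- rbinom(n, 1, plogis(0.1 - 2.5 * za))
  d$n_offspring <- d$bred
  av <- model_average(d, "binomial", "age")
  expect_equal(sum(av$weights), 1)
  # the age model dominates: full-average equals its coefficient, RI = 1
  if (length(av$top_models) == 1L) {
    expect_equal(av$table$ri[av$table$term == "age"], 1)
    expect_equal(av$table$estimate[av$table$term == "age"],
                 unname(coef(av$top_models[[1]])["age"]))
  }
})

test_that("a strong predictor earns RI 1 while pure noise is shrunk", {
  set.seed(35)
  n <- 500
  d <- data.frame(age = sample(2:5, n, TRUE), weight = rnorm(n, 8, 1))
  za <- (d$age - mean(d$age)) / (2 * sd(d$age))
  d$bred <- rbinom(n, 1, plogis(0.2 - 2 * za))
  d$n_offspring <- d$bred
  av <- model_average(d, "binomial", c("age", "weight"))
  tab <- av$table
  expect_equal(tab$ri[tab$term == "age"], 1)
  expect_lt(tab$ri[tab$term == "weight"], 1)
  expect_lt(abs(tab$estimate[tab$term == "weight"]),
            abs(tab$estimate[tab$term == "age"]))
  # full average shrinks the noise coefficient relative to conditional average
  avc <- model_average(d, "binomial", c("age", "weight"), method = "conditional")
  w_full <- tab$estimate[tab$term == "weight"]
  w_cond <- avc$table$estimate[avc$table$term == "weight"]
  if (w_cond != 0) expect_lte(abs(w_full), abs(w_cond) + 1e-12)
  # ri_prop is a proportion over the top set
  m <- length(av$top_models)
  expect_true(all(tab$ri_prop[-1] * m == round(tab$ri_prop[-1] * m)))
  # enumeration is complete: 4 subsets fitted
  expect_equal(nrow(av$selection), 4L)
})

test_that("fitted probabilities back-transform correctly and respond to the link", {
  set.seed(36)
  n <- 300
  d <- data.frame(age = sample(2:5, n, TRUE), weight = rnorm(n, 8, 1))
  za <- (d$age - mean(d$age)) / (2 * sd(d$age))
  d$bred <- rbinom(n, 1, plogis(0 - 1.5 * za))
  d$n_offspring <- d$bred
  av <- model_average(d, "binomial", c("age", "weight"))
  p <- suppressWarnings(predict(av, data.frame(age = 2:5, weight = mean(d$weight))))
  # negative age coefficient: probabilities strictly decreasing in age
  expect_true(all(diff(as.numeric(p)) < 0))
  # intercept-only back-transform: all-zero coefficients give 0.5
  av0 <- av
  av0$table$estimate[] <- 0
  expect_equal(as.numeric(predict(av0, data.frame(age = 3, weight = 8))), 0.5)
})
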