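test_that("dichotomization thresholds the trait with the boundary as case", {
  lab <- dichotomize(c(130, 150), 140)
  expect_identical(as.integer(lab), c(0L, 1L))
  expect_identical(as.integer(dichotomize(c(140, 139), 140)), c(1L, 0L))
  expect_error(dichotomize(c(130, 150), 100), "threshold")  # all cases
  expect_error(dichotomize(c(130, 150), 200), "threshold")  # all controls
})

test_that("the logistic fit recovers the closed-form 2x2 odds ratio", {
  # cases: 30 carriers / 20 non; controls: 10 carriers / 40 non -> OR = 6
  x <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  status <- c(rep(1, 50), rep(0, 50))
  fit <- single_variant_or(x, status)
  expect_equal(fit$or, (30 * 40) / (20 * 10), tolerance = 1e-6)
  expect_false(fit$fallback)
})

test_that("a null variant has log odds ratio within 3 standard errors of zero", {
  set.seed(41)
  l <- 1000L
  x <- rbinom(l, 2L, 0.3)
  status <- rbinom(l, 1L, 0.25)
  fit <- single_variant_or(x, status)
  se <- summary(glm(status ~ x, family = binomial()))$coefficients[2L, 2L]
  expect_lt(abs(fit$log_or), 3 * se)
})

test_that("separated variants fall back to a penalized fit with finite weight", {
  # the single carrier is a case: ML separates
  x <- c(2, rep(0, 59))
  status <- c(1, rep(c(1, 0), c(14, 45)))
  fit <- single_variant_or(x, status)
  expect_true(fit$fallback)
  expect_true(is.finite(fit$or) && fit$or > 0)
})

test_that("genotype risk value weights follow the average-relative-risk formula", {
  expect_equal(as.numeric(grv_weights(0.37, 1)), c(1, 1, 1))
  gw <- grv_weights(0.2, 2)
  expect_equal(attr(gw, "arr"), 1.44, tolerance = 1e-12)
  expect_equal(as.numeric(gw), c(1, 2, 4) / 1.44, tolerance = 1e-12)
  expect_error(grv_weights(0.2, 0), "positive")
  expect_error(grv_weights(0.7, 2), "0.5")
})

test_that("grv weights average to one under Hardy-Weinberg proportions", {
  for (p in c(0.001, 0.01, 0.1, 0.25, 0.5))
    for (or in c(0.2, 0.5, 1, 2, 5, 20)) {
      w <- grv_weights(p, or)
      hw <- (1 - p)^2 * w[1L] + 2 * p * (1 - p) * w[2L] + p^2 * w[3L]
      expect_equal(unname(hw), 1, tolerance = 1e-12)
    }
})

test_that("allele-frequency weights are inverse-frequency, max-normalized", {
  w <- af_weights(c(0.01, 0.25), l = 100L)
  expect_weight_vector(w, "af")
  expect_equal(w[1L] / w[2L], sqrt(0.25 * 0.75) / sqrt(0.01 * 0.99),
               tolerance = 1e-10)
  expect_equal(max(w), 1)
  expect_equal(as.numeric(af_weights(rep(0.05, 4), 10L)), rep(1, 4))
  w2 <- af_weights(c(0.05, 0.2, 0.5, 0), 50L)
  expect_equal(which.min(w2[1:3]), 3L)  # p = 0.5 gets the smallest weight
  expect_equal(w2[4L], 0)               # monomorphic
})

test_that("log-odds-ratio weights are the signed log OR with an absolute option", {
  expect_equal(as.numeric(lor_weights(log(c(1, exp(1), 0.5)))),
               c(0, 1, -log(2)))
  expect_equal(as.numeric(lor_weights(log(0.5), absolute = TRUE)), log(2))
  # complementing the labels flips the fitted log OR (direction adjustment)
  set.seed(13)
  x <- rbinom(200, 2L, 0.2)
  status <- rbinom(200, 1L, plogis(-1 + 0.8 * x))
  f1 <- single_variant_or(x, status)
  f2 <- single_variant_or(x, 1L - status)
  expect_equal(f1$log_or, -f2$log_or, tolerance = 1e-6)
})

test_that("optimal weights match the correlation / spread formula", {
  w <- ow_weights(c(-1, 0, 1), cbind(c(-1, 0, 1)))
  expect_equal(as.numeric(w), 1 / sqrt(2), tolerance = 1e-12)
  # perfect positive correlation: w = 1/sqrt(sum of squares)
  set.seed(3)
  x <- rnorm(30)
  w2 <- ow_weights(2 * x, cbind(x))
  expect_equal(as.numeric(w2), 1 / sqrt(sum((x - mean(x))^2)),
               tolerance = 1e-10)
  # negating the trait flips the sign
  expect_equal(as.numeric(ow_weights(-2 * x, cbind(x))), -as.numeric(w2),
               tolerance = 1e-10)
  # doubling the genotype spread halves the weight at fixed correlation
  expect_equal(as.numeric(ow_weights(2 * x, cbind(2 * x))),
               as.numeric(w2) / 2, tolerance = 1e-10)
  expect_error(ow_weights(rep(1, 5), cbind(rnorm(5))), "zero variance")
})

test_that("null optimal weights shrink toward zero with founder count", {
  set.seed(17)
  l <- 500L
  y <- rnorm(l)
  x <- matrix(rbinom(l * 5L, 2L, 0.2), ncol = 5L)
  w <- ow_weights(y, x)
  implied_rho <- abs(w) * sqrt(colSums(scale(x, scale = FALSE)^2))
  expect_true(all(implied_rho < 4 / sqrt(l)))
})

test_that("functional-prediction weights pass scores through with median imputation", {
  tab <- FunctionalScoreTable(data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v5", "v6", "v7"),
    gene = c("G", "H", "G", "G", "G", "G", "G"),
    annotation = c("other", "nonsynonymous", "nonsynonymous",
                   "nonsynonymous", "nonsynonymous", "nonsynonymous",
                   "other"),
    score = c(0.9, 0.35, 0.2, 0.8, 1.0, NA, NA),
    stringsAsFactors = FALSE))
  variants <- data.frame(id = paste0("v", 1:7), stringsAsFactors = FALSE)
  w <- fp_weights(tab, variants)
  expect_equal(as.numeric(w),
               c(0,      # synonymous despite having a score
                 0.35,   # pass-through
                 0.2, 0.8, 1.0,
                 0.8,    # imputed median of gene G scores {0.2, 0.8, 1.0}
                 0))
})

test_that("nonsynonymous variants in genes without any score get weight zero", {
  tab <- FunctionalScoreTable(data.frame(
    variant_id = c("v1", "v2"), gene = c("G1", "G2"),
    annotation = "nonsynonymous", score = c(NA, 0.5),
    stringsAsFactors = FALSE))
  expect_message(
    w <- fp_weights(tab, data.frame(id = c("v1", "v2"))),
    "without any")
  expect_equal(as.numeric(w), c(0, 0.5))
})

test_that("every scheme assigns weight zero to founder-monomorphic variants", {
  cohort <- simulate_cohort(sim_config(n_families = 60L, M = 8L,
                                       frac_rare = 0.2, frac_low = 0.2),
                            seed = 5L)
  cohort$geno$x[, 1L] <- 0L
  cohort$geno$variants$maf[1L] <- 0
  resid <- residualize_cohort(cohort)
  for (s in c("af", "lor", "ow", "fp")) {
    w <- compute_weights(cohort, resid, scheme = s)
    expect_equal(as.numeric(w)[1L], 0, info = s)
  }
  gw <- compute_weights(cohort, resid, scheme = "grv")
  expect_equal(unname(gw$w[, 1L]), c(0, 0, 0))
})

test_that("weights round-trip through TSV and can be injected into the test", {
  cohort <- simulate_cohort(sim_config(n_families = 60L, M = 10L), seed = 19L)
  resid <- residualize_cohort(cohort)
  w <- compute_weights(cohort, resid, scheme = "af")
  path <- tempfile(fileext = ".tsv")
  write_weights(w, cohort$geno, path)
  w2 <- read_weights(path, cohort$geno)
  expect_equal(as.numeric(w2), as.numeric(w), tolerance = 1e-12)
  expect_identical(attr(w2, "scheme"), "af")
  r_injected <- run_fbatv(cohort, weights = w2)
  r_direct <- run_fbatv(cohort, scheme = "af")
  expect_equal(r_injected$Z, r_direct$Z, tolerance = 1e-12)
  unlink(path)
})
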