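make_two_trio_cohort <- function(x_by_iid, traits) {
  ids <- c("F1", "M1", "O1", "F2", "M2", "O2")
  ped <- Pedigree(data.frame(
    fid = rep(c("T1", "T2"), each = 3L),
    iid = ids,
    father = c(NA, NA, "F1", NA, NA, "F2"),
    mother = c(NA, NA, "M1", NA, NA, "M2"),
    sex = rep(c(1L, 2L, 1L), 2L), stringsAsFactors = FALSE))
  geno <- toy_geno(matrix(x_by_iid, ncol = 1L), ids)
  toy_cohort(ped, geno, toy_pheno(ids, traits))
}

test_that("single-term contributions follow (y - mu)(x - midparent)", {
  # trio 1: parents (1,1), offspring 2, trait residual +1 -> contribution +1
  # trio 2: parents (0,0), offspring 0, trait residual -1 -> contribution  0
  co <- make_two_trio_cohort(c(1L, 1L, 2L, 0L, 0L, 0L),
                             traits = c(0, 0, 1, 0, 0, -1))
  resid <- residualize_cohort(co, covariates = character(0),
                              standardize = "none")
  scores <- variant_scores(resid, decompose_nuclear(co$ped), co$geno)
  # mean-centering leaves offspring residuals symmetric around mu = 0
  expect_equal(scores$mu, mean(resid$y[c("O1", "O2")]))
  expect_equal(unname(scores$contrib[scores$offspring == "O1", 1L]),
               (resid$y[["O1"]] - scores$mu) * 1)
  expect_equal(unname(scores$contrib[scores$offspring == "O2", 1L]), 0)
})

test_that("offspring at their Mendelian expectation contribute zero", {
  ids <- c("F", "M", "O")
  cases <- list(c(0L, 2L, 1L), c(2L, 2L, 2L), c(0L, 0L, 0L))
  for (g in cases) {
    co <- toy_cohort(trio_ped(), toy_geno(matrix(g, ncol = 1L), ids),
                     toy_pheno(ids, c(0, 0, 3)))
    resid <- residualize_cohort(co, covariates = character(0),
                                standardize = "none")
    scores <- variant_scores(resid, decompose_nuclear(co$ped), co$geno)
    expect_equal(unname(scores$U), 0)
  }
})

test_that("combining is linear and pedigree contributions add up to W", {
  contrib <- matrix(c(0.5, 0.1, -0.2,
                      0.2, -0.1, 0.0), ncol = 2L)
  sc <- toy_scores(contrib, fid = c("P1", "P1", "P2"))
  w1 <- fbatv:::new_weight_vector(c(1, 1), "af")
  cmb <- combine(sc, w1)
  expect_equal(cmb$W, sum(contrib))
  expect_equal(sum(cmb$D), cmb$W)
  expect_equal(cmb$D, c(sum(contrib[1:2, ]), sum(contrib[3, ])))
  # doubling the weights doubles W and every D_k
  cmb2 <- combine(sc, fbatv:::new_weight_vector(c(2, 2), "af"))
  expect_equal(cmb2$W, 2 * cmb$W)
  expect_equal(cmb2$D, 2 * cmb$D)
  # single variant with unit weight: W = U_1
  sc1 <- toy_scores(contrib[, 1L, drop = FALSE], fid = c("P1", "P1", "P2"))
  expect_equal(combine(sc1, fbatv:::new_weight_vector(1, "af"))$W,
               sc1$U[1L])
})

test_that("empirical variance is the sum of squared pedigree contributions", {
  expect_equal(empirical_variance(c(1, -1)), 2)
  expect_equal(empirical_variance(c(0.6, -0.2)), 0.4)
  expect_equal(empirical_variance(numeric(0)), 0)
  expect_equal(empirical_variance(c(3)), 9)
  expect_equal(empirical_variance(c(1, 3), centered = TRUE), 2)
  # two pedigrees with contributions 0.6 and -0.2 combine to W = 0.4
  contrib <- matrix(c(0.6, -0.2), ncol = 1L)
  sc <- toy_scores(contrib, fid = c("P1", "P2"))
  expect_equal(combine(sc, fbatv:::new_weight_vector(1, "af"))$W, 0.4)
})

test_that("Z is invariant to positive weight rescaling and flips under negation", {
  cohort <- simulate_cohort(sim_config(n_families = 80L, M = 15L), seed = 9L)
  resid <- residualize_cohort(cohort)
  scores <- variant_scores(resid, decompose_nuclear(cohort$ped),
                           cohort$geno)
  w <- compute_weights(cohort, resid, scheme = "af")
  z_of <- function(wv) {
    cmb <- combine(scores, wv)
    cmb$W / sqrt(empirical_variance(cmb$D))
  }
  z1 <- z_of(w)
  z7 <- z_of(fbatv:::new_weight_vector(7 * as.numeric(w), "af"))
  zn <- z_of(fbatv:::new_weight_vector(-as.numeric(w), "af"))
  expect_equal(z7, z1, tolerance = 1e-12)
  expect_equal(zn, -z1, tolerance = 1e-12)
})

test_that("Z is invariant under trait translation", {
  cohort <- simulate_cohort(sim_config(n_families = 80L, M = 15L), seed = 10L)
  res1 <- run_fbatv(cohort, scheme = "af")
  shifted <- cohort
  shifted$pheno$trait <- shifted$pheno$trait + 250
  res2 <- run_fbatv(shifted, scheme = "af")
  expect_equal(res2$Z, res1$Z, tolerance = 1e-9)
})

test_that("on unrelated trios the empirical variance equals a brute-force per-trio sum", {
  cohort <- simulate_cohort(sim_config(n_families = 50L, M = 10L), seed = 12L)
  resid <- residualize_cohort(cohort)
  fams <- decompose_nuclear(cohort$ped)
  scores <- variant_scores(resid, fams, cohort$geno)
  w <- compute_weights(cohort, resid, scheme = "af")
  cmb <- combine(scores, w)
  # brute force: loop over trios, recompute each contribution from scratch
  x <- cohort$geno$x
  brute <- vapply(fams, function(f) {
    o <- f$offspring[1L]
    dev <- x[o, ] - (x[f$father, ] + x[f$mother, ]) / 2
    hetero <- x[f$father, ] == 1L | x[f$mother, ] == 1L
    dev[!hetero] <- 0
    sum(as.numeric(w) * (resid$y[[o]] - scores$mu) * dev)
  }, numeric(1))
  expect_equal(empirical_variance(cmb$D), sum(brute^2), tolerance = 1e-10)
})

test_that("untestable regions return reason codes instead of errors", {
  ids <- c("F", "M", "O")
  # parents homozygous everywhere: no informative transmissions
  co <- toy_cohort(trio_ped(),
                   toy_geno(matrix(c(0L, 0L, 0L), ncol = 1L), ids,
                            maf = 0.1),
                  toy_pheno(ids, c(1, 2, 3)))
  res <- suppressWarnings(run_fbatv(co, scheme = "af",
                                    config = fbatv_config(covariates = character(0))))
  expect_true(res$untestable)
  expect_match(res$reason, "variance|weights|families")
  expect_true(is.na(res$p_value))
})

test_that("null Z statistics are standard normal across replicates", {
  set.seed(2024)
  seeds <- sample.int(1e6, 120L)
  cfg <- sim_config(n_families = 60L, M = 12L, frac_rare = 0.4,
                    frac_low = 0.3)
  z <- vapply(seeds, function(s) {
    run_fbatv(simulate_cohort(cfg, seed = s), scheme = "af")$Z
  }, numeric(1))
  z <- z[!is.na(z)]
  expect_gt(length(z), 100L)
  ks <- suppressWarnings(ks.test(z, pnorm))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
})

test_that("the Mendelian resampling oracle matches the normal approximation", {
  cohort <- simulate_cohort(sim_config(n_families = 150L, M = 20L),
                            seed = 4L)
  set.seed(77)
  rp <- mendelian_resample_pvalue(cohort, scheme = "af", B = 800L)
  mc_se <- sqrt(rp$p_normal * (1 - rp$p_normal) / rp$B)
  expect_lt(abs(rp$p_empirical - rp$p_normal), 4 * mc_se + 0.02)
})
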