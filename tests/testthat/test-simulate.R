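test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_families = 30L, M = 10L)
  a <- simulate_cohort(cfg, seed = 123L)
  b <- simulate_cohort(cfg, seed = 123L)
  expect_identical(a$geno$x, b$geno$x)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$scores, b$scores)
  c <- simulate_cohort(cfg, seed = 124L)
  expect_false(identical(a$geno$x, c$geno$x))
})

test_that("the realized MAF spectrum honours the configured rare fraction", {
  cfg <- sim_config(n_families = 300L, M = 1000L, frac_rare = 0.70,
                    frac_low = 0.13)
  co <- simulate_cohort(cfg, seed = 8L)
  maf <- co$geno$variants$maf
  expect_true(all(maf >= 0 & maf <= 0.5))
  frac_rare <- mean(maf < 0.01)
  expect_gt(frac_rare, 0.65)
  expect_lt(frac_rare, 0.75)
})

test_that("gene dropping reproduces Mendelian segregation frequencies", {
  # two het parents, many offspring: genotypes near (1/4, 1/2, 1/4)
  n_off <- 1e5L
  ped <- Pedigree(data.frame(
    fid = "B", iid = c("F", "M", sprintf("o%06d", seq_len(n_off))),
    father = c(NA, NA, rep("F", n_off)),
    mother = c(NA, NA, rep("M", n_off)),
    sex = c(1L, 2L, rep(1L, n_off)), stringsAsFactors = FALSE))
  fx <- matrix(c(1L, 1L), ncol = 1L, dimnames = list(c("F", "M"), NULL))
  set.seed(55)
  X <- gene_drop(ped, fx)
  off <- X[-(1:2), 1L]
  freq <- tabulate(off + 1L, nbins = 3L) / n_off
  se <- sqrt(c(3, 2, 3) / 16 / n_off)
  expect_true(all(abs(freq - c(1, 2, 1) / 4) < 3 * se))
  # homozygous parents breed true
  fx2 <- matrix(c(2L, 2L), ncol = 1L, dimnames = list(c("F", "M"), NULL))
  expect_true(all(gene_drop(ped, fx2) == 2L))
})

test_that("offspring allele frequencies track founder frequencies in expectation", {
  co <- simulate_cohort(sim_config(n_families = 300L, M = 300L,
                                   frac_rare = 0.3, frac_low = 0.3),
                        seed = 14L)
  fo <- founders(co$ped)
  off <- setdiff(rownames(co$geno$x), fo)
  p_f <- colMeans(co$geno$x[fo, ]) / 2
  p_o <- colMeans(co$geno$x[off, ]) / 2
  d <- p_o - p_f
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1e-3)
})

test_that("null-mode traits are independent of the genotyped variants", {
  co <- simulate_cohort(sim_config(n_families = 300L, M = 1000L), seed = 6L)
  fo <- founders(co$ped)
  y <- tapply(co$pheno$trait, co$pheno$iid, mean)[fo]
  x <- co$geno$x[fo, ]
  keep <- apply(x, 2L, function(v) var(v) > 0)
  rho <- suppressWarnings(cor(as.numeric(y), x[, keep]))
  l <- length(fo)
  expect_lt(mean(abs(rho) > 3 / sqrt(l)), 0.01)
})

test_that("sibling traits are uncorrelated when heritability is zero", {
  cfg <- sim_config(n_families = 1500L, structure = "nuclear",
                    n_offspring = 2L, h2 = 0, M = 2L,
                    covar_effects = c(age = 0, sex = 0, med = 0))
  co <- simulate_cohort(cfg, seed = 30L)
  y <- tapply(co$pheno$trait, co$pheno$iid, mean)
  sib1 <- y[paste0(sprintf("F%05d", 1:1500), "_3")]
  sib2 <- y[paste0(sprintf("F%05d", 1:1500), "_4")]
  expect_lt(abs(cor(sib1, sib2)), 3 / sqrt(1500))
})

test_that("the midparent regression recovers the configured heritability", {
  cfg <- sim_config(n_families = 5000L, M = 2L)
  co <- simulate_cohort(cfg, seed = 18L)
  est <- midparent_slope(co)
  expect_lt(abs(est$slope - 0.68), 4 * est$se)
})

test_that("power mode scales causal effects to the target variance explained", {
  cfg <- sim_config_map4()
  co <- simulate_cohort(cfg, seed = 25L)
  expect_length(co$truth$causal_ids, cfg$n_causal)
  expect_gt(co$truth$realized_tve, 0.055)
  expect_lt(co$truth$realized_tve, 0.075)
  # the truth record reproduces the genetic score exactly
  idx <- match(co$truth$causal_ids, co$geno$variants$id)
  score <- drop(co$geno$x[, idx] %*% co$truth$beta)
  expect_equal(var(score), co$truth$var_genetic, tolerance = 1e-12)
})

test_that("a requested TVE incompatible with the heritability errors", {
  expect_error(sim_config(h2 = 0.68, tve = 0.4), "below 1 - h2")
})

test_that("simulated score tables exercise imputation as configured", {
  cfg <- sim_config(n_families = 50L, M = 40L, tve = 0.05,
                    frac_missing_score = 0)
  co <- simulate_cohort(cfg, seed = 2L)
  ns <- co$scores$annotation == "nonsynonymous"
  expect_false(anyNA(co$scores$score[ns]))
  cfg2 <- sim_config(n_families = 50L, M = 40L, tve = 0.05,
                     frac_missing_score = 0.5)
  co2 <- simulate_cohort(cfg2, seed = 2L)
  ns2 <- co2$scores$annotation == "nonsynonymous"
  expect_gt(sum(is.na(co2$scores$score[ns2])), 0L)
  # imputed fp weights equal the per-gene median of the available scores
  w <- fp_weights(co2$scores, co2$geno$variants)
  med <- median(co2$scores$score[ns2], na.rm = TRUE)
  missing_ns <- which(ns2 & is.na(co2$scores$score))
  expect_equal(as.numeric(w)[missing_ns], rep(med, length(missing_ns)))
})

test_that("three-generation pedigrees gene-drop consistently", {
  cfg <- sim_config(n_families = 40L, structure = "threegen", M = 15L)
  co <- simulate_cohort(cfg, seed = 44L)
  expect_identical(length(founders(co$ped)), 40L * 4L)
  fams <- decompose_nuclear(co$ped)
  expect_identical(length(fams), 40L * 3L)
  # round-trip through the readers without Mendelian errors
  dir <- tempfile("tg")
  write_cohort(co, dir)
  expect_silent(back <- read_cohort(file.path(dir, "genotypes.vcf"),
                                    file.path(dir, "pedigree.ped"),
                                    file.path(dir, "phenotypes.tsv")))
  unlink(dir, recursive = TRUE)
})
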