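#' Normal-approximation binomial confidence interval for a rejection rate
#'
#' `alpha +/- 1.96 * sqrt(alpha * (1 - alpha) / R)`, rounded to three
#' decimals; the lower bound may be negative at small `alpha`.  This is the
#' interval against which empirical type I error rates are judged "under
#' control".
#'
#' @param alpha nominal significance level in (0, 1).
#' @param R number of replicates.
#' @return Numeric vector `c(lower, upper)`.
#' @export
binomial_ci <- function(alpha, R) {
  stopifnot(R >= 1L, alpha > 0, alpha <= 1)
  half <- 1.96 * sqrt(alpha * (1 - alpha) / R)
  round(c(lower = alpha - half, upper = alpha + half), 3L)
}

run_replicates <- function(config, schemes, R, seed,
                           test_config = fbatv_config()) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, R)
  pmat <- matrix(NA_real_, nrow = R, ncol = length(schemes),
                 dimnames = list(NULL, schemes))
  for (r in seq_len(R)) {
    cohort <- simulate_cohort(config, seed = seeds[r])
    res <- fbatv_all(cohort, schemes = schemes, config = test_config)
    pmat[r, ] <- vapply(res, function(z) z$p_value, numeric(1))
  }
  pmat
}

summarize_replicates <- function(pmat, levels) {
  R <- nrow(pmat)
  rows <- list()
  for (s in colnames(pmat)) {
    p <- pmat[, s]
    n_untestable <- sum(is.na(p))
    if (n_untestable / R > 0.05)
      stop("scheme ", s, ": ", n_untestable, "/", R,
           " untestable replicates (more than 5%)")
    Reff <- R - n_untestable
    for (lv in levels) {
      ci <- binomial_ci(lv, Reff)
      k <- sum(p <= lv, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = s, level = lv, rejections = k, R = Reff,
        untestable = n_untestable, rate = k / Reff,
        ci_lower = ci[[1L]], ci_upper = ci[[2L]],
        in_ci = k / Reff >= ci[[1L]] & k / Reff <= ci[[2L]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pvalues") <- pmat
  class(out) <- c("ReplicateSummary", "data.frame")
  out
}

#' Empirical type I error over replicated null simulations
#'
#' Simulates `R` independent null cohorts (a heritable trait uninfluenced
#' by any genotyped variant), runs the test under each scheme, and reports
#' the fraction of two-sided p-values at or below each nominal level,
#' flagged against the corresponding [binomial_ci].  Replicates where a
#' scheme is untestable are excluded from its denominator; more than 5% of
#' them is an error.
#'
#' @param config a [sim_config] with `tve = 0`.
#' @param schemes weighting schemes to evaluate.
#' @param R number of replicates (200 by convention).
#' @param levels nominal significance levels.
#' @param seed integer seed governing the whole replicate schedule.
#' @param test_config a [fbatv_config] passed to the test.
#' @return A `ReplicateSummary` data frame (scheme x level) with the
#'   p-value matrix attached as attribute `"pvalues"`.
#' @export
type_one_error <- function(config = sim_config(),
                           schemes = c("af", "grv", "lor", "ow", "fp"),
                           R = 200L, levels = c(0.1, 0.05, 0.01),
                           seed = 1L, test_config = fbatv_config()) {
  if (config$tve > 0)
    stop("type I error needs a null configuration (tve = 0)")
  pmat <- run_replicates(config, schemes, R, seed, test_config)
  summarize_replicates(pmat, levels)
}

#' Empirical power over replicated causal simulations
#'
#' Same machinery as [type_one_error] on a power-mode configuration
#' (`tve > 0`); rejection rates are empirical power.  Pairwise scheme
#' comparisons with paired Monte-Carlo standard errors are available via
#' [compare_power].
#'
#' @inheritParams type_one_error
#' @param config a [sim_config] with `tve > 0`.
#' @export
power_experiment <- function(config, schemes = c("af", "grv", "lor", "ow", "fp"),
                             R = 200L, levels = c(0.1, 0.05, 0.01),
                             seed = 1L, test_config = fbatv_config()) {
  if (!(config$tve > 0))
    warning("tve = 0: power collapses to the type I error rate")
  pmat <- run_replicates(config, schemes, R, seed, test_config)
  summarize_replicates(pmat, levels)
}

#' Paired power difference between two schemes
#'
#' Uses the per-replicate rejection indicators stored in a
#' `ReplicateSummary`, so the Monte-Carlo standard error accounts for the
#' pairing of schemes within replicates.
#'
#' @param summary a result of [type_one_error] or [power_experiment].
#' @param scheme1,scheme2 scheme labels to compare.
#' @param level nominal significance level.
#' @return List with `rate1`, `rate2`, `diff` (`rate1 - rate2`) and its
#'   paired Monte-Carlo `se`.
#' @export
compare_power <- function(summary, scheme1, scheme2, level = 0.05) {
  pmat <- attr(summary, "pvalues")
  stopifnot(!is.null(pmat), scheme1 %in% colnames(pmat),
            scheme2 %in% colnames(pmat))
  cc <- !is.na(pmat[, scheme1]) & !is.na(pmat[, scheme2])
  i1 <- as.numeric(pmat[cc, scheme1] <= level)
  i2 <- as.numeric(pmat[cc, scheme2] <= level)
  d <- i1 - i2
  list(rate1 = mean(i1), rate2 = mean(i2), diff = mean(d),
       se = stats::sd(d) / sqrt(length(d)), n = length(d))
}

#' Offspring-on-midparent regression slope
#'
#' Estimates narrow-sense heritability from a cohort of families: the
#' covariate-adjusted offspring trait is regressed on the midparent
#' (average of the two parents') adjusted trait.  Under the additive model
#' the slope equals `h2`.
#'
#' @param cohort an `FbatvCohort`.
#' @param covariates covariates to adjust for first.
#' @return List with `slope`, its `se` and the number of offspring used.
#' @export
midparent_slope <- function(cohort, covariates = c("age", "sex", "med")) {
  resid <- residualize_cohort(cohort, covariates = covariates)
  fams <- Filter(function(f) f$complete, decompose_nuclear(cohort$ped))
  y <- resid$y
  off <- unlist(lapply(fams, `[[`, "offspring"))
  fa <- rep(vapply(fams, `[[`, character(1), "father"),
            vapply(fams, function(f) length(f$offspring), integer(1)))
  mo <- rep(vapply(fams, `[[`, character(1), "mother"),
            vapply(fams, function(f) length(f$offspring), integer(1)))
  mid <- (y[fa] + y[mo]) / 2
  yo <- y[off]
  cc <- !is.na(mid) & !is.na(yo)
  fit <- stats::lm(yo[cc] ~ mid[cc])
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2L, 1L]), se = unname(sm[2L, 2L]), n = sum(cc))
}
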