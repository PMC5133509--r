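#' Configuration for the FBAT-v pipeline
#'
#' @param covariates covariate column names used for residualization and
#'   for the covariate-adjusted logistic fits.
#' @param standardize which residuals are scaled to unit SD
#'   (see [residualize_cohort]).
#' @param threshold case threshold on the raw trait for dichotomization
#'   (e.g. 140 for systolic blood pressure); `NULL` (default) uses the
#'   founder trait quantile `threshold_quantile`.
#' @param threshold_quantile founder-trait quantile used when `threshold`
#'   is `NULL` (default 0.75).
#' @param lor_absolute use `|log OR|` rather than the signed log odds ratio.
#' @param grv_covariates adjust the genotype-risk-value logistic fits for
#'   covariates (default `FALSE`: the marginal fit).
#' @param centered_variance center pedigree contributions before summing
#'   squares (default `FALSE`: contributions have mean zero under the null).
#' @param region region label attached to results.
#' @return A list of class `fbatv_config`.
#' @export
fbatv_config <- function(covariates = c("age", "sex", "med"),
                         standardize = "trait",
                         threshold = NULL,
                         threshold_quantile = 0.75,
                         lor_absolute = FALSE,
                         grv_covariates = FALSE,
                         centered_variance = FALSE,
                         region = NULL) {
  structure(list(covariates = covariates, standardize = standardize,
                 threshold = threshold,
                 threshold_quantile = threshold_quantile,
                 lor_absolute = lor_absolute,
                 grv_covariates = grv_covariates,
                 centered_variance = centered_variance,
                 region = region),
            class = "fbatv_config")
}

#' Per-variant score contributions over nuclear families
#'
#' For every offspring in a complete nuclear family (both parents
#' genotyped) with a trait residual, the contribution at variant `m` is
#' `(y~ - mu) * (x - (g_f + g_m)/2)`: the covariate fit on the genotype
#' side cancels exactly, so only raw genotypes enter the deviation.  Terms
#' with missing offspring genotype, missing parent genotype at that
#' variant, or uninformative parental pairs (`Var(x | parents) = 0`)
#' contribute exactly 0.  `mu` is the mean trait residual over the tested
#' offspring.
#'
#' @param resid a [residualize_cohort] result.
#' @param families list of nuclear families from [decompose_nuclear].
#' @param geno the [GenotypeMatrix].
#' @return An `FbatvScores` object: per-variant totals `U`, the
#'   offspring-by-variant contribution matrix, offspring bookkeeping
#'   (pedigree and nuclear-family keys, parental rows) and `mu`.
#' @export
variant_scores <- function(resid, families, geno) {
  x <- geno$x
  ids <- rownames(x)
  fams <- Filter(function(f) f$complete &&
                   f$father %in% ids && f$mother %in% ids, families)
  off <- character(0); fa <- character(0); mo <- character(0)
  fid <- character(0); fkey <- character(0)
  for (f in fams) {
    keep <- f$offspring[f$offspring %in% ids &
                          !is.na(resid$y[f$offspring])]
    if (length(keep) == 0L) next
    off <- c(off, keep)
    fa <- c(fa, rep(f$father, length(keep)))
    mo <- c(mo, rep(f$mother, length(keep)))
    fid <- c(fid, rep(f$fid, length(keep)))
    fkey <- c(fkey, rep(paste(f$father, f$mother, sep = "\r"),
                        length(keep)))
  }
  M <- ncol(x)
  if (length(off) == 0L) {
    return(structure(list(U = rep(0, M), contrib = matrix(0, 0, M),
                          offspring = off, fid = fid, fkey = fkey,
                          xo = matrix(NA_integer_, 0, M),
                          xf = matrix(NA_integer_, 0, M),
                          xm = matrix(NA_integer_, 0, M),
                          informative = matrix(FALSE, 0, M),
                          mu = NA_real_, n_families = 0L),
                     class = "FbatvScores"))
  }
  xo <- x[off, , drop = FALSE]
  xf <- x[fa, , drop = FALSE]
  xm <- x[mo, , drop = FALSE]
  yo <- resid$y[off]
  mu <- mean(yo)
  ep <- (xf + xm) / 2
  tv <- (xf / 2) * (1 - xf / 2) + (xm / 2) * (1 - xm / 2)
  informative <- !is.na(tv) & tv > 0
  dev <- xo - ep
  dev[is.na(dev) | !informative] <- 0
  contrib <- (yo - mu) * dev
  structure(list(U = colSums(contrib), contrib = contrib,
                 offspring = off, fid = fid, fkey = fkey,
                 xo = xo, xf = xf, xm = xm,
                 informative = informative, mu = mu,
                 n_families = length(unique(fkey))),
            class = "FbatvScores")
}

#' Combine per-variant scores with weights
#'
#' `W = sum_m w_m U_m` for per-variant weights; for a `GrvWeightSet` the
#' genotype-level weight of the offspring's own genotype multiplies each
#' offspring-variant term.  Also returns the per-pedigree contributions
#' `D_k` (which sum exactly to `W`), the independent units of the
#' empirical variance.
#'
#' @param scores an `FbatvScores` object.
#' @param weights a `WeightVector` or `GrvWeightSet`.
#' @return List with `W`, named vector `D` of per-pedigree contributions,
#'   per-variant weighted scores `WU` (`NA` for grv, whose weights are
#'   genotype-level), and the informative-family count.
#' @export
combine <- function(scores, weights) {
  contrib <- scores$contrib
  if (inherits(weights, "GrvWeightSet")) {
    stopifnot(ncol(weights$w) == ncol(contrib))
    wmat <- genotype_weight_matrix(weights, scores$xo)
    wc <- wmat * contrib
    used <- apply(weights$w != 0, 2L, any)
    per_off <- rowSums(wc)
    WU <- rep(NA_real_, ncol(contrib))
  } else {
    stopifnot(length(weights) == ncol(contrib))
    w <- as.numeric(weights)
    used <- w != 0
    per_off <- drop(contrib %*% w)
    WU <- w * scores$U
  }
  W <- sum(per_off)
  D <- if (length(per_off) > 0L)
    tapply(per_off, scores$fid, sum) else numeric(0)
  inf_entry <- scores$informative &
    matrix(used, nrow = nrow(contrib), ncol = ncol(contrib), byrow = TRUE)
  inf_fam <- if (nrow(contrib) > 0L)
    length(unique(scores$fkey[rowSums(inf_entry) > 0L])) else 0L
  list(W = W, D = as.numeric(D), pedigrees = names(D), WU = WU,
       n_informative = inf_fam, any_weight = any(used))
}

# per-offspring genotype-level weights; missing genotype -> 0
genotype_weight_matrix <- function(weights, xo) {
  idx_col <- col(xo)
  wmat <- matrix(0, nrow = nrow(xo), ncol = ncol(xo))
  okg <- !is.na(xo)
  wmat[okg] <- weights$w[cbind(xo[okg] + 1L, idx_col[okg])]
  wmat
}

#' Empirical variance of the combined score
#'
#' Pedigrees, not nuclear families, are the independent units: nuclear
#' families carved from one pedigree share transmitted haplotypes when
#' linkage is present, so the variance is estimated as the sum of squared
#' per-pedigree contributions.  Contributions have expectation zero under
#' the null, which justifies the uncentered sum (a centered version is
#' available via `centered`).
#'
#' @param D numeric vector of per-pedigree contributions.
#' @param centered subtract the mean contribution first (default `FALSE`).
#' @return The empirical variance (a scalar).
#' @export
empirical_variance <- function(D, centered = FALSE) {
  if (length(D) == 0L) return(0)
  if (centered) D <- D - mean(D)
  sum(D^2)
}

#' Run the weighted family-based rare-variant test
#'
#' Orchestrates residualization, founder-based weight computation,
#' per-family score assembly, weighting, empirical variance and the normal
#' test: `Z = W / sqrt(Var(W))`, with a two-sided p-value from `N(0, 1)`.
#' Degenerate regions (no informative families, all-zero weights, zero
#' variance) return an untestable result with a reason code rather than an
#' error.
#'
#' @param cohort an `FbatvCohort`.
#' @param scheme weighting scheme: `"af"`, `"grv"`, `"lor"`, `"ow"`, `"fp"`.
#' @param config a [fbatv_config].
#' @param resid optionally a precomputed [residualize_cohort] result.
#' @param weights optionally a precomputed `WeightVector` or `GrvWeightSet`
#'   (e.g. loaded with [read_weights]), bypassing `scheme`'s computation.
#' @return A `FbatvResult`.
#' @export
run_fbatv <- function(cohort, scheme = "af", config = fbatv_config(),
                      resid = NULL, weights = NULL) {
  if (is.null(weights))
    return(fbatv_all(cohort, schemes = scheme, config = config,
                     resid = resid)[[scheme]])
  if (is.null(resid))
    resid <- residualize_cohort(cohort, covariates = config$covariates,
                                standardize = config$standardize)
  scores <- variant_scores(resid, decompose_nuclear(cohort$ped),
                           cohort$geno)
  region <- config$region
  if (is.null(region)) region <- "region"
  finalize_result(scores, weights, scheme, region, config)
}

#' Run several weighting schemes on one cohort
#'
#' Residualization and the per-family scores are shared across schemes.
#'
#' @inheritParams run_fbatv
#' @param schemes character vector of schemes.
#' @return Named list of `FbatvResult` objects.
#' @export
fbatv_all <- function(cohort, schemes = c("af", "grv", "lor", "ow", "fp"),
                      config = fbatv_config(), resid = NULL) {
  if (is.null(resid))
    resid <- residualize_cohort(cohort, covariates = config$covariates,
                                standardize = config$standardize)
  fams <- decompose_nuclear(cohort$ped)
  scores <- variant_scores(resid, fams, cohort$geno)
  region <- config$region
  if (is.null(region)) {
    g <- unique(stats::na.omit(cohort$geno$variants$gene))
    region <- if (length(g) == 1L) g else "region"
  }
  out <- lapply(schemes, function(s) {
    weights <- compute_weights(cohort, resid, scheme = s, config = config)
    finalize_result(scores, weights, s, region, config)
  })
  stats::setNames(out, schemes)
}

finalize_result <- function(scores, weights, scheme, region, config) {
  res <- list(region = region, scheme = scheme, U = scores$U,
              mu = scores$mu, n_families = scores$n_families,
              n_variants = length(scores$U),
              n_informative = 0L, W = NA_real_, var_w = NA_real_,
              Z = NA_real_, p_value = NA_real_,
              untestable = TRUE, reason = NA_character_,
              weights = weights)
  if (scores$n_families == 0L) {
    res$reason <- "no complete families with tested offspring"
    return(structure(res, class = "FbatvResult"))
  }
  cmb <- combine(scores, weights)
  res$W <- cmb$W
  res$n_informative <- cmb$n_informative
  if (!cmb$any_weight) {
    res$reason <- "all weights are zero"
    return(structure(res, class = "FbatvResult"))
  }
  v <- empirical_variance(cmb$D, centered = isTRUE(config$centered_variance))
  res$var_w <- v
  if (!(v > 0)) {
    res$reason <- "zero empirical variance"
    return(structure(res, class = "FbatvResult"))
  }
  res$Z <- cmb$W / sqrt(v)
  res$p_value <- 2 * stats::pnorm(-abs(res$Z))
  res$untestable <- FALSE
  if (length(cmb$D) < 2L) {
    res$degenerate <- TRUE
    warning("single contributing pedigree: Z is degenerate (+/-1)")
  }
  structure(res, class = "FbatvResult")
}

#' @exportS3Method base::print
print.FbatvResult <- function(x, ...) {
  if (x$untestable) {
    cat(sprintf("FBAT-v [%s] %s: untestable (%s)\n",
                x$scheme, x$region, x$reason))
  } else {
    cat(sprintf(
      "FBAT-v [%s] %s: W=%.4g Var=%.4g Z=%.3f p=%.4g (%d/%d informative families, %d variants)\n",
      x$scheme, x$region, x$W, x$var_w, x$Z, x$p_value,
      x$n_informative, x$n_families, x$n_variants))
  }
  invisible(x)
}

#' Turn one or more results into a tidy table
#'
#' @param results an `FbatvResult` or list of them.
#' @return Data frame with one row per result.
#' @export
results_table <- function(results) {
  if (inherits(results, "FbatvResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(region = r$region, scheme = r$scheme,
               n_variants = r$n_variants,
               n_informative_families = r$n_informative,
               W = r$W, Var = r$var_w, Z = r$Z, p = r$p_value,
               untestable = r$untestable,
               stringsAsFactors = FALSE)
  }))
}

#' Mendelian-resampling check of the normal approximation
#'
#' Holding founders, traits, weights and family structure fixed, offspring
#' genotypes are re-dropped from their parents (each parent re-transmits
#' each allele with probability 1/2) and the combined score is recomputed.
#' The empirical two-sided tail probability of `|W|` is an oracle for the
#' normal-approximation p-value `2 * (1 - Phi(|Z|))`.
#'
#' @param cohort an `FbatvCohort`.
#' @param scheme weighting scheme.
#' @param config a [fbatv_config].
#' @param B number of resamples (default 2000).
#' @param chunk resamples drawn per block (memory control).
#' @return List with `p_empirical`, `p_normal`, `W_obs`, `B`.
#' @export
mendelian_resample_pvalue <- function(cohort, scheme = "af",
                                      config = fbatv_config(),
                                      B = 2000L, chunk = 250L) {
  resid <- residualize_cohort(cohort, covariates = config$covariates,
                              standardize = config$standardize)
  fams <- decompose_nuclear(cohort$ped)
  scores <- variant_scores(resid, fams, cohort$geno)
  weights <- compute_weights(cohort, resid, scheme = scheme, config = config)
  res <- finalize_result(scores, weights, scheme, "resample", config)
  if (res$untestable) stop("region untestable: ", res$reason)

  n <- nrow(scores$contrib)
  M <- ncol(scores$contrib)
  yo <- resid$y[scores$offspring] - scores$mu
  pf <- c(scores$xf / 2)
  pm <- c(scores$xm / 2)
  ep <- (pf + pm)
  mask <- is.na(pf) | is.na(pm) | !c(scores$informative)
  pf[is.na(pf) | mask] <- 0
  pm[is.na(pm) | mask] <- 0
  ep[is.na(ep)] <- 0
  is_grv <- inherits(weights, "GrvWeightSet")
  yo_nm <- rep(yo, M)  # column-major replication over variants
  if (!is_grv) {
    A <- yo_nm * rep(as.numeric(weights), each = n)
  } else {
    colidx <- rep(seq_len(M), each = n)
  }
  nm <- n * M
  W_b <- numeric(0)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    t1 <- stats::rbinom(nm * b, 1L, rep(pf, b))
    t2 <- stats::rbinom(nm * b, 1L, rep(pm, b))
    xb <- t1 + t2
    dev <- xb - rep(ep, b)
    dev[rep(mask, b)] <- 0
    if (!is_grv) {
      Wc <- colSums(matrix(dev * rep(A, b), nrow = nm, ncol = b))
    } else {
      wb <- weights$w[cbind(xb + 1L, rep(colidx, b))]
      Wc <- colSums(matrix(dev * wb * rep(yo_nm, b), nrow = nm, ncol = b))
    }
    W_b <- c(W_b, Wc)
    done <- done + b
  }
  list(p_empirical = mean(abs(W_b) >= abs(res$W) * (1 - 1e-12)),
       p_normal = res$p_value, W_obs = res$W, Z_obs = res$Z, B = B)
}
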