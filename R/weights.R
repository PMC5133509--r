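#' Dichotomize a continuous trait into case/control labels
#'
#' Individuals with trait at or above the threshold are cases (the boundary
#' counts as a case).  Intended for founders, whose labels feed the
#' single-variant logistic fits behind the genotype-risk-value and
#' log-odds-ratio weights; the classic exemplar threshold is systolic blood
#' pressure of 140 mm Hg.
#'
#' @param trait numeric trait values (typically founder means over exams).
#' @param threshold case threshold on the trait scale.
#' @return Integer vector (1 = case, 0 = control) of class
#'   `CaseControlLabels` with the threshold attached as an attribute.
#' @export
dichotomize <- function(trait, threshold) {
  stopifnot(is.numeric(trait), length(threshold) == 1L)
  lab <- as.integer(trait >= threshold)
  lab[is.na(trait)] <- NA_integer_
  n_case <- sum(lab == 1L, na.rm = TRUE)
  n_ctrl <- sum(lab == 0L, na.rm = TRUE)
  if (n_case == 0L || n_ctrl == 0L)
    stop("threshold ", threshold, " yields ", n_case, " case(s) and ",
         n_ctrl, " control(s); choose a different threshold")
  structure(lab, class = "CaseControlLabels", threshold = threshold)
}

# Firth-penalized logistic regression (Jeffreys-prior score adjustment);
# used as fallback when the ML fit separates or fails to converge.
# Newton-Raphson with step-halving on the penalized log-likelihood.
firth_logistic <- function(X, y, maxit = 100L, tol = 1e-6) {
  pen_loglik <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    ld <- determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
    sum(y * eta - log1p(exp(eta))) + 0.5 * as.numeric(ld)
  }
  beta <- rep(0, ncol(X))
  ll <- pen_loglik(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XW <- X * w
    info <- crossprod(X, XW)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) inv <- solve(info + diag(1e-8, ncol(X)))
    h <- rowSums((X %*% inv) * XW)
    score <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- drop(inv %*% score)
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
    if (max(abs(step * delta)) < tol)
      return(list(coefficients = beta, converged = TRUE))
    ll <- pen_loglik(beta)
  }
  list(coefficients = beta, converged = FALSE)
}

#' Single-variant odds ratio from founder case/control labels
#'
#' Fits a log-additive logistic regression of case status on the
#' minor-allele count (optionally adjusting for covariates) and returns the
#' per-allele odds ratio.  When the ML fit separates or diverges, a
#' Firth-penalized fit is used instead (flagged in the result); if that too
#' fails the effect is set to zero with a warning, since effect estimates
#' are unstable for very rare variants.
#'
#' @param x founder minor-allele counts at one variant.
#' @param labels a [dichotomize] result (or 0/1 vector).
#' @param covariates optional founder covariate matrix.
#' @return List with `or`, `log_or`, and logical `fallback`.
#' @export
single_variant_or <- function(x, labels, covariates = NULL) {
  X <- cbind(1, x)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  y <- as.integer(labels)
  cc <- stats::complete.cases(X) & !is.na(y)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  if (stats::var(X[, 2L]) == 0)
    stop("variant is monomorphic among labelled founders")
  boundary <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("numerically 0 or 1|did not converge", conditionMessage(w)))
          boundary <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  b <- if (!is.null(fit) && fit$converged) unname(fit$coefficients[2L])
       else NA_real_
  if (!is.null(fit) &&
      (max(fit$fitted.values) > 1 - 1e-6 || min(fit$fitted.values) < 1e-6))
    boundary <- TRUE  # (quasi-)separation: some fitted probability at 0/1
  fallback <- FALSE
  if (!is.finite(b) || abs(b) > 10 || boundary) {
    fallback <- TRUE
    ff <- firth_logistic(X, y)
    b <- ff$coefficients[2L]
    if (!ff$converged || !is.finite(b)) {
      warning("logistic fit failed even with Firth penalization; ",
              "effect set to zero")
      b <- 0
    }
  }
  list(or = unname(exp(b)), log_or = unname(b), fallback = fallback)
}

#' Genotype-risk-value weights for one variant
#'
#' Under the log-additive model the three genotypes carry relative risks
#' 1, OR, OR^2; the average relative risk in a Hardy-Weinberg population
#' with risk-allele frequency `p` is
#' `ARR = (1-p)^2 + 2p(1-p)OR + p^2 OR^2`, and the genotype weights are
#' `1/ARR`, `OR/ARR`, `OR^2/ARR` for AA, AB, BB.  Under Hardy-Weinberg
#' proportions the weights average exactly to 1.
#'
#' @param p risk (minor) allele frequency in `(0, 0.5]`.
#' @param or per-allele odds ratio, must be positive.
#' @return Named numeric vector `c(AA=, AB=, BB=)` with attributes `or`
#'   and `arr`.
#' @export
grv_weights <- function(p, or) {
  stopifnot(length(p) == 1L, length(or) == 1L)
  if (!(p > 0 && p <= 0.5)) stop("p must lie in (0, 0.5]")
  if (!(or > 0)) stop("odds ratio must be positive")
  arr <- (1 - p)^2 + 2 * p * (1 - p) * or + p^2 * or^2
  structure(c(AA = 1 / arr, AB = or / arr, BB = or^2 / arr),
            or = or, arr = arr)
}

#' Allele-frequency baseline weights
#'
#' The canonical inverse-frequency weight `1/sqrt(l * p * (1 - p))`
#' computed on the `l` founders, normalized so the largest weight is 1.
#' Rarer variants receive larger weights; founder-monomorphic variants get 0.
#'
#' @param p vector of founder minor-allele frequencies.
#' @param l number of founders.
#' @return A `WeightVector` (scheme `"af"`).
#' @export
af_weights <- function(p, l) {
  stopifnot(l >= 1L)
  w <- rep(0, length(p))
  ok <- !is.na(p) & p > 0
  w[ok] <- 1 / sqrt(l * p[ok] * (1 - p[ok]))
  if (any(w > 0)) w <- w / max(w)
  new_weight_vector(w, "af", l = l)
}

#' Log-odds-ratio weights
#'
#' The weight of each variant is the (signed) log odds ratio of its
#' association with dichotomized case status, so protective variants flip
#' the direction of their contribution.
#'
#' @param log_or vector of per-variant log odds ratios (0/NA for
#'   untestable variants).
#' @param absolute use `|log OR|` instead of the signed value.
#' @return A `WeightVector` (scheme `"lor"`).
#' @export
lor_weights <- function(log_or, absolute = FALSE) {
  w <- ifelse(is.na(log_or), 0, log_or)
  if (absolute) w <- abs(w)
  new_weight_vector(w, "lor")
}

#' Optimal weights from founder residual correlations
#'
#' `w_m = cor(y~, x~_m) / sqrt(sum_i (x~_im - mean)^2)` over the `l`
#' founders, where `y~` and `x~_m` are covariate-adjusted trait and
#' genotype residuals.  Variants rare in founders have a small residual
#' sum of squares, so this weight simultaneously up-weights rare variants
#' and variants strongly associated with the trait, with a sign that tracks
#' the direction of association.
#'
#' @param y_founders founder trait residuals (length `l`).
#' @param x_founders `l x M` matrix of founder genotype residuals.
#' @return A `WeightVector` (scheme `"ow"`).
#' @export
ow_weights <- function(y_founders, x_founders) {
  x_founders <- as.matrix(x_founders)
  stopifnot(length(y_founders) == nrow(x_founders))
  if (isTRUE(stats::sd(y_founders, na.rm = TRUE) == 0))
    stop("founder trait residuals have zero variance")
  w <- vapply(seq_len(ncol(x_founders)), function(m) {
    xm <- x_founders[, m]
    cc <- !is.na(xm) & !is.na(y_founders)
    if (sum(cc) < 3L) return(0)
    ss <- sum((xm[cc] - mean(xm[cc]))^2)
    if (ss == 0) return(0)
    rho <- stats::cor(y_founders[cc], xm[cc])
    if (!is.finite(rho)) return(0)
    rho / sqrt(ss)
  }, numeric(1))
  new_weight_vector(w, "ow", l = nrow(x_founders))
}

#' Functional-prediction weights
#'
#' Nonsynonymous variants are weighted by their functional-prediction score
#' in `[0, 1]`; nonsynonymous variants without a score are imputed with the
#' median available score of their gene (0 when the gene has none); all
#' other annotation classes get weight 0.
#'
#' @param scores a [FunctionalScoreTable].
#' @param variants variant metadata data frame (from a [GenotypeMatrix])
#'   with an `id` column.
#' @return A `WeightVector` (scheme `"fp"`).
#' @export
fp_weights <- function(scores, variants) {
  stopifnot(inherits(scores, "FunctionalScoreTable"))
  hit <- match(variants$id, scores$variant_id)
  ann <- scores$annotation[hit]
  sc <- scores$score[hit]
  gene <- scores$gene[hit]
  nonsyn_tab <- scores[scores$annotation == "nonsynonymous" &
                         !is.na(scores$score), , drop = FALSE]
  gene_median <- tapply(nonsyn_tab$score, nonsyn_tab$gene, stats::median)
  w <- rep(0, nrow(variants))
  is_ns <- !is.na(ann) & ann == "nonsynonymous"
  w[is_ns & !is.na(sc)] <- sc[is_ns & !is.na(sc)]
  imp <- is_ns & is.na(sc)
  if (any(imp)) {
    med <- gene_median[gene[imp]]
    n_nogene <- sum(is.na(med))
    if (n_nogene > 0L)
      message(n_nogene, " nonsynonymous variant(s) in gene(s) without any ",
              "score set to weight 0")
    med[is.na(med)] <- 0
    w[imp] <- med
  }
  if (any(w < 0 | w > 1)) stop("functional weights must lie in [0, 1]")
  new_weight_vector(w, "fp")
}

new_weight_vector <- function(w, scheme, l = NA_integer_, threshold = NA_real_) {
  stopifnot(all(is.finite(w)))
  structure(as.numeric(w), class = "WeightVector", scheme = scheme,
            l = l, threshold = threshold)
}

#' @exportS3Method base::print
print.WeightVector <- function(x, ...) {
  cat(sprintf("WeightVector[%s]: %d variants, %d nonzero, range %s\n",
              attr(x, "scheme"), length(x), sum(x != 0),
              paste(signif(range(x), 3), collapse = " .. ")))
  invisible(x)
}

#' Compute the weight configuration for a cohort
#'
#' Dispatcher over the five schemes.  All founder-based quantities (minor
#' allele frequencies, odds ratios, optimal weights) use founders only;
#' variants monomorphic in founders receive weight 0 under every scheme.
#' For `grv` the result is a `GrvWeightSet` (one weight per genotype per
#' variant); all other schemes return a per-variant `WeightVector`.
#'
#' @param cohort an `FbatvCohort`.
#' @param resid a [residualize_cohort] result for the same cohort.
#' @param scheme one of `"af"`, `"grv"`, `"lor"`, `"ow"`, `"fp"`.
#' @param config a [fbatv_config].
#' @return A `WeightVector` or `GrvWeightSet`.
#' @export
compute_weights <- function(cohort, resid,
                            scheme = c("af", "grv", "lor", "ow", "fp"),
                            config = fbatv_config()) {
  scheme <- match.arg(scheme)
  geno <- cohort$geno
  fo <- intersect(founders(cohort$ped), rownames(geno$x))
  l <- length(fo)
  p <- geno$variants$maf
  mono <- is.na(p) | p <= 0
  M <- ncol(geno$x)

  if (scheme == "af") return(af_weights(p, l))

  if (scheme == "ow") {
    w <- ow_weights(resid$y[fo], resid$x[fo, , drop = FALSE])
    w[mono] <- 0
    return(w)
  }

  if (scheme == "fp") {
    if (is.null(cohort$scores))
      stop("scheme 'fp' needs a functional-score table in the cohort")
    w <- fp_weights(cohort$scores, geno$variants)
    w[mono] <- 0
    return(w)
  }

  # grv / lor need founder case-control labels from the raw trait
  ft <- founder_trait(cohort)[fo]
  threshold <- config$threshold
  if (is.null(threshold))
    threshold <- stats::quantile(ft, config$threshold_quantile, na.rm = TRUE,
                                 names = FALSE)
  labels <- dichotomize(ft, threshold)
  xf <- geno$x[fo, , drop = FALSE]
  covar <- NULL
  use_covar <- (scheme == "lor") || isTRUE(config$grv_covariates)
  if (use_covar && length(config$covariates) > 0L)
    covar <- first_exam_covariates(cohort$pheno, fo, config$covariates)

  fits <- lapply(seq_len(M), function(m) {
    if (mono[m] || stats::var(xf[, m], na.rm = TRUE) %in% c(0, NA))
      return(list(or = NA_real_, log_or = NA_real_, fallback = FALSE))
    single_variant_or(xf[, m], labels,
                      covariates = if (use_covar) covar else NULL)
  })
  log_or <- vapply(fits, `[[`, numeric(1), "log_or")

  if (scheme == "lor") {
    w <- lor_weights(log_or, absolute = isTRUE(config$lor_absolute))
    attr(w, "threshold") <- threshold
    attr(w, "l") <- l
    return(w)
  }

  # grv: per-genotype weight triples
  or <- exp(log_or)
  wmat <- matrix(0, nrow = 3L, ncol = M,
                 dimnames = list(c("AA", "AB", "BB"), geno$variants$id))
  arr <- rep(NA_real_, M)
  for (m in which(!mono & is.finite(or))) {
    gw <- grv_weights(p[m], or[m])
    wmat[, m] <- gw
    arr[m] <- attr(gw, "arr")
  }
  structure(list(w = wmat, or = or, arr = arr, threshold = threshold, l = l),
            class = "GrvWeightSet")
}

#' @exportS3Method base::print
print.GrvWeightSet <- function(x, ...) {
  cat(sprintf("GrvWeightSet: %d variants (%d with fitted OR), threshold %.3g\n",
              ncol(x$w), sum(is.finite(x$or)), x$threshold))
  invisible(x)
}

# mean raw trait per individual over available exams
founder_trait <- function(cohort) {
  ph <- cohort$pheno
  tapply(ph$trait, ph$iid, mean, na.rm = TRUE)
}

first_exam_covariates <- function(pheno, ids, covariates) {
  first <- pheno[order(pheno$iid, pheno$exam), , drop = FALSE]
  first <- first[!duplicated(first$iid), , drop = FALSE]
  out <- matrix(NA_real_, nrow = length(ids), ncol = length(covariates),
                dimnames = list(ids, covariates))
  hit <- match(ids, first$iid)
  out[!is.na(hit), ] <- as.matrix(first[hit[!is.na(hit)], covariates,
                                        drop = FALSE])
  out
}

#' Export / import per-variant weights as TSV
#'
#' The table has columns `variant_id`, `scheme` and `weight`, so externally
#' computed weights (e.g. real annotation-tool output transformed into
#' weights) can be audited or injected into the test via
#' [run_fbatv]`(weights = ...)`.
#'
#' @param weights a `WeightVector`.
#' @param geno the [GenotypeMatrix] the weights are aligned to.
#' @param path output TSV path.
#' @export
write_weights <- function(weights, geno, path) {
  stopifnot(inherits(weights, "WeightVector"),
            length(weights) == ncol(geno$x))
  utils::write.table(
    data.frame(variant_id = geno$variants$id,
               scheme = attr(weights, "scheme"),
               weight = as.numeric(weights), stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @param scheme_label scheme label recorded on the imported vector.
#' @return `read_weights` returns a `WeightVector` aligned to `geno`'s
#'   variants; variants absent from the file get weight 0.
#' @export
read_weights <- function(path, geno, scheme_label = "external") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "weight") %in% names(tab)))
  w <- tab$weight[match(geno$variants$id, tab$variant_id)]
  w[is.na(w)] <- 0
  if ("scheme" %in% names(tab) && length(unique(tab$scheme)) == 1L)
    scheme_label <- tab$scheme[1L]
  new_weight_vector(w, scheme_label)
}
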