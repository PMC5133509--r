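#' Ordinary-least-squares residualization
#'
#' Regresses `values` on an intercept plus the covariate columns and returns
#' the residuals.  Collinear covariate columns are dropped with a warning.
#' Entries with missing values (or missing covariates) get `NA` residuals;
#' the fit uses complete cases only.
#'
#' @param values numeric vector.
#' @param covariates numeric matrix/data frame with one row per entry of
#'   `values`, or `NULL` for intercept-only (mean-centering).
#' @return List with `residuals` (same length as `values`) and
#'   `coefficients` (named, including the intercept).
#' @export
residualize <- function(values, covariates = NULL) {
  n <- length(values)
  if (is.null(covariates)) {
    X <- matrix(1, nrow = n, ncol = 1L,
                dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
    X <- cbind("(Intercept)" = 1, covariates)
  }
  cc <- stats::complete.cases(X) & !is.na(values)
  if (sum(cc) <= ncol(X))
    stop("too few complete observations (", sum(cc), ") for ",
         ncol(X), " regression columns")
  qr_x <- qr(X[cc, , drop = FALSE])
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warning("dropping collinear covariate column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qr_x <- qr(X[cc, , drop = FALSE])
  }
  beta <- qr.coef(qr_x, values[cc])
  res <- rep(NA_real_, n)
  res[cc] <- qr.resid(qr_x, values[cc])
  list(residuals = res, coefficients = beta)
}

# residualize many columns against one covariate design at once
residualize_matrix <- function(M, covariates = NULL) {
  n <- nrow(M)
  if (is.null(covariates)) {
    X <- matrix(1, nrow = n, ncol = 1L)
  } else {
    X <- cbind(1, as.matrix(covariates))
  }
  if (anyNA(X)) {
    out <- M
    for (j in seq_len(ncol(M)))
      out[, j] <- residualize(M[, j], covariates)$residuals
    return(out)
  }
  if (anyNA(M)) {
    na_cols <- which(colSums(is.na(M)) > 0L)
    out <- M
    Q <- qr.Q(qr(X))
    full <- setdiff(seq_len(ncol(M)), na_cols)
    if (length(full) > 0L)
      out[, full] <- M[, full, drop = FALSE] -
        Q %*% crossprod(Q, M[, full, drop = FALSE])
    for (j in na_cols)
      out[, j] <- residualize(M[, j], covariates)$residuals
    return(out)
  }
  Q <- qr.Q(qr(X))
  M - Q %*% crossprod(Q, M)
}

#' Covariate-adjust a cohort's trait and genotypes
#'
#' The trait is residualized on the covariates separately within each exam,
#' optionally standardized (divided by the residual standard deviation,
#' the default), and the per-exam residuals are averaged over the exams
#' available for each individual.  Genotype columns, being exam-invariant,
#' are residualized once against each individual's covariates at their first
#' exam.
#'
#' @param cohort an `FbatvCohort` (or a list with `geno` and `pheno`).
#' @param covariates character vector of covariate column names in the
#'   phenotype table (default `c("age", "sex", "med")`); use `character(0)`
#'   for mean-centering only.
#' @param standardize `"trait"` (default), `"both"` or `"none"`: which
#'   residual sets are scaled to unit standard deviation.
#' @return An object of class `ResidualizedCohort`: list with `ids`, trait
#'   residuals `y` (named vector, averaged over exams), genotype residuals
#'   `x` (matrix), per-exam trait coefficients `coef_y`, and the covariate
#'   design used for genotypes.
#' @export
residualize_cohort <- function(cohort, covariates = c("age", "sex", "med"),
                               standardize = c("trait", "both", "none")) {
  standardize <- match.arg(standardize)
  geno <- cohort$geno
  pheno <- cohort$pheno
  miss <- setdiff(covariates, names(pheno))
  if (length(miss) > 0L)
    stop("covariate(s) not in phenotype table: ", paste(miss, collapse = ", "))
  ids <- rownames(geno$x)

  exams <- sort(unique(pheno$exam))
  acc <- matrix(NA_real_, nrow = length(ids), ncol = length(exams),
                dimnames = list(ids, exams))
  coef_y <- list()
  for (k in seq_along(exams)) {
    sub <- pheno[pheno$exam == exams[k] & pheno$iid %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L) next
    Z <- if (length(covariates) > 0L)
      as.matrix(sub[, covariates, drop = FALSE]) else NULL
    fit <- residualize(sub$trait, Z)
    r <- fit$residuals
    if (standardize %in% c("trait", "both")) {
      s <- stats::sd(r, na.rm = TRUE)
      if (is.finite(s) && s > 0) r <- r / s
    }
    acc[sub$iid, k] <- r
    coef_y[[as.character(exams[k])]] <- fit$coefficients
  }
  y <- rowMeans(acc, na.rm = TRUE)
  y[is.nan(y)] <- NA_real_
  n_dropped <- sum(is.na(y))
  if (n_dropped > 0L)
    warning(n_dropped, " individual(s) without any trait observation ",
            "excluded from testing")

  # genotype side: covariates at each individual's first exam
  first <- pheno[order(pheno$iid, pheno$exam), , drop = FALSE]
  first <- first[!duplicated(first$iid), , drop = FALSE]
  Zg <- NULL
  if (length(covariates) > 0L) {
    Zg <- matrix(NA_real_, nrow = length(ids), ncol = length(covariates),
                 dimnames = list(ids, covariates))
    hit <- match(ids, first$iid)
    Zg[!is.na(hit), ] <- as.matrix(
      first[hit[!is.na(hit)], covariates, drop = FALSE])
  }
  xr <- residualize_matrix(geno$x * 1.0, Zg)
  if (standardize == "both") {
    s <- apply(xr, 2L, stats::sd, na.rm = TRUE)
    s[!is.finite(s) | s == 0] <- 1
    xr <- sweep(xr, 2L, s, "/")
  }
  structure(list(ids = ids, y = y, x = xr, coef_y = coef_y,
                 covariates = covariates, standardize = standardize),
            class = "ResidualizedCohort")
}

#' @exportS3Method base::print
print.ResidualizedCohort <- function(x, ...) {
  cat(sprintf("ResidualizedCohort: %d individuals, %d variants, covariates: %s\n",
              length(x$ids), ncol(x$x),
              if (length(x$covariates) > 0L)
                paste(x$covariates, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Export residual tables for audit
#'
#' Writes one row per individual: the averaged trait residual followed by
#' the genotype residual at every variant.
#'
#' @param resid a [residualize_cohort] result.
#' @param path output TSV path.
#' @export
write_residuals <- function(resid, path) {
  out <- data.frame(iid = resid$ids, trait_residual = unname(resid$y),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(resid$x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
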