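#' Offspring genotype distribution given parental genotypes
#'
#' Under additive Mendelian transmission each parent passes each of their
#' two alleles with probability 1/2, independently, so a parent with
#' minor-allele count `g` transmits a minor allele with probability `g/2`.
#' The offspring count is the sum of the two transmissions.
#'
#' @param g_father,g_mother parental minor-allele counts in `{0, 1, 2}`.
#' @return A `TransmissionDistribution`: list with `prob` (named vector over
#'   offspring counts 0/1/2), `mean` (`(g_father + g_mother)/2`) and `var`.
#' @export
transmission_distribution <- function(g_father, g_mother) {
  stopifnot(length(g_father) == 1L, length(g_mother) == 1L,
            g_father %in% 0:2, g_mother %in% 0:2)
  tf <- g_father / 2
  tm <- g_mother / 2
  prob <- c("0" = (1 - tf) * (1 - tm),
            "1" = tf * (1 - tm) + (1 - tf) * tm,
            "2" = tf * tm)
  structure(list(prob = prob,
                 mean = tf + tm,
                 var = tf * (1 - tf) + tm * (1 - tm)),
            class = "TransmissionDistribution")
}

#' @exportS3Method base::print
print.TransmissionDistribution <- function(x, ...) {
  cat(sprintf("Transmission: P(0)=%.3g P(1)=%.3g P(2)=%.3g  mean=%.3g var=%.3g\n",
              x$prob[1L], x$prob[2L], x$prob[3L], x$mean, x$var))
  invisible(x)
}

#' Conditional expectation of the residualized offspring genotype
#'
#' Returns `E(x | parents) - covariate_prediction`, i.e. the expectation of
#' the covariate-adjusted genotype given the parental pair.  Because the
#' same fitted value is subtracted from the observed residual, the deviation
#' entering the test statistic reduces exactly to
#' `x - (g_father + g_mother)/2`, making the statistic invariant to the
#' genotype-side covariate fit.
#'
#' @param g_father,g_mother parental minor-allele counts.
#' @param covariate_prediction fitted value of the genotype regression for
#'   the offspring (default 0).
#' @return Numeric scalar.
#' @export
expected_residual_genotype <- function(g_father, g_mother,
                                       covariate_prediction = 0) {
  stopifnot(g_father %in% 0:2, g_mother %in% 0:2)
  (g_father + g_mother) / 2 - covariate_prediction
}
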