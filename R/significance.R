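# Likelihood-ratio testing of variance components and genetic
# correlations, with the boundary-corrected null distribution (50:50
# mixture of chi-squared with 0 and 1 df) where the constrained parameter
# lies on the edge of the parameter space.

#' Likelihood-ratio statistic
#'
#' `LR = 2 (l_full - l_constrained)`, clamped at zero (with a warning)
#' when numerical noise leaves the constrained likelihood marginally above
#' the full one.
#'
#' @param l_full restricted log-likelihood of the full model.
#' @param l_constrained restricted log-likelihood of the constrained
#'   model.
#' @return Non-negative LR statistic.
#' @export
lr_statistic <- function(l_full, l_constrained) {
  if (!is.finite(l_full) || !is.finite(l_constrained))
    stop("non-finite log-likelihoods")
  lr <- 2 * (l_full - l_constrained)
  if (lr < 0) {
    warning("constrained likelihood exceeds full likelihood (LR = ",
            signif(lr, 3), "); clamped to 0")
    lr <- 0
  }
  lr
}

#' p-value under the boundary mixture null
#'
#' For a test of a parameter on the boundary of the parameter space
#' (heritability = 0, correlation = 1) the LR statistic is distributed
#' under the null as a 50:50 mixture of chi-squared with 0 and 1 df, so
#' `p = 0.5 P(chisq_1 > LR)` for `LR > 0` and `p = 0.5` at `LR = 0`
#' (the chi0 point mass).  The 5% threshold is `LR = 2.706`.
#'
#' @param lr LR statistic, `>= 0`.
#' @return p-value.
#' @export
p_boundary_mixture <- function(lr) {
  if (any(lr < 0)) stop("negative LR statistic")
  ifelse(lr == 0, 0.5,
         0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE))
}

#' p-value under the interior chi-squared null
#'
#' For constraints in the interior of the parameter space (e.g. a genetic
#' correlation fixed at 0), `LR ~ chisq` with df equal to the reduction in
#' the number of parameters.
#'
#' @param lr LR statistic, `>= 0`.
#' @param df degrees of freedom, `>= 1`.
#' @return p-value.
#' @export
p_chisq <- function(lr, df = 1) {
  if (any(lr < 0)) stop("negative LR statistic")
  if (df < 1) stop("invalid degrees of freedom")
  stats::pchisq(lr, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test between two fits
#'
#' Convenience wrapper: computes the LR statistic and the p-value under
#' the appropriate null.  Boundary tests (heritability vs 0 via
#' `no_genetic`, correlation vs 1 via `rg1`) use the 50:50 mixture;
#' the interior test of a correlation vs 0 (`rg0`) uses chi-squared with
#' 1 df.
#'
#' @param full,constrained `varcomp_fit` objects.
#' @param boundary is the constrained parameter on the boundary?
#' @param df degrees of freedom for the interior test.
#' @param alpha significance level recorded in the result.
#' @return List of class `lrt_result`: `lr`, `p`, `boundary`, `df`,
#'   `significant`, `alpha`.
#' @export
lr_test <- function(full, constrained, boundary = TRUE, df = 1,
                    alpha = 0.05) {
  lr <- lr_statistic(full$loglik, constrained$loglik)
  p <- if (boundary) p_boundary_mixture(lr) else p_chisq(lr, df)
  structure(list(lr = lr, p = p, boundary = boundary,
                 df = if (boundary) NA_integer_ else df,
                 significant = p < alpha, alpha = alpha),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LR = %.4f, %s null, p = %.4g%s\n", x$lr,
              if (x$boundary) "boundary-mixture" else
                sprintf("chisq(%d)", x$df),
              x$p, if (x$significant) " *" else ""))
  invisible(x)
}
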