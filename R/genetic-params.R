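# Transformations of variance components into the reported genetic
# parameters: heritabilities on the individual and pooled-cage scales,
# purebred-crossbred and trait-trait genetic correlations, phenotypic
# correlations, with delta-method standard errors.

#' Purebred heritability
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`; the denominator is the
#' purebred phenotypic variance.
#'
#' @param sigma2_a additive genetic variance.
#' @param sigma2_e residual variance.
#' @return List with `h2` and `sigma2_P`.
#' @export
h2_purebred <- function(sigma2_a, sigma2_e) {
  stopifnot(sigma2_a >= 0, sigma2_e >= 0)
  sP <- sigma2_a + sigma2_e
  if (sP == 0) stop("undefined heritability: both variances zero")
  list(h2 = sigma2_a / sP, sigma2_P = sP)
}

#' Crossbred heritability from pooled cage records
#'
#' A cage record is the average performance of `n` paternal half-sibs, so
#' the sire variance estimated from cage means must be scaled back to the
#' individual level: `sigma2_P* = sigma2_s + n * sigma2_e` (the cage-mean
#' residual variance times the cage size recovers the individual
#' phenotypic variance) and `h2 = 4 sigma2_s / sigma2_P*`.
#'
#' @param sigma2_s sire genetic variance (a quarter of the crossbred
#'   additive variance).
#' @param sigma2_e cage-mean residual variance for this cage size.
#' @param n initial number of hens in the cage (6 to 8).
#' @return List with `h2` and `sigma2_P_star`.
#' @export
h2_crossbred_pooled <- function(sigma2_s, sigma2_e, n) {
  stopifnot(sigma2_s >= 0, sigma2_e >= 0, n >= 1)
  sP <- sigma2_s + n * sigma2_e
  if (sP == 0) stop("undefined heritability: zero phenotypic variance")
  list(h2 = 4 * sigma2_s / sP, sigma2_P_star = sP)
}

#' Crossbred heritability for the log-variance trait
#'
#' The cage value of LNVAR is the log of the variance of the pooled
#' deviations, not the average of the members' individual LNVAR values,
#' so the cage-size rescaling of the residual variance does not apply:
#' `h2 = 4 sigma2_s / (sigma2_s + sigma2_e)`.
#'
#' @inheritParams h2_crossbred_pooled
#' @return Heritability (numeric).
#' @export
h2_crossbred_lnvar <- function(sigma2_s, sigma2_e) {
  stopifnot(sigma2_s >= 0, sigma2_e >= 0)
  den <- sigma2_s + sigma2_e
  if (den == 0) stop("undefined heritability: zero denominator")
  4 * sigma2_s / den
}

#' Purebred-crossbred genetic correlation
#'
#' `r_pc = sigma_apsc / (sigma_ap * sigma_sc)` with
#' `sigma_sc = sigma_ac / 2`; equivalently
#' `sigma_apsc = 0.5 r_pc sigma_ap sigma_ac`.
#'
#' @param sigma_apsc genetic covariance between the purebred animal effect
#'   and the crossbred sire effect.
#' @param sigma2_ap purebred additive variance.
#' @param sigma2_ac crossbred additive variance (`4 * sigma2_sc`).
#' @return The correlation.
#' @export
rpc <- function(sigma_apsc, sigma2_ap, sigma2_ac) {
  if (sigma2_ap <= 0 || sigma2_ac <= 0)
    stop("undefined correlation: zero genetic variance")
  sigma_apsc / (sqrt(sigma2_ap) * 0.5 * sqrt(sigma2_ac))
}

# Delta-method SE of g(theta) given the fit's asymptotic covariance.
delta_se <- function(fit, g) {
  if (is.null(fit$vcov)) return(NA_real_)
  th <- fit$estimates
  gr <- vapply(seq_along(th), function(j) {
    h <- 1e-5 * (abs(th[j]) + 1e-8)
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (g(tp) - g(tm)) / (2 * h)
  }, 0)
  v <- as.numeric(t(gr) %*% fit$vcov %*% gr)
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

#' Genetic parameters from a fitted model
#'
#' Extracts the reported quantities from a `varcomp_fit` with delta-method
#' standard errors: for a bivariate purebred-crossbred fit, the purebred
#' heritability, per-cage-size crossbred heritabilities (pooled-record
#' formula; LNVAR form when `lnvar_scale = TRUE`) and `r_pc`; for a
#' trait-pair fit, the genetic correlation `r_g = sigma_g12 /
#' (sigma_g1 sigma_g2)` and, where residual covariance is estimated, the
#' phenotypic correlation `r_P = (sigma_g12 + sigma_e12) /
#' (sigma_P1 sigma_P2)`.
#'
#' @param fit a `varcomp_fit`.
#' @param type `"purebred_crossbred"` or `"trait_pair"`.
#' @param cage_sizes named conversion from residual-stratum suffix to cage
#'   size, e.g. `c(c6 = 6, c7 = 7)`; inferred from estimate names by
#'   default.
#' @param lnvar_scale use the LNVAR pooled-record heritability (no
#'   cage-size rescaling of the residual variance).
#' @return Data frame of parameter, estimate, se.
#' @export
genetic_params <- function(fit, type = c("purebred_crossbred", "trait_pair"),
                           cage_sizes = NULL, lnvar_scale = FALSE) {
  type <- match.arg(type)
  est <- fit$estimates
  out <- list()
  add <- function(name, value, se) out[[length(out) + 1L]] <<-
    data.frame(parameter = name, estimate = value, se = se,
               stringsAsFactors = FALSE)
  if (type == "purebred_crossbred") {
    add("sigma2_ap", est[["sigma2_g1"]],
        if (!is.null(fit$se)) fit$se[["sigma2_g1"]] else NA)
    add("sigma2_ac", 4 * est[["sigma2_g2"]],
        delta_se(fit, function(th) 4 * th[["sigma2_g2"]]))
    h2p <- function(th) th[["sigma2_g1"]] /
      (th[["sigma2_g1"]] + th[["sigma2_e_p"]])
    add("h2_p", h2p(est), delta_se(fit, h2p))
    strata <- grep("^sigma2_e_c", names(est), value = TRUE)
    if (is.null(cage_sizes)) {
      cage_sizes <- as.numeric(sub("^sigma2_e_c", "", strata))
      names(cage_sizes) <- sub("^sigma2_e_", "", strata)
    }
    for (s in strata) {
      n <- cage_sizes[[sub("^sigma2_e_", "", s)]]
      h2c <- if (lnvar_scale)
        function(th) 4 * th[["sigma2_g2"]] / (th[["sigma2_g2"]] + th[[s]])
      else
        function(th) 4 * th[["sigma2_g2"]] /
          (th[["sigma2_g2"]] + n * th[[s]])
      add(paste0("h2_c", n), h2c(est), delta_se(fit, h2c))
      if (!lnvar_scale)
        add(paste0("sigma2_P_star_c", n), est[["sigma2_g2"]] + n * est[[s]],
            delta_se(fit, function(th) th[["sigma2_g2"]] + n * th[[s]]))
    }
    if (fit$g_constraint == "full") {
      rf <- function(th) th[["sigma_g12"]] /
        sqrt(th[["sigma2_g1"]] * th[["sigma2_g2"]])
      add("r_pc", rf(est), delta_se(fit, rf))
    }
  } else {
    rg <- function(th) th[["sigma_g12"]] /
      sqrt(th[["sigma2_g1"]] * th[["sigma2_g2"]])
    add("r_g", rg(est), delta_se(fit, rg))
    if ("sigma_e12" %in% names(est)) {
      rp <- function(th) (th[["sigma_g12"]] + th[["sigma_e12"]]) /
        sqrt((th[["sigma2_g1"]] + th[["sigma2_e1"]]) *
             (th[["sigma2_g2"]] + th[["sigma2_e2"]]))
      add("r_P", rp(est), delta_se(fit, rp))
    }
  }
  do.call(rbind, out)
}

#' Round to reported table precision
#'
#' Two decimals, as in the published genetic-parameter tables.  Used only
#' for report generation, never in internal computation.
#'
#' @param x numeric.
#' @param digits decimals.
#' @export
round_report <- function(x, digits = 2) round(x, digits)

#' Reference variance-component estimates for two layer lines
#'
#' Published REML estimates for egg production (EP) and the resilience
#' indicator traits in a White Leghorn (WA) and a Rhode Island (BD) layer
#' line, each recorded as purebred individual records and crossbred
#' cage-mean records.  These serve as generating truth for the
#' parameter-recovery simulations and as worked-example inputs for the
#' heritability formulas.  `cage_small`/`cage_large` are the two cage
#' sizes tested per line (6 and 7 hens for WA, 7 and 8 for BD; the
#' residual-variance columns refer to the smaller and larger cage).
#'
#' @return Data frame with one row per line x trait: `sigma2_ap`,
#'   `sigma2_ac`, `r_pc`, `sigma2_ep`, `sigma2_ec_small`,
#'   `sigma2_ec_large`, `cage_small`, `cage_large`.
#' @export
reference_varcomps <- function() {
  data.frame(
    line  = rep(c("WA", "BD"), each = 4),
    trait = rep(c("EP", "LNVAR", "SKEW", "AUTO_R"), 2),
    sigma2_ap = c(107, 0.065, 0.037, 0.003,  325, 0.137, 0.027, 0.006),
    sigma2_ac = c(91,  0.046, 0.037, 0.003,  96,  0.055, 0.016, 0.009),
    r_pc      = c(0.31, 0.16, 0.20, 0.63,    0.52, 0.47, 0.37, 0.56),
    sigma2_ep = c(873, 0.609, 0.920, 0.047,  2400, 1.022, 1.236, 0.074),
    sigma2_ec_small = c(214, 0.343, 0.399, 0.060,  293, 0.242, 0.369, 0.046),
    sigma2_ec_large = c(242, 0.336, 0.382, 0.065,  269, 0.357, 0.382, 0.049),
    cage_small = rep(c(6L, 7L), each = 4),
    cage_large = rep(c(7L, 8L), each = 4),
    stringsAsFactors = FALSE)
}
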