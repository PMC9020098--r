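# Direct simulation from the linear mixed models: breeding values drawn by
# recursion down the pedigree, records drawn from the animal model
# (purebreds) and the sire model (crossbred cage means).  This fidelity
# level is exact on the REML scale and is used for parameter-recovery
# validation.

#' Genetic architecture of the simulated traits
#'
#' Holds the simulation truth on the mixed-model scale for one trait
#' observed in the purebred (individual records, animal model) and
#' crossbred (cage-mean records, sire model) contexts, plus the process
#' parameters of the longitudinal generator.  Defaults are the estimated
#' egg-production (EP) parameters of a White Leghorn layer line: purebred
#' additive variance 107, crossbred additive variance 91, purebred-crossbred
#' genetic correlation 0.31, purebred residual variance 873 and cage-mean
#' residual variances 214 (cages of 6) and 242 (cages of 7) eggs^2.
#'
#' The sire variance for crossbreds is `sigma2_ac / 4`; the genetic
#' covariance between the purebred animal effect and the crossbred sire
#' effect is `r_pc * sigma_ap * sigma_sc`.
#'
#' @param sigma2_ap purebred additive genetic variance.
#' @param sigma2_ac crossbred additive genetic variance (sire variance is a
#'   quarter of this).
#' @param r_pc purebred-crossbred genetic correlation, in `[-1, 1]`.
#' @param sigma2_ep purebred residual variance.
#' @param sigma2_ec named vector of cage-mean residual variances, names =
#'   cage sizes.
#' @param mu_p,mu_c trait means in the two contexts.
#' @param sd_hatch_loc,sd_maternal_line SD of the fixed-effect level values
#'   (drawn once per level and recorded).
#' @param longitudinal list of process parameters for
#'   [simulate_longitudinal()]; see [longitudinal_params()].
#' @return An object of class `genetic_architecture`.
#' @export
genetic_architecture <- function(sigma2_ap = 107, sigma2_ac = 91,
                                 r_pc = 0.31,
                                 sigma2_ep = 873,
                                 sigma2_ec = c("6" = 214, "7" = 242),
                                 mu_p = 371, mu_c = 368,
                                 sd_hatch_loc = 1, sd_maternal_line = 1,
                                 longitudinal = longitudinal_params()) {
  stopifnot(sigma2_ap >= 0, sigma2_ac >= 0, abs(r_pc) <= 1,
            sigma2_ep >= 0, all(sigma2_ec >= 0))
  structure(list(sigma2_ap = sigma2_ap, sigma2_ac = sigma2_ac, r_pc = r_pc,
                 sigma2_ep = sigma2_ep, sigma2_ec = sigma2_ec,
                 mu_p = mu_p, mu_c = mu_c,
                 sd_hatch_loc = sd_hatch_loc,
                 sd_maternal_line = sd_maternal_line,
                 longitudinal = longitudinal),
            class = "genetic_architecture")
}

# 2x2 genetic covariance matrix on the (animal effect, sire effect) scale.
g0_pc <- function(arch) {
  s2sc <- arch$sigma2_ac / 4
  cov  <- arch$r_pc * sqrt(arch$sigma2_ap * s2sc)
  G0 <- matrix(c(arch$sigma2_ap, cov, cov, s2sc), 2, 2)
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("G0 not positive semi-definite")
  G0
}

#' Draw correlated breeding values down a pedigree
#'
#' Offspring value = half sire value + half dam value + Mendelian-sampling
#' deviation with covariance `k * G0`, where `k = 0.5 - 0.25 (F_s + F_d)`
#' when both parents are known (0.75 - 0.25 F_s with one known parent, 1
#' with none).  Base animals are unrelated, non-inbred draws from
#' `N(0, G0)`.
#'
#' @param ped a [pedigree].
#' @param G0 genetic covariance matrix (t x t), positive semi-definite.
#' @return n x t matrix of breeding values, rownames = ids.
#' @export
draw_breeding_values <- function(ped, G0) {
  G0 <- as.matrix(G0)
  t <- nrow(G0)
  eg <- eigen(G0, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
    stop("G0 not positive semi-definite")
  rt <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), t) # G0 = rt %*% t(rt)
  n <- nrow(ped)
  F <- inbreeding(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  bv <- matrix(0, n, t)
  z <- matrix(stats::rnorm(n * t), n, t) %*% t(rt)
  for (i in seq_len(n)) {
    mid <- numeric(t); k <- 1
    if (s[i] > 0L && d[i] > 0L) {
      mid <- 0.5 * (bv[s[i], ] + bv[d[i], ])
      k <- 0.5 - 0.25 * (F[s[i]] + F[d[i]])
    } else if (s[i] > 0L) {
      mid <- 0.5 * bv[s[i], ]
      k <- 0.75 - 0.25 * F[s[i]]
    } else if (d[i] > 0L) {
      mid <- 0.5 * bv[d[i], ]
      k <- 0.75 - 0.25 * F[d[i]]
    }
    bv[i, ] <- mid + sqrt(k) * z[i, ]
  }
  rownames(bv) <- ped$id
  bv
}

#' Simulate a trait table directly from the mixed models
#'
#' Purebred record: `mu_p + hatch_loc + a_i + e_i` with
#' `e ~ N(0, sigma2_ep)`.  Crossbred cage-mean record:
#' `mu_c + hatch_loc + maternal_line + s_sire + e_cage` with cage-mean
#' residual variance `sigma2_ec[cage size]`.  The animal and sire effects
#' are drawn jointly down the pedigree with covariance `A x G0`,
#' `G0 = [[sigma2_ap, r_pc sigma_ap sigma_sc], [., sigma2_ac / 4]]`.
#' Fixed-effect level values are drawn once per level and recorded in the
#' `"effects"` attribute together with the true genetic effects.
#'
#' @param pop a [layer_population] from [simulate_pedigree()].
#' @param arch a [genetic_architecture].
#' @param seed RNG seed.
#' @return Data frame with columns `unit_id`, `population`
#'   (`"purebred"`/`"crossbred"`), `y`, `sire`, `batch`, `hatch_loc`,
#'   `maternal_line`, `cage_size`; attribute `"effects"` holds the true
#'   breeding values and fixed-effect level values.
#' @export
simulate_trait_table <- function(pop, arch, seed = 1L) {
  stopifnot(inherits(pop, "layer_population"),
            inherits(arch, "genetic_architecture"))
  set.seed(stage_seed(seed, "direct"))
  G0 <- g0_pc(arch)
  bv <- draw_breeding_values(pop$ped, G0)
  hl_levels <- sort(unique(c(pop$purebred$hatch_loc, pop$cages$hatch_loc)))
  ml_levels <- sort(unique(pop$cages$maternal_line))
  hl_eff <- stats::setNames(stats::rnorm(length(hl_levels), 0, arch$sd_hatch_loc),
                            hl_levels)
  ml_eff <- stats::setNames(stats::rnorm(length(ml_levels), 0, arch$sd_maternal_line),
                            ml_levels)
  pb <- pop$purebred
  y_pb <- arch$mu_p + hl_eff[pb$hatch_loc] + bv[pb$unit_id, 1] +
    stats::rnorm(nrow(pb), 0, sqrt(arch$sigma2_ep))
  out_pb <- data.frame(unit_id = pb$unit_id, population = "purebred",
                       y = unname(y_pb), sire = pb$sire, batch = pb$batch,
                       hatch_loc = pb$hatch_loc,
                       maternal_line = NA_character_,
                       cage_size = NA_integer_, stringsAsFactors = FALSE)
  cg <- pop$cages
  out_cb <- NULL
  if (nrow(cg)) {
    res_sd <- sqrt(arch$sigma2_ec[as.character(cg$cage_size)])
    if (anyNA(res_sd)) stop("missing cage-mean residual variance for a cage size")
    y_cb <- arch$mu_c + hl_eff[cg$hatch_loc] + ml_eff[cg$maternal_line] +
      bv[cg$sire, 2] + stats::rnorm(nrow(cg), 0, res_sd)
    out_cb <- data.frame(unit_id = cg$unit_id, population = "crossbred",
                         y = unname(y_cb), sire = cg$sire, batch = cg$batch,
                         hatch_loc = cg$hatch_loc,
                         maternal_line = cg$maternal_line,
                         cage_size = cg$cage_size, stringsAsFactors = FALSE)
  }
  out <- rbind(out_pb, out_cb)
  attr(out, "effects") <- list(bv = bv, hatch_loc = hl_eff,
                               maternal_line = ml_eff, G0 = G0)
  out
}

#' Simulate two traits on the same units (trait-pair mode)
#'
#' Draws two genetically and residually correlated traits within one
#' population for validating the trait-pair bivariate fits: purebred
#' records under the animal model or crossbred cage means under the sire
#' model (sire-level genetic covariance `G0 / 4` if `G0` is given on the
#' additive scale; pass the sire-scale matrix directly instead).
#'
#' @param pop a [layer_population].
#' @param G0 2 x 2 genetic covariance matrix on the scale of the fitted
#'   effect (animal scale for purebreds, sire scale for crossbreds).
#' @param R0 2 x 2 residual covariance matrix.
#' @param population `"purebred"` or `"crossbred"`.
#' @param mu length-2 trait means.
#' @param cage_size for crossbreds, restrict to cages of this size.
#' @param seed RNG seed.
#' @return Data frame with columns `unit_id`, `y1`, `y2`, `sire`,
#'   `hatch_loc`, `maternal_line`, `cage_size`; `"effects"` attribute as in
#'   [simulate_trait_table()].
#' @export
simulate_trait_pair <- function(pop, G0, R0, population = "purebred",
                                mu = c(0, 0), cage_size = NULL, seed = 1L) {
  stopifnot(inherits(pop, "layer_population"))
  set.seed(stage_seed(seed, "pair"))
  bv <- draw_breeding_values(pop$ped, G0)
  Rrt <- chol(R0)
  if (population == "purebred") {
    units <- pop$purebred
    gen <- bv[units$unit_id, , drop = FALSE]
  } else {
    units <- pop$cages
    if (!is.null(cage_size)) units <- units[units$cage_size == cage_size, ]
    gen <- bv[units$sire, , drop = FALSE]
  }
  e <- matrix(stats::rnorm(2 * nrow(units)), ncol = 2) %*% Rrt
  y <- sweep(gen + e, 2, mu, "+")
  out <- data.frame(unit_id = units$unit_id, y1 = y[, 1], y2 = y[, 2],
                    sire = units$sire, hatch_loc = units$hatch_loc,
                    maternal_line = if (population == "crossbred")
                      units$maternal_line else NA_character_,
                    cage_size = if (population == "crossbred")
                      units$cage_size else NA_integer_,
                    stringsAsFactors = FALSE)
  attr(out, "effects") <- list(bv = bv, G0 = G0, R0 = R0)
  out
}
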