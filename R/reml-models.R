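# Model-level wrappers: univariate animal and sire models, the bivariate
# purebred-crossbred model (animal effect on purebred individual records,
# sire effect on crossbred cage means, genetic covariance through the
# pedigree, zero residual covariance, separate residual variance per cage
# size) and the within-population trait-pair model (genetic and residual
# covariances estimated).

# Sparse incidence of records onto genetic-effect levels; slot-major
# column layout matching kronecker(G0inv, Ainv).
make_Z <- function(gen_id, levels, slot = 1L, n_slots = 1L) {
  j <- match(gen_id, levels)
  if (anyNA(j)) stop("genetic ids missing from the pedigree")
  Matrix::sparseMatrix(i = seq_along(gen_id), j = (slot - 1L) * length(levels) + j,
                       x = 1, dims = c(length(gen_id), n_slots * length(levels)))
}

# Apply a genetic constraint to a prepared model and fit it.
apply_constraint <- function(model, constraint) {
  if (constraint == "no_genetic") {
    model$gtype <- "none"; model$Z <- NULL; model$Ainv <- NULL
  } else if (model$gtype == "bi") {
    model$g_constraint <- constraint
  } else if (constraint != "full") {
    stop("constraint '", constraint, "' requires a bivariate genetic structure")
  }
  model
}

#' Fit a constrained variant of a prepared model
#'
#' `no_genetic` drops the random genetic term (null model for
#' heritability LRTs); `rg0` fixes the genetic covariance at zero; `rg1`
#' imposes a rank-1 genetic covariance matrix (single-factor Cholesky,
#' `G0 = lambda lambda'`, i.e. genetic correlation of +/-1).
#'
#' @param model a model object as built internally by the `fit_*`
#'   wrappers (returned in their `$model` element).
#' @param constraint one of `"full"`, `"no_genetic"`, `"rg0"`, `"rg1"`.
#' @param init,options passed to [reml_fit()].
#' @return A `varcomp_fit`.
#' @export
fit_constrained <- function(model, constraint = c("full", "no_genetic",
                                                  "rg0", "rg1"),
                            init = NULL, options = list()) {
  constraint <- match.arg(constraint)
  reml_fit(apply_constraint(model, constraint), init, options)
}

#' Univariate animal model for purebred records
#'
#' `y = mu + fixed effects + a + e` with `a ~ N(0, A sigma2_a)` over the
#' pedigree and a single residual variance.
#'
#' @param trait_table purebred trait table.
#' @param ped a [pedigree] containing all recorded individuals.
#' @param trait response column.
#' @param fixed fixed-effect factor columns.
#' @param constraint `"full"` or `"no_genetic"`.
#' @param prune prune the pedigree to recorded individuals and their
#'   ancestors (likelihood-preserving, see [prune_pedigree()]).
#' @param init,options passed to [reml_fit()].
#' @return A `varcomp_fit` with the prepared model in `$model`.
#' @export
fit_animal <- function(trait_table, ped, trait = "y",
                       fixed = c("hatch_loc"), constraint = "full",
                       prune = TRUE, init = NULL, options = list()) {
  d <- build_design(trait_table, trait, fixed, genetic = "animal")
  if (prune) ped <- prune_pedigree(ped, unique(d$gen_id))
  Ainv <- build_A_inverse(ped)
  Z <- make_Z(d$gen_id, ped$id)
  model <- reml_model(d$y, d$X, Z, Ainv, "uni", resid_strata(d$stratum))
  fit <- reml_fit(apply_constraint(model, constraint), init, options)
  fit$model <- model
  fit
}

#' Univariate sire model for crossbred cage-mean records
#'
#' `y = mu + fixed effects + s_sire + e` with `var(s) = sigma2_ac / 4` and
#' a separate residual variance per cage size.  With `ped = NULL` the
#' sires are treated as unrelated.
#'
#' @inheritParams fit_animal
#' @param ped pedigree over (at least) the sires, or `NULL` for unrelated
#'   sires.
#' @export
fit_sire <- function(trait_table, ped = NULL, trait = "y",
                     fixed = c("hatch_loc", "maternal_line"),
                     constraint = "full", prune = TRUE, init = NULL,
                     options = list()) {
  d <- build_design(trait_table, trait, fixed, genetic = "sire")
  if (!is.null(ped) && prune) ped <- prune_pedigree(ped, unique(d$gen_id))
  if (is.null(ped)) {
    levels <- sort(unique(d$gen_id))
    Ainv <- Matrix::Diagonal(length(levels))
    dimnames(Ainv) <- list(levels, levels)
  } else {
    levels <- ped$id
    Ainv <- build_A_inverse(ped)
  }
  Z <- make_Z(d$gen_id, levels)
  model <- reml_model(d$y, d$X, Z, Ainv, "uni", resid_strata(d$stratum))
  fit <- reml_fit(apply_constraint(model, constraint), init, options)
  fit$model <- model
  fit
}

# Moment-based starting values for the purebred-crossbred fit from the
# paternal half-sib structure: between/within family variances on both
# sides, and the covariance of purebred family means (carrying half the
# sire breeding value) with crossbred sire means.
pc_moment_init <- function(yp, sire_p, yc, sire_c, stratum_c, constraint) {
  vp <- stats::var(yp); vc <- stats::var(yc)
  fm <- tapply(yp, sire_p, mean)
  wf <- mean(tapply(yp, sire_p, stats::var), na.rm = TRUE)
  nbar <- mean(table(sire_p))
  g1 <- min(max(4 * (stats::var(fm) - wf / nbar), 0.02 * vp), 0.8 * vp)
  ep <- max(vp - g1, 0.1 * vp)
  cm <- tapply(yc, sire_c, mean)
  wc <- mean(tapply(yc, sire_c, stats::var), na.rm = TRUE)
  ncb <- mean(table(sire_c))
  g2 <- min(max(stats::var(cm) - wc / ncb, 0.02 * vc), 0.8 * vc)
  common <- intersect(names(fm), names(cm))
  c12 <- if (length(common) > 2)
    2 * stats::cov(fm[common], cm[common]) else 0
  cap <- 0.7 * sqrt(g1 * g2)
  c12 <- max(min(c12, cap), -cap)
  y_all <- c(yp, yc)
  stratum_all <- c(rep("p", length(yp)), stratum_c)
  r0 <- vapply(sort(unique(stratum_all)), function(s) {
    if (s == "p") return(ep)
    ys <- y_all[stratum_all == s]
    max(stats::var(ys) - g2, 0.2 * stats::var(ys))
  }, 0)
  g0 <- switch(constraint,
               full = c(g1, c12, g2),
               rg0 = c(g1, g2),
               rg1 = c(sqrt(g1), sign(c12 + 1e-12) * sqrt(g2)),
               no_genetic = NULL)
  list(g = g0, r = unname(r0))
}

#' Bivariate purebred-crossbred model
#'
#' Treats the purebred individual records and the crossbred cage means of
#' the same trait as two traits: animal effect `a_p` on purebred records,
#' sire effect `s_c` on cage records, jointly normal with covariance
#' `A x [[sigma2_ap, sigma_apsc], [sigma_apsc, sigma2_sc]]` where
#' `sigma2_sc = sigma2_ac / 4`.  The residual covariance is fixed at zero
#' (a hen is present in only one environment); each cage size has its own
#' residual variance.  Fixed effects are fitted per trait (the crossbred
#' side additionally gets the maternal line).
#'
#' @param trait purebred/crossbred response column (same name in both
#'   tables).
#' @param purebred_table,crossbred_table trait tables for the two
#'   contexts.
#' @param ped joint [pedigree] (purebred animals and crossbred sires).
#' @param fixed_p,fixed_c fixed-effect columns for each side.
#' @param constraint `"full"`, `"rg0"`, `"rg1"` or `"no_genetic"`.
#' @param prune prune the pedigree to recorded individuals/sires and
#'   their ancestors.
#' @param init,options passed to [reml_fit()].
#' @return A `varcomp_fit`; estimate names are `sigma2_g1` (purebred
#'   additive), `sigma_g12` (animal-sire covariance), `sigma2_g2` (sire
#'   variance), `sigma2_e_p` and `sigma2_e_c<size>`.
#' @export
fit_purebred_crossbred <- function(trait, purebred_table, crossbred_table,
                                   ped, fixed_p = c("hatch_loc"),
                                   fixed_c = c("hatch_loc", "maternal_line"),
                                   constraint = "full", prune = TRUE,
                                   init = NULL, options = list()) {
  if (!nrow(purebred_table) || !nrow(crossbred_table))
    stop("both purebred and crossbred tables must be non-empty")
  dp <- build_design(purebred_table, trait, fixed_p, genetic = "animal")
  dc <- build_design(crossbred_table, trait, fixed_c, genetic = "sire")
  if (prune) ped <- prune_pedigree(ped, unique(c(dp$gen_id, dc$gen_id)))
  y <- c(dp$y, dc$y)
  X <- as.matrix(Matrix::bdiag(dp$X, dc$X))
  colnames(X) <- c(paste0("p:", colnames(dp$X)), paste0("c:", colnames(dc$X)))
  N <- nrow(ped)
  Z <- rbind(make_Z(dp$gen_id, ped$id, slot = 1L, n_slots = 2L),
             make_Z(dc$gen_id, ped$id, slot = 2L, n_slots = 2L))
  stratum <- c(dp$stratum, dc$stratum)
  if (is.null(init))
    init <- pc_moment_init(dp$y, purebred_table$sire[dp$rows],
                           dc$y, crossbred_table$sire[dc$rows],
                           dc$stratum, constraint)
  model <- reml_model(y, X, Z, build_A_inverse(ped), "bi",
                      resid_strata(stratum))
  fit <- reml_fit(apply_constraint(model, constraint), init, options)
  fit$model <- model
  fit
}

#' Bivariate model for two traits in one population
#'
#' Both traits measured on the same units: genetic covariance through the
#' pedigree (animal effects for purebreds, sire effects for crossbred cage
#' means) and an estimated residual covariance for units carrying both
#' traits.  Records missing one trait are dropped for that trait only
#' (pairwise).  For crossbreds, analyse one cage size at a time.
#'
#' @param trait1,trait2 response columns.
#' @param trait_table one-population trait table.
#' @param ped joint [pedigree]; `NULL` for unrelated sires.
#' @param population `"purebred"` (animal model) or `"crossbred"` (sire
#'   model).
#' @param fixed fixed-effect columns (applied to both traits).
#' @param cage_size optional single cage size to keep (crossbreds).
#' @param constraint `"full"`, `"rg0"`, `"rg1"` or `"no_genetic"`.
#' @param prune prune the pedigree to recorded units' genetic ids and
#'   their ancestors.
#' @param init,options passed to [reml_fit()].
#' @return A `varcomp_fit` with genetic (`sigma2_g1`, `sigma_g12`,
#'   `sigma2_g2`) and residual (`sigma2_e1`, `sigma_e12`, `sigma2_e2`)
#'   components.
#' @export
fit_trait_pair <- function(trait1, trait2, trait_table, ped = NULL,
                           population = c("purebred", "crossbred"),
                           fixed = c("hatch_loc"), cage_size = NULL,
                           constraint = "full", prune = TRUE, init = NULL,
                           options = list()) {
  population <- match.arg(population)
  tt <- trait_table
  if (!is.null(cage_size)) tt <- tt[tt$cage_size %in% cage_size, ]
  genetic <- if (population == "purebred") "animal" else "sire"
  d1 <- build_design(tt, trait1, fixed, genetic = genetic)
  d2 <- build_design(tt, trait2, fixed, genetic = genetic)
  if (!is.null(ped) && prune)
    ped <- prune_pedigree(ped, unique(c(d1$gen_id, d2$gen_id)))
  y <- c(d1$y, d2$y)
  X <- as.matrix(Matrix::bdiag(d1$X, d2$X))
  colnames(X) <- c(paste0(trait1, ":", colnames(d1$X)),
                   paste0(trait2, ":", colnames(d2$X)))
  if (is.null(ped)) {
    levels <- sort(unique(c(d1$gen_id, d2$gen_id)))
    Ainv <- Matrix::Diagonal(length(levels))
    dimnames(Ainv) <- list(levels, levels)
  } else {
    levels <- ped$id
    Ainv <- build_A_inverse(ped)
  }
  Z <- rbind(make_Z(d1$gen_id, levels, slot = 1L, n_slots = 2L),
             make_Z(d2$gen_id, levels, slot = 2L, n_slots = 2L))
  unit <- c(tt$unit_id[d1$rows], tt$unit_id[d2$rows])
  traitn <- c(rep(1L, length(d1$y)), rep(2L, length(d2$y)))
  model <- reml_model(y, X, Z, Ainv, "bi", resid_bivariate(unit, traitn))
  fit <- reml_fit(apply_constraint(model, constraint), init, options)
  fit$model <- model
  fit
}

#' Serialise a fit to JSON
#'
#' Writes estimates, standard errors, the restricted log-likelihood,
#' convergence diagnostics and the model structure to a JSON file.
#'
#' @param fit a `varcomp_fit`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(estimates = as.list(fit$estimates),
              se = if (!is.null(fit$se)) as.list(fit$se) else NULL,
              loglik = fit$loglik,
              converged = fit$converged,
              iterations = unname(fit$iterations),
              n = fit$n,
              model = list(gtype = fit$gtype,
                           g_constraint = fit$g_constraint,
                           residual = fit$r_par_names))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
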