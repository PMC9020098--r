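# REML engine for pedigree-based animal and sire models.
#
# The restricted log-likelihood is evaluated through the mixed-model
# equations identity
#   -2 l = (n - p) log(2 pi) + log|R| + log|G| + log|C| + y' P y,
# where C is the full MME coefficient matrix.  The residual covariance R is
# expressed as a weighted sum of fixed sparse pattern matrices, so all
# cross-products W' B_k W are precomputed once and each likelihood
# evaluation reduces to a sparse Cholesky factorisation of C (with the
# symbolic factorisation reused across iterations).  Optimisation is on an
# unconstrained scale: log variances, atanh correlations (clipped to
# +/- 0.999), and a Cholesky-factor parameterisation for the rank-1
# genetic structure.

# ---- residual structures ----------------------------------------------

# Heterogeneous diagonal residual: one variance per stratum.
resid_strata <- function(stratum) {
  stratum <- as.character(stratum)
  levs <- sort(unique(stratum))
  list(type = "strata", stratum = stratum, levels = levs,
       n_par = length(levs))
}

# Bivariate residual for two traits on the same units: per-unit 2x2 block
# with covariance, units with a single trait get the marginal variance.
resid_bivariate <- function(unit, trait) {
  stopifnot(all(trait %in% 1:2))
  list(type = "biv", unit = as.character(unit), trait = as.integer(trait),
       n_par = 3L)
}

# ---- model container ---------------------------------------------------

#' Assemble design matrices for a REML fit
#'
#' Builds the response vector, a full-rank fixed-effect matrix (reference
#' level dropped per factor; single-level factors dropped with a warning;
#' remaining aliased columns removed), the genetic incidence map and the
#' residual stratum index from a trait table.
#'
#' @param trait_table a trait table (see [build_trait_table()] or
#'   [simulate_trait_table()]); the response column may be `y` or a named
#'   trait column.
#' @param trait name of the response column.
#' @param fixed character vector of fixed-effect factor columns (an
#'   intercept is always included).
#' @param genetic `"animal"` (effect indexed by `unit_id`) or `"sire"`
#'   (effect indexed by `sire`).
#' @return List with `y`, `X`, `gen_id`, `stratum` (`"p"` for purebred
#'   records, `"c<size>"` for cage records), and the row subset used.
#' @export
build_design <- function(trait_table, trait = "y",
                         fixed = c("hatch_loc", "surv_class"),
                         genetic = c("animal", "sire")) {
  genetic <- match.arg(genetic)
  keep <- !is.na(trait_table[[trait]])
  tt <- trait_table[keep, , drop = FALSE]
  if (!nrow(tt)) stop("empty design: no non-missing records for ", trait)
  y <- tt[[trait]]
  Xl <- list(`(Intercept)` = matrix(1, nrow(tt), 1))
  for (f in fixed) {
    v <- tt[[f]]
    if (is.null(v)) stop("unknown fixed-effect column: ", f)
    if (anyNA(v)) stop("missing levels in fixed effect ", f)
    lv <- sort(unique(as.character(v)))
    if (length(lv) < 2L) {
      warning("fixed effect '", f, "' has a single level and was dropped")
      next
    }
    M <- outer(as.character(v), lv[-1L], "==") * 1
    colnames(M) <- paste0(f, lv[-1L])
    Xl[[f]] <- M
  }
  X <- do.call(cbind, Xl)
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  gen_id <- if (genetic == "animal") tt$unit_id else tt$sire
  stratum <- ifelse(tt$population == "purebred", "p",
                    paste0("c", tt$cage_size))
  list(y = y, X = X, gen_id = gen_id, stratum = stratum, rows = which(keep))
}

# Internal: full model description for the engine.
# gtype: "uni", "bi" (with constraint "full" | "rg0" | "rg1"), or "none".
# Z: sparse incidence onto n_levels * n_gtraits columns (slot-major).
reml_model <- function(y, X, Z, Ainv, gtype, rspec,
                       g_constraint = "full", gen_names = NULL) {
  n <- length(y)
  stopifnot(nrow(X) == n, is.null(Z) || nrow(Z) == n)
  list(y = y, X = as.matrix(X), Z = Z, Ainv = Ainv, gtype = gtype,
       g_constraint = g_constraint, rspec = rspec, gen_names = gen_names)
}

# Pattern matrices B_k and log|R| / weight functions for a residual spec.
# Returns list(patterns = list of sparse n x n, weights = function(rpar)
# -> numeric k, logdet = function(rpar) -> scalar, n_par, par_names,
# init = function(y) natural-scale inits, trans/untrans)
resid_engine <- function(rspec, n) {
  if (rspec$type == "strata") {
    levs <- rspec$levels
    pats <- lapply(levs, function(s) {
      idx <- which(rspec$stratum == s)
      Matrix::sparseMatrix(i = idx, j = idx, x = 1, dims = c(n, n))
    })
    counts <- vapply(levs, function(s) sum(rspec$stratum == s), 0L)
    list(patterns = pats,
         weights = function(rp) 1 / rp,
         logdet = function(rp) sum(counts * log(rp)),
         n_par = length(levs),
         par_names = paste0("sigma2_e_", levs),
         is_var = rep(TRUE, length(levs)),
         trans = function(rp) log(rp),
         untrans = function(tp) exp(tp))
  } else { # bivariate by unit
    u <- rspec$unit; tr <- rspec$trait
    paired_units <- intersect(u[tr == 1L], u[tr == 2L])
    p1 <- which(tr == 1L & u %in% paired_units)
    p2 <- which(tr == 2L & u %in% paired_units)
    # align pair indices by unit
    p1 <- p1[order(u[p1])]; p2 <- p2[order(u[p2])]
    s1 <- which(tr == 1L & !(u %in% paired_units))
    s2 <- which(tr == 2L & !(u %in% paired_units))
    diagpat <- function(i) Matrix::sparseMatrix(i = i, j = i, x = rep(1, length(i)),
                                                dims = c(n, n))
    offpat <- if (length(p1))
      Matrix::sparseMatrix(i = c(p1, p2), j = c(p2, p1),
                           x = rep(1, 2 * length(p1)), dims = c(n, n)) else
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(n, n))
    pats <- list(P11 = diagpat(p1), P22 = diagpat(p2), P12 = offpat,
                 S1 = diagpat(s1), S2 = diagpat(s2))
    np <- length(p1)
    list(patterns = pats,
         weights = function(rp) { # rp = (s2e1, se12, s2e2)
           det <- rp[1] * rp[3] - rp[2]^2
           c(rp[3] / det, rp[1] / det, -rp[2] / det,
             1 / rp[1], 1 / rp[3])
         },
         logdet = function(rp) {
           det <- rp[1] * rp[3] - rp[2]^2
           np * log(det) + length(s1) * log(rp[1]) + length(s2) * log(rp[3])
         },
         n_par = 3L,
         par_names = c("sigma2_e1", "sigma_e12", "sigma2_e2"),
         is_var = c(TRUE, FALSE, TRUE),
         trans = function(rp)
           c(log(rp[1]), atanh(max(min(rp[2] / sqrt(rp[1] * rp[3]), 0.999),
                                   -0.999)), log(rp[3])),
         untrans = function(tp)
           c(exp(tp[1]), tanh(tp[2]) * sqrt(exp(tp[1]) * exp(tp[3])),
             exp(tp[3])))
  }
}

# Genetic-structure engine: natural-scale params <-> G0, transforms.
gen_engine <- function(gtype, constraint) {
  if (gtype == "none") return(list(n_par = 0L, par_names = character(0)))
  if (gtype == "uni")
    return(list(n_par = 1L, par_names = "sigma2_g",
                is_var = TRUE,
                G0 = function(gp) matrix(gp, 1, 1),
                trans = function(gp) log(gp),
                untrans = function(tp) exp(tp)))
  switch(constraint,
    full = list(n_par = 3L,
                par_names = c("sigma2_g1", "sigma_g12", "sigma2_g2"),
                is_var = c(TRUE, FALSE, TRUE),
                G0 = function(gp)
                  matrix(c(gp[1], gp[2], gp[2], gp[3]), 2, 2),
                trans = function(gp)
                  c(log(gp[1]),
                    atanh(max(min(gp[2] / sqrt(gp[1] * gp[3]), 0.999),
                              -0.999)), log(gp[3])),
                untrans = function(tp)
                  c(exp(tp[1]), tanh(tp[2]) * sqrt(exp(tp[1]) * exp(tp[3])),
                    exp(tp[3]))),
    rg0 = list(n_par = 2L, par_names = c("sigma2_g1", "sigma2_g2"),
               is_var = c(TRUE, TRUE),
               G0 = function(gp) diag(gp, 2),
               trans = function(gp) log(gp),
               untrans = function(tp) exp(tp)),
    rg1 = list(n_par = 2L, par_names = c("lambda1", "lambda2"),
               is_var = c(FALSE, FALSE),
               G0 = function(gp) tcrossprod(gp),
               trans = function(gp) c(log(max(gp[1], 1e-12)), gp[2]),
               untrans = function(tp) c(exp(tp[1]), tp[2])),
    stop("unknown genetic constraint: ", constraint))
}

# ---- the fitter --------------------------------------------------------

#' Fit variance components by REML
#'
#' Maximises the restricted log-likelihood of a pedigree-based mixed model
#' over an unconstrained parameterisation (log variances, atanh-scaled
#' correlations), with the likelihood evaluated through sparse mixed-model
#' equations.  Standard errors come from the observed information (numeric
#' Hessian on the natural scale) at the optimum.
#'
#' This is the low-level entry point; see [fit_animal()], [fit_sire()],
#' [fit_purebred_crossbred()] and [fit_trait_pair()] for model-specific
#' wrappers.
#'
#' @param model internal model object from `reml_model()`.
#' @param init optional named list with elements `g` and `r` of
#'   natural-scale starting values.
#' @param options list: `maxit` (default 2000), `reltol` (1e-10),
#'   `restarts` (Nelder-Mead restart rounds, default 4), `se` (compute
#'   SEs, default TRUE), `polish` (bounded quasi-Newton polish after each
#'   round, default TRUE).
#' @return An object of class `varcomp_fit`: estimates, log-likelihood,
#'   information matrix and asymptotic covariance of the estimates,
#'   convergence diagnostics, and a closure `loglik_fun(gp, rp)` that
#'   re-evaluates the restricted likelihood at arbitrary natural-scale
#'   parameters.
#' @export
reml_fit <- function(model, init = NULL, options = list()) {
  opt <- utils::modifyList(list(maxit = 2000L, reltol = 1e-10, se = TRUE,
                                polish = TRUE, restarts = 4L), options)
  y <- model$y; X <- model$X
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("singular fixed-effect matrix")
  re <- resid_engine(model$rspec, n)
  ge <- gen_engine(model$gtype, model$g_constraint)
  has_g <- model$gtype != "none"
  nt <- if (model$gtype == "bi") 2L else if (model$gtype == "uni") 1L else 0L

  W <- if (has_g) cbind(methods::as(X, "CsparseMatrix"), model$Z)
       else methods::as(X, "CsparseMatrix")
  M <- lapply(re$patterns, function(B) Matrix::forceSymmetric(
    Matrix::crossprod(W, B %*% W)))
  v <- lapply(re$patterns, function(B) as.numeric(Matrix::crossprod(W, B %*% y)))
  s <- vapply(re$patterns, function(B) as.numeric(Matrix::crossprod(y, B %*% y)), 0)

  # component matrices of C: residual cross-products, then the padded
  # G-inverse blocks; C(theta) is a weighted sum with constant sparsity,
  # assembled by writing into the x-slot of a fixed template.  The rank-1
  # (rr1) genetic structure uses the reduced single-factor system
  # W = [X, lambda1 Z1 + lambda2 Z2] with w ~ N(0, A), so its design
  # cross-products carry lambda-dependent coefficients.
  rg1 <- has_g && nt == 2L && model$g_constraint == "rg1"
  if (has_g) {
    Nlev <- nrow(model$Ainv)
    chA <- Matrix::Cholesky(methods::as(model$Ainv, "CsparseMatrix"),
                            LDL = FALSE)
    logdetAinv <- 2 * as.numeric(Matrix::determinant(chA, sqrt = TRUE)$modulus)
  }
  if (!rg1) {
    comps <- M
    if (has_g) {
      zp <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(p, p))
      zN <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(Nlev, Nlev))
      if (nt == 1L) {
        comps <- c(comps, list(Matrix::forceSymmetric(
          Matrix::bdiag(zp, model$Ainv))))
      } else {
        At <- methods::as(methods::as(model$Ainv, "generalMatrix"),
                          "TsparseMatrix")
        K12 <- Matrix::sparseMatrix(i = c(At@i + 1L, At@j + 1L + Nlev),
                                    j = c(At@j + 1L + Nlev, At@i + 1L),
                                    x = c(At@x, At@x) / 2,
                                    dims = c(2L * Nlev, 2L * Nlev))
        comps <- c(comps, list(
          Matrix::forceSymmetric(Matrix::bdiag(zp, model$Ainv, zN)),
          Matrix::forceSymmetric(Matrix::bdiag(zp, zN, model$Ainv)),
          Matrix::forceSymmetric(Matrix::bdiag(zp, K12 + Matrix::t(K12)))))
      }
    }
    dimC <- ncol(W)
    # coefficients aligned with comps; rhs and y'Ry from the full W blocks
    coef_all <- function(wts, gp) {
      if (!has_g) return(wts)
      G0 <- ge$G0(gp)
      if (nt == 1L) {
        if (!is.finite(G0[1, 1]) || G0[1, 1] <= 0) return(NULL)
        return(c(wts, 1 / G0[1, 1]))
      }
      # closed-form 2x2 inverse: immune to the conditioning failures of
      # solve() at extreme variance ratios explored by the optimizer
      a <- G0[1, 1]; b <- G0[2, 2]; c12 <- G0[1, 2]
      dG <- a * b - c12^2
      if (!is.finite(dG) || dG <= 1e-14 * a * b) return(NULL)
      c(wts, b / dG, a / dG, -c12 / dG)
    }
    logdetG_fun <- function(gp) {
      if (!has_g) return(0)
      Nlev * log(det(ge$G0(gp))) - nt * logdetAinv
    }
    rhs_fun <- function(wts, gp) Reduce(`+`, Map(`*`, v, wts))
  } else {
    Xs <- methods::as(X, "CsparseMatrix")
    Z1 <- model$Z[, seq_len(Nlev), drop = FALSE]
    Z2 <- model$Z[, Nlev + seq_len(Nlev), drop = FALSE]
    dimC <- p + Nlev
    pad_tr <- function(Mx) { # p x N block into top-right + transpose
      Tx <- methods::as(methods::as(Mx, "generalMatrix"), "TsparseMatrix")
      Matrix::sparseMatrix(i = c(Tx@i + 1L, Tx@j + 1L + p),
                           j = c(Tx@j + 1L + p, Tx@i + 1L),
                           x = rep(Tx@x, 2), dims = c(dimC, dimC))
    }
    pad_br <- function(Mx) { # N x N block into bottom-right
      Tx <- methods::as(methods::as(Mx, "generalMatrix"), "TsparseMatrix")
      Matrix::sparseMatrix(i = Tx@i + 1L + p, j = Tx@j + 1L + p, x = Tx@x,
                           dims = c(dimC, dimC))
    }
    pad_tl <- function(Mx) { # p x p block into top-left
      Tx <- methods::as(methods::as(Mx, "generalMatrix"), "TsparseMatrix")
      Matrix::sparseMatrix(i = Tx@i + 1L, j = Tx@j + 1L, x = Tx@x,
                           dims = c(dimC, dimC))
    }
    comps <- list()
    vX <- v1 <- v2 <- list()
    for (k in seq_along(re$patterns)) {
      B <- re$patterns[[k]]
      comps <- c(comps, list(
        pad_tl(Matrix::crossprod(Xs, B %*% Xs)),
        pad_tr(Matrix::crossprod(Xs, B %*% Z1)),
        pad_tr(Matrix::crossprod(Xs, B %*% Z2)),
        pad_br(Matrix::crossprod(Z1, B %*% Z1)),
        pad_br(Matrix::crossprod(Z1, B %*% Z2) +
                 Matrix::crossprod(Z2, B %*% Z1)),
        pad_br(Matrix::crossprod(Z2, B %*% Z2))))
      vX[[k]] <- as.numeric(Matrix::crossprod(Xs, B %*% y))
      v1[[k]] <- as.numeric(Matrix::crossprod(Z1, B %*% y))
      v2[[k]] <- as.numeric(Matrix::crossprod(Z2, B %*% y))
    }
    comps <- c(comps, list(pad_br(model$Ainv)))
    coef_all <- function(wts, gp) {
      l1 <- gp[1]; l2 <- gp[2]
      c(as.vector(vapply(wts, function(w)
        w * c(1, l1, l2, l1^2, l1 * l2, l2^2), numeric(6))), 1)
    }
    logdetG_fun <- function(gp) -logdetAinv
    rhs_fun <- function(wts, gp) {
      out <- numeric(dimC)
      for (k in seq_along(wts)) {
        out[seq_len(p)] <- out[seq_len(p)] + wts[k] * vX[[k]]
        out[p + seq_len(Nlev)] <- out[p + seq_len(Nlev)] +
          wts[k] * (gp[1] * v1[[k]] + gp[2] * v2[[k]])
      }
      out
    }
  }
  comps <- lapply(comps, function(m)
    methods::as(Matrix::forceSymmetric(m), "CsparseMatrix"))
  tmpl <- Reduce(`+`, lapply(comps, abs))
  tmpl <- methods::as(Matrix::forceSymmetric(tmpl), "CsparseMatrix")
  key_of <- function(m) {
    j <- rep.int(seq_len(ncol(m)), diff(m@p))
    as.numeric(j) * dimC + m@i
  }
  keyT <- key_of(tmpl)
  maps <- lapply(comps, function(m) {
    idx <- match(key_of(m), keyT)
    if (anyNA(idx)) stop("internal error: template sparsity mismatch")
    idx
  })
  xvals <- lapply(comps, function(m) m@x)

  cache <- new.env(parent = emptyenv())
  chm_update <- methods::getMethod("update", "CHMfactor")
  var_floor <- 1e-10 * stats::var(y)

  neg2 <- function(gp, rp) {
    wts <- re$weights(rp)
    co <- coef_all(wts, gp)
    if (is.null(co) || any(!is.finite(co))) return(NA_real_)
    logdetG <- logdetG_fun(gp)
    if (!is.finite(logdetG)) return(NA_real_)
    xC <- numeric(length(keyT))
    for (k in seq_along(comps))
      if (co[k] != 0) xC[maps[[k]]] <- xC[maps[[k]]] + co[k] * xvals[[k]]
    C <- tmpl
    C@x <- xC
    rhs <- rhs_fun(wts, gp)
    yRy <- sum(s * wts)
    # CHOLMOD signals an indefinite C by a warning; reject such points
    ch <- tryCatch({
      if (is.null(cache$ch)) cache$ch <- Matrix::Cholesky(C, LDL = FALSE,
                                                          super = NA)
      chm_update(cache$ch, C)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(ch)) return(NA_real_)
    logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    yPy <- yRy - sum(rhs * sol)
    (n - p) * log(2 * pi) + re$logdet(rp) + logdetG + logdetC + yPy
  }
  loglik_fun <- function(gp, rp) -0.5 * neg2(gp, rp)

  # starting values: equal split of the phenotypic variance
  vy <- stats::var(y)
  g0 <- if (!is.null(init$g)) init$g else switch(model$gtype,
    none = numeric(0),
    uni = 0.3 * vy,
    bi = switch(model$g_constraint,
                full = c(0.3 * vy, 0.05 * vy, 0.3 * vy),
                rg0 = c(0.3 * vy, 0.3 * vy),
                rg1 = c(sqrt(0.3 * vy), sqrt(0.3 * vy))))
  r0 <- if (!is.null(init$r)) init$r else
    if (model$rspec$type == "strata") rep(0.7 * vy, re$n_par)
    else c(0.7 * vy, 0, 0.7 * vy)

  ng <- ge$n_par
  split_par <- function(tp) list(g = if (ng) ge$untrans(tp[seq_len(ng)])
                                     else numeric(0),
                                 r = re$untrans(tp[ng + seq_len(re$n_par)]))
  obj <- function(tp) {
    pr <- split_par(tp)
    val <- neg2(pr$g, pr$r)
    if (!is.finite(val)) 1e12 else val
  }
  tp0 <- c(if (ng) ge$trans(g0), re$trans(r0))

  # bounds on the transformed scale: variance floor, correlation clip
  lo <- rep(-Inf, length(tp0)); hi <- rep(Inf, length(tp0))
  is_var_all <- c(if (ng) ge$is_var, re$is_var)
  is_log <- is_var_all
  lo[is_log] <- log(var_floor)
  hi[is_log] <- log(1e6 * vy)
  corr_par <- !is_var_all &
    c(if (ng) ge$par_names, re$par_names) %in% c("sigma_g12", "sigma_e12")
  lo[corr_par] <- atanh(-0.999); hi[corr_par] <- atanh(0.999)

  # central differences; the step balances truncation against rounding
  # noise in an objective of magnitude ~ n log(2 pi)
  numgrad <- function(par) vapply(seq_along(par), function(j) {
    h <- 1e-4 * (abs(par[j]) + 1e-2)
    e <- par; e[j] <- e[j] + h
    f1 <- obj(e); e[j] <- e[j] - 2 * h
    (f1 - obj(e)) / (2 * h)
  }, 0)
  bounded <- function(par) par <= lo + 1e-7 | par >= hi - 1e-7

  total_iters <- 0L
  if (length(tp0) == 1L) {
    best <- stats::optim(tp0, obj, method = "Brent",
                         lower = max(lo, tp0 - 30), upper = min(hi, tp0 + 30),
                         control = list(maxit = opt$maxit))
    total_iters <- best$counts[1]
    gr <- numgrad(best$par)
  } else {
    # Nelder-Mead with restarts (a collapsed simplex can stall far from
    # the optimum), each round followed by a bounded quasi-Newton polish;
    # stop when a round no longer improves and the gradient is small
    best <- list(par = tp0, value = obj(tp0))
    gr <- rep(Inf, length(tp0))
    for (round in seq_len(opt$restarts)) {
      prev <- best$value
      f1 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = opt$maxit,
                                        reltol = opt$reltol))
      total_iters <- total_iters + f1$counts[1]
      if (f1$value <= best$value) best <- f1
      if (opt$polish) {
        f2 <- tryCatch(
          stats::optim(best$par, obj, method = "L-BFGS-B", lower = lo,
                       upper = hi,
                       control = list(maxit = 200L, factr = 1e4)),
          error = function(e) NULL)
        if (!is.null(f2)) {
          total_iters <- total_iters + f2$counts[1]
          if (f2$value <= best$value) best <- f2
        }
      }
      gr <- numgrad(best$par)
      if (prev - best$value < 1e-7 && all(abs(gr[!bounded(best$par)]) < 0.05))
        break
    }
  }
  pr <- split_par(best$par)
  ll <- -0.5 * best$value
  converged <- all(abs(gr[!bounded(best$par)]) < 0.05)

  est <- c(pr$g, pr$r)
  names(est) <- c(if (ng) ge$par_names, re$par_names)

  info <- vcov <- NULL
  if (opt$se) {
    th <- est
    nb <- length(th)
    hs <- 1e-4 * (abs(th) + 1e-6)
    f0 <- neg2(pr$g, pr$r)
    fneg2 <- function(x) {
      val <- neg2(x[seq_len(ng)], x[ng + seq_len(re$n_par)])
      if (is.finite(val)) val else NA_real_
    }
    H <- matrix(NA_real_, nb, nb)
    for (a in seq_len(nb)) for (b in a:nb) {
      if (a == b) {
        xp <- th; xp[a] <- th[a] + hs[a]
        xm <- th; xm[a] <- th[a] - hs[a]
        H[a, a] <- (fneg2(xp) - 2 * f0 + fneg2(xm)) / hs[a]^2
      } else {
        xpp <- th; xpp[c(a, b)] <- th[c(a, b)] + hs[c(a, b)]
        xpm <- th; xpm[a] <- th[a] + hs[a]; xpm[b] <- th[b] - hs[b]
        xmp <- th; xmp[a] <- th[a] - hs[a]; xmp[b] <- th[b] + hs[b]
        xmm <- th; xmm[c(a, b)] <- th[c(a, b)] - hs[c(a, b)]
        H[a, b] <- H[b, a] <-
          (fneg2(xpp) - fneg2(xpm) - fneg2(xmp) + fneg2(xmm)) /
          (4 * hs[a] * hs[b])
      }
    }
    info <- H / 2  # observed information of the log-likelihood
    vcov <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vcov)) dimnames(vcov) <- list(names(est), names(est))
    if (!is.null(info)) dimnames(info) <- list(names(est), names(est))
  }
  structure(list(estimates = est, g = pr$g, r = pr$r, loglik = ll,
                 information = info, vcov = vcov,
                 se = if (!is.null(vcov)) sqrt(pmax(diag(vcov), 0)) else NULL,
                 converged = converged, gradient = gr,
                 iterations = total_iters, n = n, p = p,
                 gtype = model$gtype, g_constraint = model$g_constraint,
                 r_par_names = re$par_names,
                 loglik_fun = loglik_fun),
            class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("REML variance-component fit (", x$gtype,
      if (x$gtype == "bi") paste0("/", x$g_constraint), ")\n", sep = "")
  est <- data.frame(estimate = x$estimates,
                    se = if (!is.null(x$se)) x$se else NA)
  print(round(est, 4))
  cat(sprintf("logLik = %.4f   n = %d   converged: %s\n",
              x$loglik, x$n, x$converged))
  invisible(x)
}
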