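#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam` (character or
#' integer-like ids; `0` or `NA` marks an unknown parent).  Individuals must
#' be topologically ordered: every parent appears as an `id` before any of
#' its offspring.
#'
#' @param id vector of unique individual ids.
#' @param sire,dam parent ids; `0` or `NA` for unknown.
#' @return An object of class `pedigree`: a data frame with character
#'   columns `id`, `sire`, `dam` plus integer columns `sire_idx`, `dam_idx`
#'   (0 = unknown) used internally.
#' @export
pedigree <- function(id, sire, dam) {
  id   <- as.character(id)
  sire <- as.character(sire)
  dam  <- as.character(dam)
  sire[is.na(sire)] <- "0"
  dam[is.na(dam)]   <- "0"
  if (anyDuplicated(id))
    stop("duplicated individual ids in pedigree")
  if (any(id == "0"))
    stop("'0' is reserved for unknown parents")
  if (any(sire == id) || any(dam == id))
    stop("individual recorded as its own parent")
  pos <- seq_along(id)
  names(pos) <- id
  sire_idx <- unname(ifelse(sire == "0", 0L, pos[sire]))
  dam_idx  <- unname(ifelse(dam  == "0", 0L, pos[dam]))
  if (anyNA(sire_idx) || anyNA(dam_idx))
    stop("parent id not present in pedigree")
  if (any(sire_idx >= pos) || any(dam_idx >= pos))
    stop("pedigree not topologically ordered (parents must precede offspring)")
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    sire_idx = as.integer(sire_idx),
                    dam_idx = as.integer(dam_idx),
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read / write pedigree CSV
#'
#' Three-column CSV `id,sire,dam` with `0` for unknown parents, ids
#' topologically ordered.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a [pedigree] object.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  pedigree(d$id, d$sire, d$dam)
}

#' @rdname read_pedigree
#' @param ped a [pedigree].
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped[, c("id", "sire", "dam")], path,
                   row.names = FALSE, quote = FALSE)
}

#' Export a sparse matrix as coordinate triplets
#'
#' Writes `row,col,value` CSV (1-based indices, ids in a header comment
#' omitted; row/col names preserved as separate columns when present).
#' Intended for handing `A^-1` to external mixed-model software.
#'
#' @param m a sparse (symmetric) matrix, e.g. from [build_A_inverse()].
#' @param path output file.
#' @export
write_triplets <- function(m, path) {
  Tm <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  d <- data.frame(row = Tm@i + 1L, col = Tm@j + 1L, value = Tm@x)
  if (!is.null(rownames(m))) {
    d$row_id <- rownames(m)[d$row]
    d$col_id <- colnames(m)[d$col]
  }
  d <- d[order(d$col, d$row), ]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Prune a pedigree to the individuals relevant for a set of records
#'
#' Restricts the pedigree to the individuals carrying records and their
#' ancestors, then absorbs recordless base parents with a single offspring
#' (their effect is indistinguishable from the offspring's
#' Mendelian-sampling deviation, so the restricted likelihood is
#' unchanged).  Standard pedigree pruning: it can shrink the mixed-model
#' equations dramatically when many pedigree members carry no records.
#'
#' @param ped a [pedigree].
#' @param ids ids of individuals with records (for sire models, the
#'   sires).
#' @return A pruned [pedigree].
#' @export
prune_pedigree <- function(ped, ids) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  keep <- ped$id %in% ids
  if (!any(keep)) stop("no record ids found in pedigree")
  has_rec <- keep
  for (i in n:1) if (keep[i]) {
    if (ped$sire_idx[i] > 0L) keep[ped$sire_idx[i]] <- TRUE
    if (ped$dam_idx[i] > 0L) keep[ped$dam_idx[i]] <- TRUE
  }
  sire <- ped$sire; dam <- ped$dam
  repeat {
    noff <- table(factor(c(sire[keep], dam[keep]),
                         levels = ped$id))
    base <- keep & !has_rec & sire == "0" & dam == "0" &
      as.integer(noff[ped$id]) == 1L
    if (!any(base)) break
    drop_ids <- ped$id[base]
    sire[sire %in% drop_ids] <- "0"
    dam[dam %in% drop_ids] <- "0"
    keep[base] <- FALSE
  }
  pedigree(ped$id[keep], sire[keep], dam[keep])
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes Wright's inbreeding coefficient F for every individual from the
#' L'DL factorisation of the numerator relationship matrix, without forming
#' A.  Base individuals (both parents unknown) have F = 0.
#'
#' @param ped a [pedigree].
#' @return Named numeric vector of F, in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  F <- numeric(n)
  # diagonal of A via sparse evaluation of L rows (Meuwissen & Luo 1992)
  Dvec <- numeric(n)
  for (i in seq_len(n)) {
    Fs <- if (s[i] > 0L) F[s[i]] else -1
    Fd <- if (d[i] > 0L) F[d[i]] else -1
    Dvec[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (s[i] == 0L && d[i] == 0L) { F[i] <- 0; next }
    # accumulate a_ii = sum_j L_ij^2 D_j by walking ancestors
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * Dvec[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  names(F) <- ped$id
  F
}

#' Dense additive relationship matrix (tabular method)
#'
#' Intended as an oracle for small pedigrees; the REML engine uses the
#' sparse inverse from [build_A_inverse()] instead.
#'
#' @param ped a [pedigree].
#' @param ids optional subset of ids for the returned matrix (rows/columns);
#'   relationships are still computed over the full pedigree.
#' @return Dense numeric matrix with dimnames.
#' @export
build_A_dense <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    as_ <- if (s[i] > 0L) A[seq_len(i - 1L), s[i]] else numeric(i - 1L)
    ad_ <- if (d[i] > 0L) A[seq_len(i - 1L), d[i]] else numeric(i - 1L)
    if (i > 1L) {
      off <- 0.5 * (as_ + ad_)
      A[seq_len(i - 1L), i] <- off
      A[i, seq_len(i - 1L)] <- off
    }
    Fsd <- if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
    A[i, i] <- 1 + Fsd
  }
  dimnames(A) <- list(ped$id, ped$id)
  if (!is.null(ids)) A <- A[ids, ids, drop = FALSE]
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: individual i with parents s, d
#' contributes 1/d_i to the (i,i) cell, -1/(2 d_i) to (i,parent) and
#' 1/(4 d_i) to (parent,parent'), where d_i is the Mendelian-sampling
#' variance given parental inbreeding.
#'
#' @param ped a [pedigree].
#' @return Sparse symmetric `dsCMatrix` with dimnames in pedigree order.
#' @export
build_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  F <- inbreeding(ped)
  Fs <- Fd <- numeric(n)
  Fs[s > 0L] <- F[s[s > 0L]]
  Fd[d > 0L] <- F[d[d > 0L]]
  npar <- (s > 0L) + (d > 0L)
  Dvec <- ifelse(npar == 2L, 0.5 - 0.25 * (Fs + Fd),
          ifelse(npar == 1L, 0.75 - 0.25 * (Fs + Fd), 1))
  w <- 1 / Dvec
  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  idx <- seq_len(n)
  push(idx, idx, w)
  for (p in list(s, d)) {
    has <- p > 0L
    if (any(has)) {
      push(idx[has], p[has], -0.5 * w[has])
      push(p[has], idx[has], -0.5 * w[has])
      push(p[has], p[has], 0.25 * w[has])
    }
  }
  both <- s > 0L & d > 0L
  if (any(both)) {
    push(s[both], d[both], 0.25 * w[both])
    push(d[both], s[both], 0.25 * w[both])
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}
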