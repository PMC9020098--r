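# Independent oracles used across the suite.

# Dense restricted log-likelihood of y ~ N(Xb, V):
#   l = -1/2 [ (n-p) log 2pi + log|V| + log|X' V^-1 X| + y'Py ]
dense_reml_ll <- function(y, X, V) {
  X <- as.matrix(X)
  n <- length(y)
  p <- qr(X)$rank
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  beta <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(crossprod(r, Vi %*% r))
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
            quad)
}

# Phenotypic covariance of records under a (possibly bivariate) genetic
# structure: V_ij = G0[slot_i, slot_j] * A[gid_i, gid_j] + R_ij.
dense_V <- function(gen_id, slot, A, G0, R) {
  n <- length(gen_id)
  G0 <- as.matrix(G0)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    V[i, j] <- G0[slot[i], slot[j]] * A[gen_id[i], gen_id[j]]
  V + R
}

# Random valid pedigree: n_base founders, then n_desc individuals whose
# parents are drawn from earlier individuals (possibly unknown).
random_pedigree <- function(n_base, n_desc, seed = 1) {
  set.seed(seed)
  id <- sprintf("I%04d", seq_len(n_base + n_desc))
  sire <- dam <- rep("0", n_base + n_desc)
  for (i in (n_base + 1):(n_base + n_desc)) {
    cand <- id[seq_len(i - 1)]
    pick <- sample(cand, 2)
    if (runif(1) < 0.85) sire[i] <- pick[1]
    if (runif(1) < 0.85) dam[i] <- pick[2]
  }
  pedigree(id, sire, dam)
}

# Balanced paternal half-sib design with unrelated sires: returns a trait
# table in the package's crossbred layout (for fit_sire with ped = NULL).
balanced_sire_data <- function(n_sires, n_per_sire, sigma2_s, sigma2_e,
                               mu = 10, seed = 1) {
  set.seed(seed)
  sire <- rep(sprintf("S%03d", seq_len(n_sires)), each = n_per_sire)
  s_eff <- rnorm(n_sires, 0, sqrt(sigma2_s))
  names(s_eff) <- sprintf("S%03d", seq_len(n_sires))
  y <- mu + s_eff[sire] + rnorm(length(sire), 0, sqrt(sigma2_e))
  data.frame(unit_id = paste0("u", seq_along(y)), y = as.numeric(y),
             sire = sire, population = "crossbred", cage_size = 6L,
             hatch_loc = "H1", maternal_line = "M1",
             stringsAsFactors = FALSE)
}

# ANOVA (method-of-moments) estimates for a balanced one-way sire design.
anova_sire_varcomp <- function(tab) {
  n_per <- table(tab$sire)
  stopifnot(length(unique(n_per)) == 1)
  n0 <- unname(n_per[1])
  a <- stats::anova(stats::lm(y ~ sire, data = tab))
  msb <- a$`Mean Sq`[1]
  msw <- a$`Mean Sq`[2]
  c(sigma2_s = (msb - msw) / n0, sigma2_e = msw)
}
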