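test_that("sparse MME likelihood equals the dense oracle off-optimum", {
  # univariate animal model, real pedigree, 30 records
  rp <- random_pedigree(8, 32, seed = 21)
  ids <- rp$id[9:38]
  set.seed(22)
  tab <- data.frame(unit_id = ids, y = rnorm(30, 10, 2),
                    population = "purebred", cage_size = NA_integer_,
                    sire = NA, hatch_loc = rep(c("H1", "H2"), 15),
                    stringsAsFactors = FALSE)
  fit <- fit_animal(tab, rp, fixed = "hatch_loc", prune = FALSE,
                    options = list(se = FALSE, maxit = 200))
  A <- build_A_dense(rp)
  d <- build_design(tab, "y", "hatch_loc", "animal")
  for (theta in list(c(1, 3), c(0.5, 2.5), c(4, 1))) {
    V <- dense_V(d$gen_id, rep(1L, 30), A, matrix(theta[1]),
                 diag(theta[2], 30))
    expect_equal(fit$loglik_fun(theta[1], theta[2]),
                 dense_reml_ll(d$y, d$X, V), tolerance = 1e-6)
  }
})

test_that("bivariate purebred-crossbred likelihood matches the dense oracle", {
  des <- population_design(n_sires = 6, n_purebred_per_sire = 3,
                           n_crossbred_per_sire = 12, cage_sizes = 6,
                           n_hatch_locations = 2, n_maternal_lines = 2,
                           seed = 31)
  pop <- simulate_pedigree(des)
  arch <- genetic_architecture(sigma2_ap = 5, sigma2_ac = 4, r_pc = 0.5,
                               sigma2_ep = 10, sigma2_ec = c("6" = 3),
                               mu_p = 20, mu_c = 18)
  tt <- simulate_trait_table(pop, arch, seed = 8)
  pb <- tt[tt$population == "purebred", ]
  cb <- tt[tt$population == "crossbred", ]
  fit <- fit_purebred_crossbred("y", pb, cb, pop$ped,
                                fixed_p = "hatch_loc",
                                fixed_c = c("hatch_loc", "maternal_line"),
                                prune = FALSE,
                                options = list(se = FALSE, maxit = 300))
  A <- build_A_dense(pop$ped)
  dp <- build_design(pb, "y", "hatch_loc", "animal")
  dc <- build_design(cb, "y", c("hatch_loc", "maternal_line"), "sire")
  gid <- c(dp$gen_id, dc$gen_id)
  slot <- rep(1:2, c(length(dp$y), length(dc$y)))
  X <- as.matrix(Matrix::bdiag(dp$X, dc$X))
  y <- c(dp$y, dc$y)
  for (th in list(c(5, 1.2, 1.1, 9, 3), c(3, -0.5, 2, 12, 4))) {
    G0 <- matrix(c(th[1], th[2], th[2], th[3]), 2)
    R <- diag(c(rep(th[4], length(dp$y)), rep(th[5], length(dc$y))))
    V <- dense_V(gid, slot, A, G0, R)
    expect_equal(fit$loglik_fun(c(th[1], th[2], th[3]),
                                c(th[5], th[4])),
                 dense_reml_ll(y, X, V), tolerance = 1e-6)
  }
  # rank-1 path: singular G0 = lambda lambda' through the reduced system
  fr1 <- fit_purebred_crossbred("y", pb, cb, pop$ped,
                                fixed_p = "hatch_loc",
                                fixed_c = c("hatch_loc", "maternal_line"),
                                constraint = "rg1", prune = FALSE,
                                options = list(se = FALSE, maxit = 50))
  lam <- c(2, 0.7)
  Vr1 <- dense_V(gid, slot, A, tcrossprod(lam),
                 diag(c(rep(9, length(dp$y)), rep(3, length(dc$y)))))
  expect_equal(fr1$loglik_fun(lam, c(3, 9)), dense_reml_ll(y, X, Vr1),
               tolerance = 1e-6)
})

test_that("trait-pair likelihood with residual covariance matches dense", {
  des <- population_design(n_sires = 5, n_purebred_per_sire = 5,
                           n_crossbred_per_sire = 0,
                           n_hatch_locations = 2, seed = 41)
  pop <- simulate_pedigree(des)
  G0 <- matrix(c(2, 0.8, 0.8, 1.5), 2)
  R0 <- matrix(c(4, 1, 1, 3), 2)
  tp <- simulate_trait_pair(pop, G0, R0, seed = 9)
  tp$population <- "purebred"; tp$cage_size <- NA_integer_
  tp$y2[1:3] <- NA  # pairwise missing
  fit <- fit_trait_pair("y1", "y2", tp, pop$ped, "purebred",
                        fixed = "hatch_loc", prune = FALSE,
                        options = list(se = FALSE, maxit = 300))
  A <- build_A_dense(pop$ped)
  d1 <- build_design(tp, "y1", "hatch_loc", "animal")
  d2 <- build_design(tp, "y2", "hatch_loc", "animal")
  gid <- c(d1$gen_id, d2$gen_id)
  slot <- rep(1:2, c(length(d1$y), length(d2$y)))
  y <- c(d1$y, d2$y)
  X <- as.matrix(Matrix::bdiag(d1$X, d2$X))
  th_g <- c(2.2, 0.6, 1.4); th_r <- c(3.5, 0.9, 2.8)
  n1 <- length(d1$y); n2 <- length(d2$y)
  R <- matrix(0, n1 + n2, n1 + n2)
  diag(R) <- c(rep(th_r[1], n1), rep(th_r[3], n2))
  unit <- c(tp$unit_id[d1$rows], tp$unit_id[d2$rows])
  for (i in seq_len(n1)) {
    j <- which(unit[(n1 + 1):(n1 + n2)] == unit[i])
    if (length(j)) R[i, n1 + j] <- R[n1 + j, i] <- th_r[2]
  }
  G0t <- matrix(c(th_g[1], th_g[2], th_g[2], th_g[3]), 2)
  V <- dense_V(gid, slot, A, G0t, R)
  expect_equal(fit$loglik_fun(th_g, th_r), dense_reml_ll(y, X, V),
               tolerance = 1e-6)
})

test_that("balanced sire design: REML equals the ANOVA estimators", {
  tab <- balanced_sire_data(40, 10, sigma2_s = 2, sigma2_e = 8, seed = 42)
  fit <- suppressWarnings(fit_sire(tab, ped = NULL, fixed = character(0)))
  mom <- anova_sire_varcomp(tab)
  expect_equal(unname(fit$estimates[["sigma2_g"]]),
               unname(mom["sigma2_s"]), tolerance = 1e-4)
  expect_equal(unname(fit$estimates[["sigma2_e_c6"]]),
               unname(mom["sigma2_e"]), tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("likelihood is invariant to the fixed-effect reference level", {
  tab <- balanced_sire_data(20, 8, 2, 8, seed = 5)
  tab$hatch_loc <- rep(c("H1", "H2", "H3", "H4"), 40)
  f1 <- suppressWarnings(fit_sire(tab, NULL, fixed = "hatch_loc",
                                  options = list(se = FALSE)))
  tab2 <- tab
  # relabel so a different level sorts first (new reference)
  tab2$hatch_loc <- chartr("H", "Z", tab2$hatch_loc)
  tab2$hatch_loc[tab2$hatch_loc == "Z4"] <- "A4"
  f2 <- suppressWarnings(fit_sire(tab2, NULL, fixed = "hatch_loc",
                                  options = list(se = FALSE)))
  expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
})

test_that("a 2-sire toy problem attains the dense grid optimum", {
  set.seed(3)
  tab <- balanced_sire_data(2, 2, 1, 2, seed = 13)
  fit <- suppressWarnings(fit_sire(tab, NULL, fixed = character(0),
                                   options = list(se = FALSE)))
  A <- diag(2); dimnames(A) <- list(c("S001", "S002"), c("S001", "S002"))
  grid <- expand.grid(s = exp(seq(log(0.01), log(20), length.out = 60)),
                      e = exp(seq(log(0.05), log(20), length.out = 60)))
  ll <- apply(grid, 1, function(g) {
    V <- dense_V(tab$sire, rep(1L, 4), A, matrix(g[1]), diag(g[2], 4))
    dense_reml_ll(tab$y, matrix(1, 4, 1), V)
  })
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("null data push the genetic variance to the boundary", {
  tab <- balanced_sire_data(30, 8, sigma2_s = 0, sigma2_e = 5, seed = 77)
  fit <- suppressWarnings(fit_sire(tab, NULL, fixed = character(0)))
  expect_lt(fit$estimates[["sigma2_g"]], 0.3)
  null <- fit_constrained(fit$model, "no_genetic")
  expect_lt(2 * (fit$loglik - null$loglik), 6)
})

test_that("trait-pair fits recover degenerate and null correlations", {
  des <- population_design(n_sires = 30, n_purebred_per_sire = 10,
                           n_crossbred_per_sire = 0, seed = 51)
  pop <- simulate_pedigree(des)
  # duplicated trait: genetic and residual correlations -> 1
  G0 <- matrix(c(3, 2.9999, 2.9999, 3), 2)
  tp <- simulate_trait_pair(pop, G0, matrix(c(2, 1.9999, 1.9999, 2), 2),
                            seed = 3)
  tp$y2 <- tp$y1
  tp$population <- "purebred"; tp$cage_size <- NA_integer_
  fit <- fit_trait_pair("y1", "y2", tp, pop$ped, "purebred",
                        fixed = character(0),
                        options = list(se = FALSE))
  gp <- genetic_params(fit, "trait_pair")
  expect_gt(gp$estimate[gp$parameter == "r_g"], 0.98)
  expect_gt(gp$estimate[gp$parameter == "r_P"], 0.98)
  # independent traits: correlations near 0
  tp2 <- simulate_trait_pair(pop, diag(c(3, 3)), diag(c(5, 5)), seed = 4)
  tp2$population <- "purebred"; tp2$cage_size <- NA_integer_
  fit2 <- fit_trait_pair("y1", "y2", tp2, pop$ped, "purebred",
                         fixed = character(0),
                         options = list(se = FALSE))
  gp2 <- genetic_params(fit2, "trait_pair")
  expect_lt(abs(gp2$estimate[gp2$parameter == "r_P"]), 0.25)
})

test_that("genetic-correlation constraints behave under their truths", {
  des <- population_design(n_sires = 40, n_purebred_per_sire = 8,
                           n_crossbred_per_sire = 12, cage_sizes = 6,
                           seed = 61)
  pop <- simulate_pedigree(des)
  # rank-1 truth: rg1 fit loses nothing vs the full fit
  arch1 <- genetic_architecture(sigma2_ap = 8, sigma2_ac = 8, r_pc = 1,
                                sigma2_ep = 10, sigma2_ec = c("6" = 4),
                                mu_p = 0, mu_c = 0)
  tt <- simulate_trait_table(pop, arch1, seed = 6)
  pb <- tt[tt$population == "purebred", ]
  cb <- tt[tt$population == "crossbred", ]
  opts <- list(se = FALSE)
  full <- fit_purebred_crossbred("y", pb, cb, pop$ped,
                                 fixed_p = character(0),
                                 fixed_c = character(0), options = opts)
  r1 <- fit_purebred_crossbred("y", pb, cb, pop$ped,
                               fixed_p = character(0),
                               fixed_c = character(0),
                               constraint = "rg1", options = opts)
  expect_lt(abs(full$loglik - r1$loglik), 0.05)
  # zero-correlation truth: rg0 fit loses little
  arch0 <- genetic_architecture(sigma2_ap = 8, sigma2_ac = 8, r_pc = 0,
                                sigma2_ep = 10, sigma2_ec = c("6" = 4),
                                mu_p = 0, mu_c = 0)
  tt0 <- simulate_trait_table(pop, arch0, seed = 7)
  pb0 <- tt0[tt0$population == "purebred", ]
  cb0 <- tt0[tt0$population == "crossbred", ]
  full0 <- fit_purebred_crossbred("y", pb0, cb0, pop$ped,
                                  fixed_p = character(0),
                                  fixed_c = character(0), options = opts)
  rg0 <- fit_purebred_crossbred("y", pb0, cb0, pop$ped,
                                fixed_p = character(0),
                                fixed_c = character(0),
                                constraint = "rg0", options = opts)
  expect_lt(2 * (full0$loglik - rg0$loglik), 6)
  expect_gte(full0$loglik + 1e-6, rg0$loglik)
})

test_that("information-based SEs track the replicate spread", {
  ests <- ses <- numeric(40)
  for (i in seq_len(40)) {
    tab <- balanced_sire_data(30, 10, 2, 8, seed = 100 + i)
    f <- suppressWarnings(fit_sire(tab, NULL, fixed = character(0)))
    ests[i] <- f$estimates[["sigma2_g"]]
    ses[i] <- f$se[["sigma2_g"]]
  }
  ratio <- median(ses) / sd(ests)
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.4)
})

test_that("design construction validates input", {
  tab <- balanced_sire_data(4, 3, 1, 1, seed = 2)
  tab$y <- NA
  expect_error(build_design(tab, "y"), "empty design")
  tab2 <- balanced_sire_data(4, 3, 1, 1, seed = 2)
  expect_error(build_design(tab2, "y", fixed = "nonexistent"),
               "unknown fixed-effect")
  expect_warning(build_design(tab2, "y", fixed = "hatch_loc"),
                 "single level")
})
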