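test_that("purebred heritability follows the variance ratio", {
  h <- h2_purebred(107, 873)
  expect_equal(h$sigma2_P, 980)
  expect_equal(round(h$h2, 2), 0.11)
  h2 <- h2_purebred(325, 2400)
  expect_equal(h2$sigma2_P, 2725)
  expect_equal(round(h2$h2, 2), 0.12)
  expect_equal(h2_purebred(0, 1)$h2, 0)
  expect_error(h2_purebred(0, 0), "undefined")
})

test_that("pooled-record crossbred heritability rescales to individuals", {
  h <- h2_crossbred_pooled(22.75, 214, 6)
  expect_equal(h$sigma2_P_star, 1306.75)
  expect_equal(round(h$h2, 2), 0.07)
  h2 <- h2_crossbred_pooled(24, 293, 7)
  expect_equal(round(h2$h2, 2), 0.05)
  expect_equal(h2_crossbred_pooled(0, 5, 6)$h2, 0)
  # n = 1 collapses to the purebred formula (with the 4x sire scaling):
  # 4 s / (s + e) at s = a/4 equals a / (a/4 + e)
  a <- 12; e <- 30
  expect_equal(h2_crossbred_pooled(a / 4, e, 1)$h2,
               a / (a / 4 + e))
})

test_that("LNVAR crossbred heritability skips the cage-size rescaling", {
  expect_equal(round(h2_crossbred_lnvar(0.046 / 4, 0.343), 2), 0.13)
  expect_equal(round(h2_crossbred_lnvar(0.055 / 4, 0.242), 2), 0.22)
  expect_equal(h2_crossbred_lnvar(0, 2), 0)
  expect_error(h2_crossbred_lnvar(0, 0), "undefined")
})

test_that("rpc round-trips the generating correlation", {
  expect_equal(rpc(0, 10, 8), 0)
  s_ap <- sqrt(10); s_ac <- sqrt(8)
  expect_equal(rpc(0.5 * s_ap * s_ac, 10, 8), 1)
  set.seed(31)
  for (i in 1:20) {
    v1 <- runif(1, 0.5, 50); v2 <- runif(1, 0.5, 50)
    r <- runif(1, -1, 1)
    cov <- 0.5 * r * sqrt(v1) * sqrt(v2)
    expect_equal(rpc(cov, v1, v2), r, tolerance = 1e-12)
  }
  expect_error(rpc(1, 0, 5), "undefined")
})

test_that("pooled cage means recover the individual-scale heritability", {
  # individual crossbred phenotype: sire effect (var a/4) + independent
  # rest (var P - a/4); cage mean of n half-sibs; fitting the sire model
  # to cage means and applying the pooled formula must recover a / P
  set.seed(8)
  a <- 24; P <- 100; n <- 6
  h_ind <- a / P
  ests <- replicate(30, {
    ns <- 60; ncage <- 6
    s <- rnorm(ns, 0, sqrt(a / 4))
    cage_mean <- as.vector(vapply(seq_len(ns), function(i)
      s[i] + colMeans(matrix(rnorm(n * ncage, 0, sqrt(P - a / 4)), n)),
      numeric(ncage)))
    sire <- rep(sprintf("S%03d", seq_len(ns)), each = ncage)
    tab <- data.frame(unit_id = paste0("c", seq_along(cage_mean)),
                      y = cage_mean, sire = sire,
                      population = "crossbred", cage_size = n,
                      hatch_loc = "H1", maternal_line = "M1")
    f <- suppressWarnings(fit_sire(tab, NULL, fixed = character(0),
                                   options = list(se = FALSE)))
    h2_crossbred_pooled(f$estimates[["sigma2_g"]],
                        f$estimates[[paste0("sigma2_e_c", n)]], n)$h2
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - h_ind), 2 * mc_se + 0.005)
})

test_that("genetic_params extracts pc parameters with finite SEs", {
  des <- population_design(n_sires = 40, n_purebred_per_sire = 8,
                           n_crossbred_per_sire = 12, cage_sizes = 6,
                           seed = 71)
  pop <- simulate_pedigree(des)
  arch <- genetic_architecture(sigma2_ap = 8, sigma2_ac = 6, r_pc = 0.5,
                               sigma2_ep = 12, sigma2_ec = c("6" = 4),
                               mu_p = 0, mu_c = 0)
  tt <- simulate_trait_table(pop, arch, seed = 2)
  fit <- fit_purebred_crossbred("y", tt[tt$population == "purebred", ],
                                tt[tt$population == "crossbred", ],
                                pop$ped, fixed_p = character(0),
                                fixed_c = character(0))
  gp <- genetic_params(fit, "purebred_crossbred")
  expect_setequal(
    setdiff(c("sigma2_ap", "sigma2_ac", "h2_p", "h2_c6",
              "sigma2_P_star_c6", "r_pc"), gp$parameter), character(0))
  expect_true(all(is.finite(gp$estimate)))
  rpc_row <- gp[gp$parameter == "r_pc", ]
  expect_true(rpc_row$se > 0 && rpc_row$se < 1)
  h2p <- gp$estimate[gp$parameter == "h2_p"]
  expect_true(h2p >= 0 && h2p <= 1)
})
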