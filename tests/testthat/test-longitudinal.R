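quiet_pop <- function(n_sires = 10, n_pb = 6, n_cb = 0, seed = 1,
                      weeks = 25:83)
  simulate_pedigree(population_design(
    n_sires = n_sires, n_purebred_per_sire = n_pb,
    n_crossbred_per_sire = n_cb, cage_sizes = 6, n_batches = 2,
    n_hatch_locations = 2, n_maternal_lines = 2, weeks = weeks,
    seed = seed))

test_that("longitudinal simulation is deterministic and conserves eggs", {
  pop <- quiet_pop(3, 4, 12, seed = 2, weeks = 25:40)
  arch <- genetic_architecture()
  s1 <- simulate_longitudinal(pop, arch, seed = 5)
  s2 <- simulate_longitudinal(pop, arch, seed = 5)
  expect_identical(s1$records, s2$records)
  expect_true(all(s1$records$eggs >= 0))
  # cage records cover all cages; hen records all purebred hens
  expect_setequal(unique(s1$records$unit_id),
                  c(pop$purebred$unit_id, pop$cages$unit_id))
})

test_that("undisturbed iid series concentrate LNVAR near mu_v", {
  # no perturbations, no genetic/permanent variance in v, rho = 0,
  # no hen mean-level variance, curve low enough to avoid clamping
  par <- longitudinal_params(sd_a_m = 0, mu_v = -1, sd_a_v = 0,
                             sd_env_v = 0, mu_rho_link = 0, sd_a_rho = 0,
                             perturb_rate = 0, weekly_mortality = 0,
                             peak_rate = 4.5, sd_batch = 0)
  arch <- genetic_architecture(longitudinal = par)
  pop <- quiet_pop(10, 8, 0, seed = 3)
  sim <- simulate_longitudinal(pop, arch, seed = 11)
  tab <- construct_traits(sim$records, sim$metadata,
                          population = "purebred")
  expect_gt(sum(!is.na(tab$LNVAR)), 70)
  # closed form: iid N(0, exp(mu_v)) deviations -> LNVAR ~ mu_v
  expect_lt(abs(mean(tab$LNVAR, na.rm = TRUE) - (-1)), 0.12)
  # rho = 0: mean AUTO-R sits at the -1/T small-sample bias
  T <- length(25:83)
  se <- sd(tab$AUTO_R, na.rm = TRUE) / sqrt(sum(!is.na(tab$AUTO_R)))
  expect_lt(abs(mean(tab$AUTO_R, na.rm = TRUE) - (-1 / T)),
            3 * se + 0.02)
})

test_that("corrupt records exercise the three-egg discard filter", {
  pop <- quiet_pop(4, 6, 0, seed = 4, weeks = 25:40)
  arch0 <- genetic_architecture(
    longitudinal = longitudinal_params(corrupt_fraction = 0,
                                       weekly_mortality = 0))
  sim0 <- simulate_longitudinal(pop, arch0, seed = 6)
  start <- setNames(as.Date(sim0$metadata$hatch_date) + 24 * 7 - 1,
                    sim0$metadata$unit_id)
  d0 <- daily_from_collections(sim0$records, start = start)
  expect_null(attr(d0, "discarded"))
  arch1 <- genetic_architecture(
    longitudinal = longitudinal_params(corrupt_fraction = 0.05,
                                       weekly_mortality = 0))
  sim1 <- simulate_longitudinal(pop, arch1, seed = 6)
  d1 <- daily_from_collections(sim1$records, start = start)
  expect_gt(nrow(attr(d1, "discarded")), 0)
})

test_that("genetic variance in log innovation variance propagates to LNVAR", {
  # between-sire variance of offspring-mean LNVAR rises with sd_a_v
  grid <- c(0, 0.4, 0.8)
  between <- vapply(grid, function(sv) {
    par <- longitudinal_params(sd_a_m = 0, sd_a_v = sv, sd_env_v = 0.1,
                               perturb_rate = 0, weekly_mortality = 0,
                               peak_rate = 4.5)
    arch <- genetic_architecture(longitudinal = par)
    pop <- quiet_pop(12, 8, 0, seed = 9)
    sim <- simulate_longitudinal(pop, arch, seed = 13)
    tab <- construct_traits(sim$records, sim$metadata,
                            population = "purebred")
    sire <- pop$purebred$sire[match(tab$unit_id, pop$purebred$unit_id)]
    var(tapply(tab$LNVAR, sire, mean, na.rm = TRUE))
  }, 0)
  expect_true(all(diff(between) > 0))
})

test_that("perturbations drag the skew negative", {
  pop <- quiet_pop(8, 8, 0, seed = 14)
  calm <- genetic_architecture(longitudinal = longitudinal_params(
    perturb_rate = 0, weekly_mortality = 0, peak_rate = 4.5))
  rough <- genetic_architecture(longitudinal = longitudinal_params(
    perturb_rate = 0.08, perturb_depth = 2.5, weekly_mortality = 0,
    peak_rate = 4.5))
  t_calm <- construct_traits(
    simulate_longitudinal(pop, calm, seed = 3)$records,
    simulate_longitudinal(pop, calm, seed = 3)$metadata,
    population = "purebred")
  sim_r <- simulate_longitudinal(pop, rough, seed = 3)
  t_rough <- construct_traits(sim_r$records, sim_r$metadata,
                              population = "purebred")
  expect_lt(mean(t_rough$SKEW, na.rm = TRUE),
            mean(t_calm$SKEW, na.rm = TRUE))
  expect_gt(mean(t_rough$LNVAR, na.rm = TRUE),
            mean(t_calm$LNVAR, na.rm = TRUE))
})

test_that("mortality truncates records and shrinks cage denominators", {
  pop <- quiet_pop(4, 5, 24, seed = 15, weeks = 25:50)
  arch <- genetic_architecture(longitudinal = longitudinal_params(
    weekly_mortality = 0.02))
  sim <- simulate_longitudinal(pop, arch, seed = 16)
  dead <- sim$truth[!is.na(sim$truth$death_week) &
                      sim$truth$unit_id == sim$truth$hen_id, ]
  if (nrow(dead)) {
    h <- dead[1, ]
    hd <- as.Date(sim$metadata$hatch_date[
      sim$metadata$unit_id == h$unit_id])
    rec <- sim$records[sim$records$unit_id == h$unit_id, ]
    wk <- as.integer(rec$date - hd) %/% 7 + 1
    expect_equal(sum(rec$eggs[wk > h$death_week]), 0)
  }
  expect_true(any(!is.na(sim$members$death_week)) ||
                all(is.na(sim$members$death_week)))
  # end-to-end crossbred construction with denominators runs
  tab_c <- construct_traits(
    sim$records[sim$records$unit_type == "cage", ],
    sim$metadata[sim$metadata$unit_type == "cage", ],
    members = sim$members, population = "crossbred")
  expect_true(all(tab_c$AUTO_R >= -1 & tab_c$AUTO_R <= 1, na.rm = TRUE))
  expect_true(all(is.finite(tab_c$EP)))
})

test_that("the pipeline runs end to end on the tiny fixture", {
  fx <- make_fixture("tiny", seed = 2)
  out <- withr::local_tempdir()
  cfg <- run_config(fx$pop$design, fx$arch, seed = 2, out_dir = out,
                    traits = "EP", pc_trait = "EP")
  # few deaths at tiny scale: the survival-class factor may collapse to
  # one level and is then dropped with a warning
  res <- suppressWarnings(run_pipeline(cfg))
  expect_true(file.exists(file.path(out, "trait_table.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(all(c("EP", "LNVAR", "SKEW", "AUTO_R") %in%
                    names(res$trait_table)))
  expect_true(all(is.finite(res$parameters$estimate)))
  expect_true(file.exists(file.path(out, "fit_pc.json")))
  # determinism of the simulated inputs
  fx2 <- make_fixture("tiny", seed = 2)
  s1 <- simulate_longitudinal(fx$pop, fx$arch, seed = 2)
  s2 <- simulate_longitudinal(fx2$pop, fx2$arch, seed = 2)
  expect_identical(s1$records, s2$records)
})
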