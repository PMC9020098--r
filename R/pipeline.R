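# Orchestration: simulate -> construct traits -> fit -> report, as one
# configurable, reproducible run.  The numbered scripts under analysis/
# are thin drivers over these functions.

#' Bundled simulation scales
#'
#' `tiny`: 5 sires, shortened recording window — deterministic smoke-test
#' fixture.  `demo`: 100 sires with 30 purebred offspring each plus
#' crossbred cages — the scale used for the parameter-recovery runs.
#'
#' @param scale `"tiny"` or `"demo"`.
#' @param seed RNG seed.
#' @return List with `pop` (a [layer_population]) and `arch` (a
#'   [genetic_architecture]).
#' @export
make_fixture <- function(scale = c("tiny", "demo"), seed = 1L) {
  scale <- match.arg(scale)
  design <- switch(scale,
    tiny = population_design(n_sires = 5, n_purebred_per_sire = 6,
                             n_crossbred_per_sire = 12, cage_sizes = 6,
                             n_batches = 2, n_hatch_locations = 2,
                             n_maternal_lines = 2, weeks = 25:44,
                             seed = seed),
    demo = population_design(n_sires = 100, n_purebred_per_sire = 30,
                             n_crossbred_per_sire = 60, cage_sizes = 6,
                             n_batches = 6, n_hatch_locations = 5,
                             n_maternal_lines = 5, weeks = 25:83,
                             seed = seed))
  list(pop = simulate_pedigree(design), arch = genetic_architecture())
}

#' Run configuration
#'
#' @param design a [population_design].
#' @param arch a [genetic_architecture].
#' @param seed run seed; all stage seeds are derived from it.
#' @param out_dir output directory.
#' @param traits traits to analyse univariately in the purebreds.
#' @param pc_trait trait for the bivariate purebred-crossbred fit (NULL to
#'   skip).
#' @param min_weeks,outlier_k trait-construction settings.
#' @return A list of class `run_config`.
#' @export
run_config <- function(design, arch = genetic_architecture(), seed = 1L,
                       out_dir = "results/run", traits = c("EP", "LNVAR"),
                       pc_trait = "EP", min_weeks = 10L, outlier_k = 4) {
  structure(list(design = design, arch = arch, seed = as.integer(seed),
                 out_dir = out_dir, traits = traits, pc_trait = pc_trait,
                 min_weeks = min_weeks, outlier_k = outlier_k),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulates a longitudinal dataset, constructs the trait table, fits the
#' univariate purebred animal models (full and without the genetic term,
#' for the heritability LRT) and optionally the bivariate
#' purebred-crossbred model, and writes the trait table, fit JSONs,
#' parameter tables, LRT annotations and a manifest (seeds, removal
#' fractions, convergence) under `out_dir`.
#'
#' @param config a [run_config].
#' @return Invisibly, a list with the trait tables, fits and parameter
#'   tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- simulate_pedigree(config$design)
  sim <- simulate_longitudinal(pop, config$arch, seed = config$seed)
  write_pedigree(pop$ped, file.path(config$out_dir, "pedigree.csv"))
  utils::write.csv(sim$records, file.path(config$out_dir, "records.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$metadata, file.path(config$out_dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)

  meta_p <- sim$metadata[sim$metadata$unit_type == "hen", ]
  meta_c <- sim$metadata[sim$metadata$unit_type == "cage", ]
  rec_p <- sim$records[sim$records$unit_type == "hen", ]
  rec_c <- sim$records[sim$records$unit_type == "cage", ]
  tab_p <- construct_traits(rec_p, meta_p, population = "purebred",
                            min_weeks = config$min_weeks,
                            k = config$outlier_k)
  tab_c <- if (nrow(rec_c))
    construct_traits(rec_c, meta_c, members = sim$members,
                     population = "crossbred",
                     min_weeks = config$min_weeks, k = config$outlier_k)
  tab <- rbind(tab_p, tab_c)
  utils::write.csv(tab, file.path(config$out_dir, "trait_table.csv"),
                   row.names = FALSE, quote = FALSE)

  fits <- list(); params <- list(); lrts <- list()
  for (tr in config$traits) {
    full <- fit_animal(tab_p, pop$ped, trait = tr,
                       fixed = c("hatch_loc", "surv_class"))
    null <- fit_constrained(full$model, "no_genetic")
    lt <- lr_test(full, null, boundary = TRUE)
    fits[[paste0("purebred_", tr)]] <- full
    lrts[[tr]] <- data.frame(trait = tr, model = "h2_purebred_vs_0",
                             lr = lt$lr, p = lt$p,
                             significant = lt$significant)
    h <- h2_purebred(full$estimates[["sigma2_g"]],
                     full$estimates[["sigma2_e_p"]])
    params[[tr]] <- data.frame(trait = tr, parameter = "h2_p",
                               estimate = h$h2,
                               se = delta_se(full, function(th)
                                 th[["sigma2_g"]] /
                                   (th[["sigma2_g"]] + th[["sigma2_e_p"]])))
    write_fit_json(full, file.path(config$out_dir,
                                   paste0("fit_purebred_", tr, ".json")))
  }
  if (!is.null(config$pc_trait) && !is.null(tab_c) && nrow(tab_c)) {
    pc <- fit_purebred_crossbred(config$pc_trait, tab_p, tab_c, pop$ped,
                                 fixed_p = c("hatch_loc", "surv_class"),
                                 fixed_c = c("hatch_loc", "surv_class",
                                             "maternal_line"))
    fits[["pc"]] <- pc
    gp <- genetic_params(pc, "purebred_crossbred",
                         lnvar_scale = config$pc_trait == "LNVAR")
    gp$trait <- config$pc_trait
    params[["pc"]] <- gp[, c("trait", "parameter", "estimate", "se")]
    write_fit_json(pc, file.path(config$out_dir, "fit_pc.json"))
  }
  param_tab <- do.call(rbind, params)
  lrt_tab <- do.call(rbind, lrts)
  utils::write.csv(param_tab, file.path(config$out_dir, "parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(lrt_tab, file.path(config$out_dir, "lrt.csv"),
                   row.names = FALSE)
  manifest <- list(seed = config$seed,
                   design = unclass(config$design)[c(
                     "n_sires", "n_purebred_per_sire",
                     "n_crossbred_per_sire", "cage_sizes", "n_batches")],
                   removed = as.list(attr(tab_p, "removed")),
                   converged = lapply(fits, function(f) f$converged),
                   n_units = nrow(tab))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(trait_table = tab, fits = fits, parameters = param_tab,
                 lrt = lrt_tab))
}
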