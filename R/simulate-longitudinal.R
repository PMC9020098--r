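# Full longitudinal simulation: batch lay curves, genetically structured
# hen-level mean, innovation variance and lag-one autocorrelation of the
# weekly deviations, perturbation events with individual recovery rates,
# mortality, and irregular egg-collection schedules.  This fidelity level
# exercises the whole trait-construction pipeline; its mapping from
# process parameters to indicator-trait heritabilities is nonlinear and is
# checked qualitatively only.

#' Process parameters of the longitudinal egg-production generator
#'
#' @param mu_m baseline of the hen-level mean deviation from the batch lay
#'   curve (eggs/week).
#' @param sd_a_m additive genetic SD of the hen mean level (eggs/week).
#' @param mu_v mean log innovation variance of the weekly AR(1) deviations.
#' @param sd_a_v additive genetic SD of the log innovation variance.
#' @param sd_env_v permanent environmental SD of the log innovation
#'   variance.
#' @param mu_rho_link baseline lag-one autocorrelation on the scaled-logit
#'   link `logit((rho + 1) / 2)`; 0.43 corresponds to `rho` of about 0.21.
#' @param sd_a_rho additive genetic SD on the link scale.
#' @param perturb_rate probability of a batch perturbation event per week.
#' @param perturb_depth mean initial depth of a perturbation (eggs/week);
#'   depths are exponentially distributed.
#' @param perturb_susceptibility probability that an individual hen is
#'   affected by a given event.  Deviations are taken from the batch
#'   average, so an event hitting every hen equally is absorbed by the
#'   contemporary-group mean; only heterogeneous exposure shows up in the
#'   indicator traits (and produces their negative skew).
#' @param recovery_rate median individual recovery rate (per week); the
#'   perturbation deficit decays as `exp(-recovery * weeks since event)`.
#' @param sd_recovery log-scale SD of the individual recovery rate.
#' @param weekly_mortality weekly death hazard per hen.
#' @param corrupt_fraction fraction of purebred collection records forced
#'   to imply three or more eggs per day, to exercise the discard filter.
#' @param peak_rate asymptote of the batch lay curve (eggs/hen/week).
#' @param sd_batch SD of the batch-level intercept around the lay curve.
#' @return A list of class `longitudinal_params`.
#' @export
longitudinal_params <- function(mu_m = 0, sd_a_m = 0.35,
                                mu_v = -1.0, sd_a_v = 0.22, sd_env_v = 0.60,
                                mu_rho_link = 0.43, sd_a_rho = 0.30,
                                perturb_rate = 0.03, perturb_depth = 1.5,
                                perturb_susceptibility = 0.5,
                                recovery_rate = 0.5, sd_recovery = 0.3,
                                weekly_mortality = 0.001,
                                corrupt_fraction = 0,
                                peak_rate = 6.3, sd_batch = 0.15) {
  structure(as.list(environment()), class = "longitudinal_params")
}

# Deterministic template lay curve: rapid rise to peak around 30 weeks,
# slow linear decline afterwards, clamped to [0, 7] eggs/week.
lay_curve <- function(weeks, peak = 6.3) {
  v <- peak * (1 - exp(-0.45 * (weeks - 19))) * (1 - 0.004 * pmax(weeks - 30, 0))
  pmin(pmax(v, 0), 7)
}

#' Simulate longitudinal egg-collection records
#'
#' Generates weekly egg production per hen as batch lay curve + hen mean
#' level + AR(1) deviations - perturbation deficits, clamped to `[0, 7]`
#' eggs/week, then disaggregates the daily production into egg-collection
#' records at irregular 1-4 day intervals (integer egg counts via
#' cumulative rounding, so totals are conserved).  Hen-level process
#' parameters carry additive genetic structure drawn down the pedigree:
#' the mean level directly, the innovation variance on the log scale and
#' the autocorrelation on a scaled-logit link.  Perturbation events are
#' batch-wide with exponentially distributed depths; each hen recovers at
#' an individual lognormal rate, which induces negative skew.  Mortality
#' draws a death week per hen; records cease at death and cage
#' denominators decrease.
#'
#' @param pop a [layer_population] from [simulate_pedigree()].
#' @param arch a [genetic_architecture]; its `longitudinal` element holds
#'   the process parameters.
#' @param seed RNG seed.
#' @return A list of class `longitudinal_sim`:
#'   \describe{
#'     \item{records}{data frame `unit_id`, `date`, `eggs`, `unit_type`}
#'     \item{metadata}{per unit: `unit_id`, `unit_type`, `batch`,
#'       `hatch_loc`, `cage_size`, `maternal_line`, `death_week`,
#'       `hatch_date`, `sire`}
#'     \item{members}{crossbred hen to cage mapping with `death_week`}
#'     \item{batches}{batch registry: per batch-week lay-curve values}
#'     \item{events}{perturbation events: `batch`, `week`, `severity`}
#'     \item{truth}{hen-level true process parameters}
#'   }
#' @export
simulate_longitudinal <- function(pop, arch, seed = 1L) {
  stopifnot(inherits(pop, "layer_population"),
            inherits(arch, "genetic_architecture"))
  par <- arch$longitudinal
  stopifnot(inherits(par, "longitudinal_params"))
  design <- pop$design
  weeks <- design$weeks
  nw <- length(weeks)
  set.seed(stage_seed(seed, "longitudinal"))

  hens <- rbind(
    data.frame(hen_id = pop$purebred$unit_id, unit_id = pop$purebred$unit_id,
               unit_type = "hen", batch = pop$purebred$batch,
               stringsAsFactors = FALSE),
    if (nrow(pop$cage_members)) {
      cage_batch <- stats::setNames(pop$cages$batch, pop$cages$unit_id)
      data.frame(hen_id = pop$cage_members$hen_id,
                 unit_id = pop$cage_members$unit_id,
                 unit_type = "cage",
                 batch = unname(cage_batch[pop$cage_members$unit_id]),
                 stringsAsFactors = FALSE)
    })
  n <- nrow(hens)

  # genetically structured hen-level process parameters
  G0 <- diag(c(par$sd_a_m, par$sd_a_v, par$sd_a_rho)^2)
  bv <- draw_breeding_values(pop$ped, G0)[hens$hen_id, , drop = FALSE]
  m_i   <- par$mu_m + bv[, 1]
  v_i   <- exp(par$mu_v + bv[, 2] + stats::rnorm(n, 0, par$sd_env_v))
  rho_i <- 2 * stats::plogis(par$mu_rho_link + bv[, 3]) - 1
  rec_i <- exp(log(par$recovery_rate) + stats::rnorm(n, 0, par$sd_recovery))

  batches <- sort(unique(hens$batch))
  hatch_dates <- stats::setNames(
    as.Date("2015-01-05") + 28 * (seq_along(batches) - 1), batches)
  curve <- sapply(batches, function(b)
    pmin(pmax(lay_curve(weeks, par$peak_rate) +
                stats::rnorm(1, 0, par$sd_batch), 0), 7))
  dimnames(curve) <- list(NULL, batches)

  # batch-wide perturbation events
  ev <- do.call(rbind, lapply(batches, function(b) {
    hit <- which(stats::runif(nw) < par$perturb_rate)
    if (!length(hit)) return(NULL)
    data.frame(batch = b, week = weeks[hit],
               severity = stats::rexp(length(hit), 1 / par$perturb_depth),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev))
    ev <- data.frame(batch = character(0), week = integer(0),
                     severity = numeric(0))

  # AR(1) deviations, stationary start
  d <- matrix(0, n, nw)
  sd_in <- sqrt(v_i)
  d[, 1] <- stats::rnorm(n, 0, sd_in / sqrt(pmax(1 - rho_i^2, 1e-8)))
  for (t in 2:nw)
    d[, t] <- rho_i * d[, t - 1] + stats::rnorm(n, 0, sd_in)

  # perturbation deficit per hen-week; each event hits a susceptible
  # subset of the batch (exposure shared by a whole cage)
  deficit <- matrix(0, n, nw)
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      in_b <- which(hens$batch == ev$batch[k])
      lag <- weeks - ev$week[k]
      act <- lag >= 0
      if (!any(act) || !length(in_b)) next
      unit_b <- unique(hens$unit_id[in_b])
      hit_unit <- unit_b[stats::runif(length(unit_b)) <
                           par$perturb_susceptibility]
      hit <- in_b[hens$unit_id[in_b] %in% hit_unit]
      if (!length(hit)) next
      deficit[hit, act] <- deficit[hit, act] +
        ev$severity[k] * exp(-outer(rec_i[hit], lag[act]))
    }
  }

  eggs_wk <- curve[, hens$batch, drop = FALSE]
  eggs_wk <- t(eggs_wk) + m_i + d - deficit
  eggs_wk <- pmin(pmax(eggs_wk, 0), 7)

  # mortality: death at the start of death_week, no eggs from then on
  death_week <- rep(NA_integer_, n)
  if (par$weekly_mortality > 0) {
    dw_idx <- stats::rgeom(n, par$weekly_mortality) + 1L
    death_week <- ifelse(dw_idx <= nw, weeks[pmin(dw_idx, nw)], NA_integer_)
  }
  for (i in which(!is.na(death_week)))
    eggs_wk[i, weeks >= death_week[i]] <- 0

  # daily production and collection schedule (per batch, ends at the last
  # day of the final recorded week)
  day0 <- (min(weeks) - 1L) * 7L       # housing start, age in days
  day1 <- max(weeks) * 7L - 1L
  days <- day0:day1
  daily <- eggs_wk[, rep(seq_len(nw), each = 7), drop = FALSE] / 7
  sched <- lapply(batches, function(b) {
    g <- cumsum(sample(1:4, length(days), replace = TRUE))
    g <- g[g <= length(days)]
    if (!length(g) || g[length(g)] < length(days)) g <- c(g, length(days))
    g                                   # indices into `days`
  })
  names(sched) <- batches

  unit_rows <- function(unit_id, unit_type, batch, daily_u) {
    cut <- sched[[batch]]
    cum <- round(cumsum(daily_u) + 1e-9)
    eggs <- diff(c(0, cum[cut]))
    data.frame(unit_id = unit_id,
               date = hatch_dates[batch] + days[cut],
               eggs = as.integer(eggs), unit_type = unit_type,
               stringsAsFactors = FALSE)
  }
  rec_list <- vector("list", 0)
  pb_idx <- which(hens$unit_type == "hen")
  for (i in pb_idx)
    rec_list[[length(rec_list) + 1L]] <-
      unit_rows(hens$unit_id[i], "hen", hens$batch[i], daily[i, ])
  if (nrow(pop$cages)) {
    for (ci in seq_len(nrow(pop$cages))) {
      cid <- pop$cages$unit_id[ci]
      mem <- which(hens$unit_id == cid)
      rec_list[[length(rec_list) + 1L]] <-
        unit_rows(cid, "cage", hens$batch[mem[1]],
                  colSums(daily[mem, , drop = FALSE]))
    }
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL

  # inject corrupt purebred records (>= 3 eggs/day) to exercise the filter
  if (par$corrupt_fraction > 0) {
    is_hen <- which(records$unit_type == "hen")
    n_bad <- round(par$corrupt_fraction * length(is_hen))
    if (n_bad > 0) {
      bad <- sample(is_hen, n_bad)
      # interval length implied by the previous record of the same unit
      records$eggs[bad] <- records$eggs[bad] + 12L  # >= 3/day for gaps <= 4
    }
  }

  cage_batch <- stats::setNames(pop$cages$batch, pop$cages$unit_id)
  metadata <- rbind(
    data.frame(unit_id = pop$purebred$unit_id, unit_type = "hen",
               batch = pop$purebred$batch, hatch_loc = pop$purebred$hatch_loc,
               cage_size = NA_integer_, maternal_line = NA_character_,
               death_week = death_week[match(pop$purebred$unit_id, hens$hen_id)],
               hatch_date = hatch_dates[pop$purebred$batch],
               sire = pop$purebred$sire, stringsAsFactors = FALSE),
    if (nrow(pop$cages))
      data.frame(unit_id = pop$cages$unit_id, unit_type = "cage",
                 batch = pop$cages$batch, hatch_loc = pop$cages$hatch_loc,
                 cage_size = pop$cages$cage_size,
                 maternal_line = pop$cages$maternal_line,
                 death_week = NA_integer_,
                 hatch_date = hatch_dates[pop$cages$batch],
                 sire = pop$cages$sire, stringsAsFactors = FALSE))
  rownames(metadata) <- NULL
  members <- pop$cage_members
  if (nrow(members))
    members$death_week <- death_week[match(members$hen_id, hens$hen_id)]

  truth <- data.frame(hen_id = hens$hen_id, unit_id = hens$unit_id,
                      m = m_i, v = v_i, rho = rho_i, recovery = rec_i,
                      death_week = death_week, stringsAsFactors = FALSE)
  batch_table <- data.frame(batch = rep(batches, each = nw),
                            week = rep(weeks, length(batches)),
                            lay_curve = as.vector(curve),
                            stringsAsFactors = FALSE)
  structure(list(records = records, metadata = metadata, members = members,
                 batches = batch_table, events = ev, truth = truth),
            class = "longitudinal_sim")
}
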