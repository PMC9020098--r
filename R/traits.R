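# Trait construction: raw egg-collection records -> daily -> weekly
# production -> deviations from the batch average -> EP, LNVAR, SKEW,
# AUTO-R with the published filtering rules.

#' Spread egg-collection records into daily production
#'
#' Each day in the half-open interval (previous collection date, collection
#' date] receives `egg_count / interval_days`.  For individually recorded
#' purebred hens, any collection implying three or more eggs on a single
#' day (`egg_count / interval_days >= 3`) is biologically impossible and is
#' discarded before spreading; two-egg days are retained (the first egg may
#' have been laid after collection time the day before).  The first record
#' of a unit spreads backward to the housing start when one is supplied,
#' otherwise it covers its own date only.
#'
#' @param records data frame `unit_id`, `date` (Date or ISO-8601 string),
#'   `eggs`, `unit_type` (`"hen"` or `"cage"`).
#' @param start optional named vector (by unit id) or single Date: the
#'   housing start; the first interval is `(start, first date]`.
#' @return Data frame `unit_id`, `date`, `eggs` (per day), `unit_type`,
#'   with one row per covered day.  Attribute `"discarded"` holds the
#'   offending raw records.
#' @export
daily_from_collections <- function(records, start = NULL) {
  records$date <- as.Date(records$date)
  if (any(records$eggs < 0)) stop("negative egg counts")
  out <- vector("list", 0)
  disc <- vector("list", 0)
  for (uid in unique(records$unit_id)) {
    r <- records[records$unit_id == uid, ]
    if (is.unsorted(r$date, strictly = TRUE)) stop("unordered or duplicated dates for unit ", uid)
    s <- if (is.null(start)) r$date[1] - 1L
         else if (length(start) == 1L && is.null(names(start))) as.Date(start)
         else as.Date(start[[uid]])
    prev <- c(s, r$date[-nrow(r)])
    ndays <- as.integer(r$date - prev)
    if (any(ndays < 1)) stop("collection before housing start for unit ", uid)
    rate <- r$eggs / ndays
    bad <- r$unit_type == "hen" & rate >= 3
    if (any(bad)) disc[[length(disc) + 1L]] <- r[bad, ]
    keep <- which(!bad)
    if (!length(keep)) next
    day <- as.Date(unlist(lapply(keep, function(k)
      seq(prev[k] + 1L, r$date[k], by = "day"))), origin = "1970-01-01")
    out[[length(out) + 1L]] <- data.frame(
      unit_id = uid, date = day,
      eggs = rep(rate[keep], ndays[keep]),
      unit_type = r$unit_type[1], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(unit_id = character(0), date = as.Date(character(0)),
               eggs = numeric(0), unit_type = character(0))
  rownames(res) <- NULL
  attr(res, "discarded") <- if (length(disc)) do.call(rbind, disc) else NULL
  res
}

#' Weekly egg production per unit on the age scale
#'
#' Sums the spread daily values over the 7 days of each age week
#' (`week = floor(age_days / 7) + 1` relative to the hatch date).  Weeks
#' whose covered-day fraction falls below `completeness` are dropped
#' (default: only fully covered weeks are emitted).  For cage units the
#' weekly cage total is divided by the average number of hens alive in the
#' cage that week, giving eggs per hen per week.
#'
#' @param daily output of [daily_from_collections()].
#' @param metadata per-unit table with `unit_id` and `hatch_date`.
#' @param alive optional data frame `unit_id`, `week`, `n_alive` giving
#'   cage denominators (see [alive_counts()]); hens default to 1.
#' @param completeness minimum fraction of the 7 days that must be covered.
#' @return Data frame `unit_id`, `week`, `weekly_eggs` (per hen).
#' @export
weekly_production <- function(daily, metadata, alive = NULL,
                              completeness = 1.0) {
  hatch <- as.Date(metadata$hatch_date)[match(daily$unit_id, metadata$unit_id)]
  if (anyNA(hatch)) stop("hatch date missing for some units")
  week <- as.integer(as.integer(daily$date - hatch) %/% 7L) + 1L
  key <- paste(daily$unit_id, week, sep = "\r")
  tot <- tapply(daily$eggs, key, sum)
  cov <- tapply(daily$eggs, key, length)
  parts <- strsplit(names(tot), "\r", fixed = TRUE)
  out <- data.frame(unit_id = vapply(parts, `[`, "", 1L),
                    week = as.integer(vapply(parts, `[`, "", 2L)),
                    weekly_eggs = as.numeric(tot),
                    stringsAsFactors = FALSE)
  out <- out[cov >= 7 * completeness, ]
  if (!is.null(alive)) {
    idx <- match(paste(out$unit_id, out$week), paste(alive$unit_id, alive$week))
    n_alive <- ifelse(is.na(idx), 1, alive$n_alive[idx])
    out <- out[n_alive > 0, ]
    n_alive <- n_alive[n_alive > 0]
    out$weekly_eggs <- out$weekly_eggs / n_alive
  }
  out <- out[order(out$unit_id, out$week), ]
  rownames(out) <- NULL
  out
}

#' Hens alive per cage-week
#'
#' A hen is alive in week `w` when its `death_week` is missing or greater
#' than `w` (death occurs at the start of `death_week`).
#'
#' @param members data frame `hen_id`, `unit_id`, `death_week`.
#' @param weeks integer vector of age weeks.
#' @return Data frame `unit_id`, `week`, `n_alive`.
#' @export
alive_counts <- function(members, weeks) {
  out <- expand.grid(unit_id = unique(members$unit_id), week = weeks,
                     stringsAsFactors = FALSE)
  out$n_alive <- mapply(function(u, w) {
    dw <- members$death_week[members$unit_id == u]
    sum(is.na(dw) | dw > w)
  }, out$unit_id, out$week)
  out[order(out$unit_id, out$week), ]
}

#' Batch averages and weekly deviations
#'
#' The average weekly egg number of a batch is the total number of eggs
#' laid that week divided by the number of hens alive (at week start);
#' cages contribute hen-weighted.  Deviations are each unit's per-hen
#' weekly production minus its batch average.
#'
#' @param weekly output of [weekly_production()] (per-hen values).
#' @param metadata per-unit table with `unit_id`, `batch`, `death_week`,
#'   and `cage_size` (NA for individually housed hens).
#' @param alive optional `unit_id`, `week`, `n_alive` for cage units.
#' @return List with `averages` (`batch`, `week`, `avg`) and `deviations`
#'   (`unit_id`, `week`, `weekly_eggs`, `deviation`, `batch`, `n_alive`).
#' @export
batch_deviations <- function(weekly, metadata, alive = NULL) {
  m <- match(weekly$unit_id, metadata$unit_id)
  if (anyNA(m)) stop("units without batch metadata")
  batch <- metadata$batch[m]
  dw <- metadata$death_week[m]
  is_cage <- !is.na(metadata$cage_size[m])
  n_alive <- rep(1, nrow(weekly))
  if (!is.null(alive)) {
    idx <- match(paste(weekly$unit_id, weekly$week),
                 paste(alive$unit_id, alive$week))
    n_alive[!is.na(idx)] <- alive$n_alive[idx[!is.na(idx)]]
  }
  # individually housed hens drop out of the denominator once dead
  n_alive[!is_cage & !is.na(dw) & dw <= weekly$week] <- 0
  keep <- n_alive > 0
  w <- weekly[keep, ]
  batch <- batch[keep]; n_alive <- n_alive[keep]
  key <- paste(batch, w$week, sep = "\r")
  tot  <- tapply(w$weekly_eggs * n_alive, key, sum)
  hens <- tapply(n_alive, key, sum)
  avg <- as.numeric(tot) / as.numeric(hens)
  parts <- strsplit(names(tot), "\r", fixed = TRUE)
  averages <- data.frame(batch = vapply(parts, `[`, "", 1L),
                         week = as.integer(vapply(parts, `[`, "", 2L)),
                         avg = avg, stringsAsFactors = FALSE)
  w$batch <- batch
  w$n_alive <- n_alive
  w$deviation <- w$weekly_eggs -
    averages$avg[match(key, paste(averages$batch, averages$week, sep = "\r"))]
  rownames(w) <- NULL
  list(averages = averages, deviations = w)
}

#' Total egg production between 25 and 83 weeks of age
#'
#' `EP = sum of the weekly per-hen values for weeks 25 to 83` (59 weeks);
#' missing weeks contribute zero, so death truncates the sum (the survival
#' class fixed effect later absorbs this).
#'
#' @param weekly data frame `unit_id`, `week`, `weekly_eggs` for one or
#'   more units.
#' @param week_range inclusive age-week range.
#' @return Named numeric vector of EP per unit.
#' @export
egg_production_total <- function(weekly, week_range = c(25L, 83L)) {
  keep <- weekly$week >= week_range[1] & weekly$week <= week_range[2]
  w <- weekly[keep, ]
  ep <- tapply(w$weekly_eggs, w$unit_id, sum)
  all_units <- unique(weekly$unit_id)
  out <- stats::setNames(numeric(length(all_units)), all_units)
  out[names(ep)] <- as.numeric(ep)
  out
}

#' Resilience indicators of a deviation series
#'
#' `lnvar()` is the natural log of the (n-1 denominator) sample variance of
#' the weekly deviations.  `skew()` is the moment skewness
#' `m3 / s^3` with `m3` the third central moment (1/n) and `s` the n-1
#' sample SD — the default (type 3) estimator of the e1071 `skewness()`
#' function, through which it is computed.  `autor()` is the lag-one
#' autocorrelation in the `acf()` convention: overall mean, denominator
#' over all T terms; only consecutive-week pairs enter the numerator, so
#' gaps in the series break pairs.
#'
#' All three return `NA` when fewer than `min_weeks` deviations are
#' available or when the series has zero variance.
#'
#' @param deviations numeric vector of weekly deviations.
#' @param weeks optional integer week indices (for gap detection in
#'   `autor()`); consecutive weeks assumed if omitted.
#' @param min_weeks minimum number of deviations required.
#' @return A single numeric value or `NA`.
#' @export
lnvar <- function(deviations, min_weeks = 10L) {
  d <- deviations[!is.na(deviations)]
  if (length(d) < max(min_weeks, 2L)) return(NA_real_)
  v <- stats::var(d)
  if (v <= 0) return(NA_real_)
  log(v)
}

#' @rdname lnvar
#' @export
skew <- function(deviations, min_weeks = 10L) {
  d <- deviations[!is.na(deviations)]
  if (length(d) < max(min_weeks, 2L)) return(NA_real_)
  if (stats::var(d) <= 0) return(NA_real_)
  e1071::skewness(d, type = 3)
}

#' @rdname lnvar
#' @export
autor <- function(deviations, weeks = NULL, min_weeks = 10L) {
  ok <- !is.na(deviations)
  d <- deviations[ok]
  n <- length(d)
  if (n < max(min_weeks, 2L)) return(NA_real_)
  dc <- d - mean(d)
  den <- sum(dc^2)
  if (den <= 0) return(NA_real_)
  if (is.null(weeks)) {
    num <- sum(dc[-n] * dc[-1])
  } else {
    w <- weeks[ok]
    consec <- which(diff(w) == 1L)
    if (!length(consec)) return(NA_real_)
    num <- sum(dc[consec] * dc[consec + 1L])
  }
  num / den
}

#' Build the trait table from deviation series
#'
#' One row per purebred hen or crossbred cage with EP, LNVAR, SKEW and
#' AUTO-R plus the model covariates.  The survival class bins lifespan into
#' 4-week classes (see [surv_class()]); units that survive to the end of
#' recording fall in the last observed class.
#'
#' @param deviations the `deviations` element of [batch_deviations()].
#' @param metadata per-unit metadata (with `batch`, `hatch_loc`,
#'   `cage_size`, `maternal_line`, `death_week`, `sire`).
#' @param population label for the population (line x purebred/crossbred).
#' @param min_weeks minimum deviations for the indicator traits.
#' @param week_range EP summation range.
#' @return Data frame `unit_id`, `population`, `EP`, `LNVAR`, `SKEW`,
#'   `AUTO_R`, `hatch_loc`, `surv_class`, `maternal_line`, `cage_size`,
#'   `sire`, `batch`.
#' @export
build_trait_table <- function(deviations, metadata, population = "purebred",
                              min_weeks = 10L, week_range = c(25L, 83L)) {
  sp <- split(deviations, deviations$unit_id)
  ep <- egg_production_total(deviations, week_range)
  rows <- lapply(names(sp), function(uid) {
    s <- sp[[uid]]
    s <- s[order(s$week), ]
    data.frame(unit_id = uid,
               EP = unname(ep[uid]),
               LNVAR = lnvar(s$deviation, min_weeks),
               SKEW = skew(s$deviation, min_weeks),
               AUTO_R = autor(s$deviation, s$week, min_weeks),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- match(out$unit_id, metadata$unit_id)
  out$population <- population
  out$hatch_loc <- metadata$hatch_loc[m]
  end_week <- max(week_range)
  lifespan <- ifelse(is.na(metadata$death_week[m]), end_week,
                     metadata$death_week[m])
  out$surv_class <- surv_class(lifespan)
  out$maternal_line <- metadata$maternal_line[m]
  out$cage_size <- metadata$cage_size[m]
  out$sire <- metadata$sire[m]
  out$batch <- metadata$batch[m]
  rownames(out) <- NULL
  out
}

#' Survival class from lifespan
#'
#' Lifespan duration binned into intervals of four weeks spanning 24 to
#' 112 weeks of age (22 classes), used as a fixed effect so that the
#' effect of survival on the phenotypes is accounted for without assuming
#' linearity.
#'
#' @param lifespan_weeks lifespan (or age at end of recording) in weeks.
#' @return Character vector of class labels.
#' @export
surv_class <- function(lifespan_weeks) {
  w <- pmin(pmax(lifespan_weeks, 24), 112)
  bin <- pmin((w - 24) %/% 4, 21)
  sprintf("SC%02d", bin + 1)
}

#' Discard outlying resilience-indicator observations
#'
#' Within each population, observations of LNVAR, SKEW or AUTO-R outside
#' the population mean plus or minus `k` standard deviations are set to
#' missing.  Only the offending indicator is discarded: the unit's other
#' indicators and its EP are kept.  Mean and SD are computed once from the
#' pre-filter values (single pass).
#'
#' @param trait_table output of [build_trait_table()].
#' @param k number of SDs (default 4).
#' @param traits columns to filter.
#' @return The filtered table; attribute `"removed"` holds the per
#'   population x trait removal fractions.
#' @export
filter_outliers <- function(trait_table, k = 4,
                            traits = c("LNVAR", "SKEW", "AUTO_R")) {
  removed <- list()
  for (popn in unique(trait_table$population)) {
    in_pop <- trait_table$population == popn
    for (tr in traits) {
      x <- trait_table[[tr]][in_pop]
      mu <- mean(x, na.rm = TRUE)
      sdev <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(sdev) || sdev == 0) {
        removed[[paste(popn, tr)]] <- 0
        next
      }
      out <- !is.na(x) & abs(x - mu) > k * sdev
      x[out] <- NA
      trait_table[[tr]][in_pop] <- x
      removed[[paste(popn, tr)]] <- mean(out)
    }
  }
  attr(trait_table, "removed") <- unlist(removed)
  trait_table
}

#' Construct the trait table from raw records in one call
#'
#' Convenience wrapper chaining [daily_from_collections()],
#' [weekly_production()], [batch_deviations()], [build_trait_table()] and
#' [filter_outliers()] for one population.
#'
#' @param records raw collection records.
#' @param metadata unit metadata (see [simulate_longitudinal()]).
#' @param members cage membership with death weeks (crossbreds), or NULL.
#' @param population population label.
#' @param min_weeks,completeness,k tuning parameters, see the step
#'   functions.
#' @return Filtered trait table.
#' @export
construct_traits <- function(records, metadata, members = NULL,
                             population = "purebred", min_weeks = 10L,
                             completeness = 1.0, k = 4) {
  start <- stats::setNames(as.Date(metadata$hatch_date) +
                             (25L - 1L) * 7L - 1L, metadata$unit_id)
  daily <- daily_from_collections(records, start = start)
  alive <- NULL
  if (!is.null(members) && nrow(members)) {
    age_days <- as.integer(as.Date(records$date) -
      as.Date(metadata$hatch_date)[match(records$unit_id, metadata$unit_id)])
    wk_range <- range(age_days %/% 7L + 1L)
    alive <- alive_counts(members, seq(wk_range[1], wk_range[2]))
  }
  weekly <- weekly_production(daily, metadata, alive, completeness)
  dev <- batch_deviations(weekly, metadata, alive)
  tab <- build_trait_table(dev$deviations, metadata, population, min_weeks)
  filter_outliers(tab, k)
}
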