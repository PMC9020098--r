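mkrec <- function(unit_id, dates, eggs, type = "hen")
  data.frame(unit_id = unit_id, date = as.Date(dates), eggs = eggs,
             unit_type = type, stringsAsFactors = FALSE)

test_that("collections spread evenly across the interval days", {
  r <- mkrec("h1", c("2020-01-03", "2020-01-06"), c(2, 6))
  d <- daily_from_collections(r, start = as.Date("2020-01-01"))
  expect_equal(nrow(d), 5)
  expect_equal(d$eggs, c(1, 1, 2, 2, 2))  # 2 over 2 days, then 6 over 3
  expect_equal(sum(d$eggs), 8)            # totals conserved
})

test_that("three-or-more eggs per day are discarded for hens only", {
  r <- mkrec("h1", c("2020-01-02", "2020-01-03", "2020-01-04"), c(1, 3, 2))
  d <- daily_from_collections(r, start = as.Date("2020-01-01"))
  expect_equal(d$eggs, c(1, 2))           # the 3-egg day removed, 2 kept
  expect_equal(attr(d, "discarded")$eggs, 3)
  # cage records can exceed 3/day (several hens)
  rc <- mkrec("c1", c("2020-01-02"), 5, type = "cage")
  dc <- daily_from_collections(rc, start = as.Date("2020-01-01"))
  expect_equal(dc$eggs, 5)
  # spread rate >= 3 also removed: 12 eggs over 4 days = 3/day
  r2 <- mkrec("h1", "2020-01-05", 12)
  d2 <- daily_from_collections(r2, start = as.Date("2020-01-01"))
  expect_equal(nrow(d2), 0)
  expect_error(daily_from_collections(
    mkrec("h1", c("2020-01-05", "2020-01-02"), c(1, 1))), "unordered")
  expect_error(daily_from_collections(mkrec("h1", "2020-01-02", -1)),
               "negative")
})

test_that("weekly production sums 7 days on the age scale", {
  hatch <- as.Date("2020-01-01")
  meta <- data.frame(unit_id = "h1", hatch_date = hatch)
  # constant 1 egg/day across age weeks 2 and 3, partial week 4
  d <- data.frame(unit_id = "h1", date = hatch + 7:24, eggs = 1,
                  unit_type = "hen")
  w <- weekly_production(d, meta)
  expect_equal(w$weekly_eggs[w$week %in% c(2, 3)], c(7, 7))
  expect_false(4 %in% w$week)   # only 4 covered days at completeness 1
  w2 <- weekly_production(d, meta, completeness = 0.5)
  expect_true(4 %in% w2$week)
  # cage series: per-hen value = cage total / average hens alive
  dc <- data.frame(unit_id = "c1", date = hatch + 7:13, eggs = 12,
                   unit_type = "cage")
  metac <- data.frame(unit_id = "c1", hatch_date = hatch)
  alive <- data.frame(unit_id = "c1", week = 2, n_alive = 6)
  wc <- weekly_production(dc, metac, alive)
  expect_equal(wc$weekly_eggs, 12 * 7 / 6)
})

test_that("EP accumulates weekly values over weeks 25-83", {
  w <- data.frame(unit_id = "h1", week = 25:83, weekly_eggs = 7)
  expect_equal(unname(egg_production_total(w)), 413)  # 59 x 7
  w2 <- data.frame(unit_id = "h1", week = 25:49, weekly_eggs = 6)
  expect_equal(unname(egg_production_total(w2)), 150) # death truncates
  w3 <- data.frame(unit_id = "h1", week = 5:10, weekly_eggs = 3)
  expect_equal(unname(egg_production_total(w3)), 0)   # outside the range
})

test_that("batch averages use hens alive and deviations centre to zero", {
  meta <- data.frame(unit_id = c("h1", "h2"), batch = "B1",
                     death_week = c(NA, 30), cage_size = NA_integer_)
  w <- data.frame(unit_id = rep(c("h1", "h2"), each = 2),
                  week = rep(c(28, 31), 2), weekly_eggs = c(6, 6, 8, 8))
  bd <- batch_deviations(w, meta)
  expect_equal(bd$averages$avg[bd$averages$week == 28], 7)   # (6+8)/2
  expect_equal(bd$averages$avg[bd$averages$week == 31], 6)   # survivor only
  # hen-weighted deviations sum to zero within each batch-week
  sums <- tapply(bd$deviations$deviation * bd$deviations$n_alive,
                 bd$deviations$week, sum)
  expect_equal(unname(as.numeric(sums)), rep(0, 2), tolerance = 1e-12)
})

test_that("lnvar matches hand-computed n-1 variances", {
  expect_equal(lnvar(c(1, -1), min_weeks = 2), log(2))
  expect_equal(lnvar(c(2, -1, -1, 0), min_weeks = 2), log(2))
  expect_true(is.na(lnvar(rep(3, 20))))          # zero variance
  expect_true(is.na(lnvar(rnorm(5), min_weeks = 10)))  # too short
})

test_that("skew matches the moment oracle", {
  expect_equal(skew(c(-1, 0, 1), min_weeks = 3), 0)
  expect_lt(skew(c(0, 0, 0, -4), min_weeks = 4), 0)
  d <- c(1, 2, 3, 10)
  m3 <- mean((d - mean(d))^3)
  oracle <- m3 / sd(d)^3
  expect_equal(skew(d, min_weeks = 4), oracle, tolerance = 1e-12)
})

test_that("autor matches the acf convention and breaks at gaps", {
  expect_equal(autor(c(1, -1, 1, -1), min_weeks = 4), -0.75)
  expect_equal(autor(c(1, 1, -1, -1), min_weeks = 4), 0.25)
  set.seed(1)
  d <- rnorm(59)
  expect_equal(autor(d, min_weeks = 10),
               unname(acf(d, lag.max = 1, plot = FALSE)$acf[2, 1, 1]),
               tolerance = 1e-12)
  # a gap removes exactly the bridging pair from the numerator
  w <- c(1:10, 12:20)
  dg <- rnorm(19)
  dc <- dg - mean(dg)
  manual <- (sum(dc[1:9] * dc[2:10]) + sum(dc[11:18] * dc[12:19])) /
    sum(dc^2)
  expect_equal(autor(dg, weeks = w, min_weeks = 10), manual,
               tolerance = 1e-12)
  expect_true(abs(autor(dg, weeks = w, min_weeks = 10)) <= 1)
})

test_that("iid series show the -1/T small-sample autocorrelation bias", {
  set.seed(7)
  T <- 59
  r <- replicate(1000, autor(rnorm(T), min_weeks = 10))
  mc_se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - (-1 / T)), 3 * mc_se)
})

test_that("the outlier filter removes only the offending indicator", {
  set.seed(2)
  n <- 200
  tab <- data.frame(unit_id = paste0("u", 1:n), population = "purebred",
                    EP = rnorm(n, 370, 20), LNVAR = rnorm(n),
                    SKEW = rnorm(n), AUTO_R = rnorm(n, 0, 0.1))
  tab$LNVAR[1] <- mean(tab$LNVAR) + 8 * sd(tab$LNVAR)
  # still beyond the fence under the pre-filter moments (which include it)
  mu <- mean(tab$LNVAR); s <- sd(tab$LNVAR)
  expect_gt(abs(tab$LNVAR[1] - mu), 4 * s)
  f <- filter_outliers(tab)
  expect_true(is.na(f$LNVAR[1]))
  expect_false(is.na(f$EP[1]))       # EP never filtered
  expect_false(is.na(f$SKEW[1]))     # other indicators kept
  # all values within bounds -> table unchanged
  clean <- tab[-1, ]
  expect_equal(filter_outliers(clean)$LNVAR, clean$LNVAR)
  # degenerate SD = 0 population removes nothing
  tab0 <- data.frame(unit_id = "a", population = "p", EP = 1,
                     LNVAR = rep(1, 5), SKEW = 1, AUTO_R = 1)
  expect_equal(sum(is.na(filter_outliers(tab0)$LNVAR)), 0)
})

test_that("survival classes bin lifespan into 4-week intervals", {
  expect_equal(surv_class(24), "SC01")
  expect_equal(surv_class(27), "SC01")
  expect_equal(surv_class(28), "SC02")
  expect_equal(surv_class(112), "SC22")
  expect_equal(length(unique(surv_class(24:112))), 22)
})
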