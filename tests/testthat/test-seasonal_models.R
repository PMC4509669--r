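test_that("BIC weights match direct arithmetic", {
  w <- bic_weights(c(100, 102, 110))
  direct <- exp(-c(0, 2, 10) / 2) / sum(exp(-c(0, 2, 10) / 2))
  expect_equal(w, direct, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # property: closed form for arbitrary BIC vectors
  set.seed(51)
  for (k in 1:20) {
    b <- runif(sample(2:8, 1), 50, 500)
    expect_equal(bic_weights(b), exp(-(b - min(b)) / 2) / sum(exp(-(b - min(b)) / 2)),
                 tolerance = 1e-12)
  }
})

.make_daily <- function(n_days = 120, n_animals = 6, phi = 0.5, sd_e = 6,
                        sd_id = 5, curve = function(d) 40 + 25 * sin(d / 18),
                        seed = 52, year = factor("2010")) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_animals), function(a) {
    e <- if (phi == 0) rnorm(n_days, 0, sd_e) else {
      as.numeric(arima.sim(list(ar = phi), n_days, sd = sd_e * sqrt(1 - phi^2)))
    }
    data.frame(id = sprintf("S%02d", a),
               date = as.Date("2010-09-01") + 0:(n_days - 1),
               day = 0:(n_days - 1), year = year,
               depth = curve(0:(n_days - 1)) + rnorm(1, 0, sd_id) + e,
               complete = TRUE)
  }))
}

test_that("seasonal GAMM recovers a flat and a smooth truth", {
  # near-noiseless flat truth: fitted smooth is constant
  d <- .make_daily(n_days = 60, n_animals = 3, phi = 0, sd_e = 1e-4,
                   sd_id = 1e-4, curve = function(d) rep(30, length(d)))
  f <- suppressWarnings(fit_seasonal_gamm(d, "depth", ar1 = FALSE))
  pr <- predict_seasonal(f)
  expect_lt(diff(range(pr$fit)), 1e-2)
  expect_equal(mean(pr$fit), 30, tolerance = 1e-2)

  # known smooth curve + AR(1) noise + animal offsets: 95% band covers the
  # population curve at >= 90% of dates
  curve <- function(d) 45 + 30 * sin(2 * pi * d / 120) + 12 * cos(2 * pi * d / 55)
  d2 <- .make_daily(n_days = 150, n_animals = 8, phi = 0.5, sd_e = 7,
                    sd_id = 6, curve = curve, seed = 53)
  f2 <- fit_seasonal_gamm(d2, "depth", ar1 = TRUE, k = 15)
  expect_false(is.na(f2$phi))
  pr2 <- predict_seasonal(f2)
  truth <- curve(pr2$day)
  cover <- mean(truth >= pr2$lo & truth <= pr2$hi)
  expect_gte(cover, 0.90)
})

test_that("per-year smooths track year-specific peaks", {
  curve1 <- function(d) 60 + 50 * exp(-((d - 120) / 25)^2)  # Dec 30 peak
  curve2 <- function(d) 60 + 50 * exp(-((d - 210) / 25)^2)  # Mar 30 peak
  d1 <- .make_daily(n_days = 250, n_animals = 4, phi = 0.3, sd_e = 6,
                    curve = curve1, seed = 54, year = factor("2009"))
  d2 <- .make_daily(n_days = 250, n_animals = 4, phi = 0.3, sd_e = 6,
                    curve = curve2, seed = 55, year = factor("2010"))
  d2$id <- sub("S0", "T0", d2$id)
  dd <- rbind(d1, d2)
  dd$year <- factor(dd$year)
  f <- fit_seasonal_gamm(dd, "depth", k = 12)
  pr <- predict_seasonal(f)
  p1 <- pr[pr$year == "2009", ]; p2 <- pr[pr$year == "2010", ]
  expect_lt(abs(p1$day[which.max(p1$fit)] - 120), 15)
  expect_lt(abs(p2$day[which.max(p2$fit)] - 210), 15)
})

test_that("model selection requires identical rows and ranks by BIC", {
  d <- .make_daily(n_days = 80, n_animals = 4, seed = 56)
  f1 <- fit_seasonal_gamm(d, "depth", method = "ML", label = "a")
  f2 <- fit_seasonal_gamm(d, "depth", method = "ML", label = "b")
  sel <- select_models(list(f1, f2))
  expect_equal(sel$dbic, c(0, 0))
  expect_equal(sel$bicw, c(0.5, 0.5))

  f3 <- fit_seasonal_gamm(d[d$day < 60, ], "depth", method = "ML")
  expect_error(select_models(list(f1, f3)), "differing row sets")
})

test_that("diel LME detects an injected night effect and not its absence", {
  t0 <- as.POSIXct("2010-09-01", tz = "UTC")
  mk6h <- function(effect, seed) {
    set.seed(seed)
    do.call(rbind, lapply(1:8, function(a) {
      ps <- t0 + seq(0, 30 * 86400 - 1, by = 21600)
      per <- diel_bin(ps, collapse = TRUE)
      mu <- log(40) + rnorm(1, 0, 0.2) + ifelse(per == "night", effect, 0)
      data.frame(id = sprintf("S%02d", a), period_start = ps,
                 depth = exp(mu + rnorm(length(ps), 0, 0.15)))
    }))
  }
  with_eff <- mk6h(0.2, 61)
  fits <- lapply(c("1", "period"), function(rhs)
    fit_diel_lme(with_eff, "depth", rhs))
  sel <- select_models(fits)
  expect_equal(sel$label[1], "period")

  no_eff <- mk6h(0, 62)
  fits0 <- lapply(c("1", "period"), function(rhs)
    fit_diel_lme(no_eff, "depth", rhs))
  sel0 <- select_models(fits0)
  expect_equal(sel0$label[1], "1")

  # zero-variance response under log errors
  ze <- with_eff; ze$depth <- 40
  expect_error(fit_diel_lme(ze, "depth", "period"), "zero-variance")
  # sex candidates only appear September through December
  expect_true(any(grepl("sex", diel_candidates(10, with_sex = TRUE))))
  expect_false(any(grepl("sex", diel_candidates(2, with_sex = TRUE))))
})

test_that("multinomial dive-type model normalises and tracks composition", {
  set.seed(63)
  months <- factor(rep(sprintf("%02d", c(9:12, 1:4)), each = 300),
                   levels = sprintf("%02d", c(9:12, 1:4)))
  p_coast <- seq(0.7, 0.1, length.out = 8)[as.integer(months)]
  p_ben <- 0.1 + 0.05 * as.integer(months) / 8
  cls <- vapply(seq_along(months), function(i) {
    sample(c("coastal", "benthic", "pelagic"), 1,
           prob = c(p_coast[i], p_ben[i], 1 - p_coast[i] - p_ben[i]))
  }, character(1))
  dt <- data.frame(class = factor(cls), month = months,
                   year = factor("2010"))
  fit <- fit_dive_type_multinomial(dt, candidates = c("1", "month"))
  expect_equal(fit$selection$label[1], "month")
  pm <- fit$probs
  pcols <- c("coastal", "benthic", "pelagic")
  expect_true(all(abs(rowSums(pm[pcols]) - 1) < 1e-9))
  ord <- match(levels(months), pm$month)
  expect_true(all(diff(pm$coastal[ord]) < 0.05))
  expect_lt(pm$coastal[ord][8], pm$coastal[ord][1])

  one <- dt; one$class <- factor("coastal")
  expect_error(fit_dive_type_multinomial(one), ">= 2")
})

test_that("wind-lag model selection recovers an injected lag", {
  set.seed(64)
  t0 <- as.POSIXct("2010-09-01", tz = "UTC")
  tt <- t0 + seq(0, 250 * 86400 - 1, by = 21600)
  v <- rnorm(length(tt), 0, 3)
  ev <- sort(sample(30:240, 14))
  dayi <- as.numeric(difftime(tt, t0, units = "days"))
  for (s in ev) v[dayi >= s & dayi < s + 3] <- -(10 + runif(sum(dayi >= s & dayi < s + 3), 0, 4))
  wind <- data.frame(time = tt, u = rnorm(length(tt), 0, 2), v = v)
  dates <- as.Date("2010-09-01") + 0:249
  cov <- wind_covariate_grid(wind, dates, lags = 1:7)
  day <- 0:249
  base <- 1.5 + 0.8 * sin(2 * pi * day / 250)
  daily <- data.frame(date = dates, day = day, year = factor("2010"),
                      complete = TRUE, id = "pool",
                      t_bottom = base + 0.35 * cov$North_7 + rnorm(250, 0, 0.25))
  daily <- cbind(daily, cov[-1])
  res <- fit_wind_gam(daily, "t_bottom", lags = 1:7)
  expect_lte(abs(res$best_lag - 7), 1)
  expect_true(grepl("North", res$best_label))
  # a wind-bearing model beats date-only decisively
  sel <- res$selection
  expect_gt(sel$bic[sel$label == "f(date, by=year)"] - min(sel$bic), 6)

  # permuted covariate: the date-only model is competitive again
  set.seed(65)
  daily_p <- daily
  for (k in 1:7) {
    daily_p[[paste0("North_", k)]] <- sample(daily_p[[paste0("North_", k)]])
    daily_p[[paste0("NorthEast_", k)]] <- sample(daily_p[[paste0("NorthEast_", k)]])
  }
  res_p <- fit_wind_gam(daily_p, "t_bottom", lags = 1:7)
  sel_p <- res_p$selection
  expect_lt(sel_p$bic[sel_p$label == "f(date, by=year)"] - min(sel_p$bic), 6)
})

test_that("date-only model wins under the null in most replicates", {
  set.seed(66)
  t0 <- as.POSIXct("2010-09-01", tz = "UTC")
  wins <- 0; nrep <- 20
  for (r in 1:nrep) {
    tt <- t0 + seq(0, 150 * 86400 - 1, by = 21600)
    wind <- data.frame(time = tt, u = rnorm(length(tt), 0, 3),
                       v = rnorm(length(tt), 0, 4))
    dates <- as.Date("2010-09-01") + 0:149
    cov <- wind_covariate_grid(wind, dates, lags = c(3, 7))
    day <- 0:149
    daily <- data.frame(date = dates, day = day, year = factor("2010"),
                        complete = TRUE, id = "pool",
                        resp = 2 + sin(2 * pi * day / 150) + rnorm(150, 0, 0.3))
    daily <- cbind(daily, cov[-1])
    res <- fit_wind_gam(daily, "resp", lags = c(3, 7))
    if (res$selection$label[1] == "f(date, by=year)") wins <- wins + 1
  }
  expect_gte(wins / nrep, 0.8)
})

test_that("lag-1 autocorrelation estimator recovers phi", {
  set.seed(67)
  for (phi in c(0, 0.5, 0.8)) {
    x <- if (phi == 0) rnorm(5000) else as.numeric(arima.sim(list(ar = phi), 5000))
    expect_lt(abs(ar1_phi(x) - phi), 0.1)
  }
})
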