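# The statistical layer: penalised-spline additive mixed models of daily dive
# parameters, monthly diel mixed models, a multinomial dive-type model and
# wind-lag additive models -- all compared by BIC with BIC weights.
#
# BIC accounting uses n = number of observations (not groups); smoothing is
# selected by REML for reported fits, while model comparison across fixed
# structures uses ML refits. Cubic regression splines, default 10 basis
# functions per year-smooth.

#' BIC weights
#'
#' `BICw_i = exp(-dBIC_i/2) / sum_j exp(-dBIC_j/2)` over the full candidate
#' set, with `dBIC` relative to the smallest BIC.
#'
#' @param bic numeric vector of BIC values.
#' @return numeric vector of weights summing to 1.
#' @export
bic_weights <- function(bic) {
  d <- bic - min(bic)
  w <- exp(-d / 2)
  w / sum(w)
}

.sd_fit <- function(label, fit, logLik_obj, n, extra = list()) {
  df <- attr(logLik_obj, "df")
  ll <- as.numeric(logLik_obj)
  structure(c(list(label = label, fit = fit, logLik = ll, df = df, n = n,
                   bic = -2 * ll + df * log(n)), extra),
            class = "sd_fit")
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf("<sd_fit> %s: logLik %.2f, df %.1f, n %d, BIC %.2f\n",
              x$label, x$logLik, x$df, x$n, x$bic))
  invisible(x)
}

#' Fit a seasonal additive mixed model to daily series
#'
#' A penalised-regression-spline additive model for a daily dive parameter,
#' with a separate seasonal smooth per year (cubic regression splines), an
#' animal-level random intercept and AR(1) within-animal residuals to absorb
#' day-to-day dependence. Gaussian responses use `mgcv::gamm` (smoothing by
#' REML or ML); the Poisson daily-count model is fitted as a penalised Poisson
#' additive model with an animal random-effect smooth and no AR(1) term,
#' flagged in the result.
#'
#' @param daily complete daily series (see [daily_series()]); must contain
#'   `id`, `date`, the response and any linear-term columns. A numeric `day`
#'   column (days from the series start) and factor `year` and `id` columns
#'   are derived if absent.
#' @param response name of the response column.
#' @param linear character vector of linear fixed terms (e.g. `"sex"`).
#' @param by_year fit one smooth per season-year (`TRUE`) or a common smooth.
#' @param family `gaussian()` or `poisson()`.
#' @param ar1 include the AR(1) residual correlation (gaussian only).
#' @param k basis dimension per smooth.
#' @param method `"REML"` for reported fits, `"ML"` for BIC comparison.
#' @param label optional label for selection tables.
#' @return an `sd_fit` with the fitted model, BIC (n = rows) and, for
#'   gaussian fits, the estimated AR(1) phi and random-intercept SD.
#' @export
fit_seasonal_gamm <- function(daily, response, linear = character(),
                              by_year = TRUE, family = gaussian(), ar1 = TRUE,
                              k = 10, method = "REML", label = NULL) {
  d <- .prep_daily(daily)
  sm <- if (by_year && nlevels(d$year) > 1) {
    sprintf("s(day, by = year, bs = 'cr', k = %d)", k)
  } else {
    sprintf("s(day, bs = 'cr', k = %d)", k)
  }
  fixed_terms <- c(sm, if (by_year && nlevels(d$year) > 1) "year", linear)
  fml <- as.formula(paste(response, "~", paste(fixed_terms, collapse = " + ")))
  if (is.null(label)) {
    label <- paste0("f(date", if (by_year) ", by=year", ")",
                    if (length(linear)) paste0(" + ", paste(linear, collapse = " + ")))
  }
  if (family$family == "gaussian") {
    corr <- if (ar1) nlme::corAR1(form = ~ day | id) else NULL
    g <- mgcv::gamm(fml, random = list(id = ~1), correlation = corr,
                    data = d, family = family, method = method)
    ll <- logLik(g$lme)
    phi <- if (ar1) {
      cs <- g$lme$modelStruct$corStruct
      as.numeric(coef(cs, unconstrained = FALSE)[1])
    } else NA_real_
    vc <- nlme::VarCorr(g$lme)
    re_sd <- suppressWarnings(as.numeric(vc[rownames(vc) == "(Intercept)",
                                            "StdDev"][1]))
    .sd_fit(label, g, ll, nrow(d),
            list(phi = phi, re_sd = re_sd, backend = "gamm",
                 data = d, response = response))
  } else {
    fml2 <- stats::update.formula(fml, . ~ . + s(id, bs = "re"))
    g <- mgcv::gam(fml2, data = d, family = family,
                   method = if (method == "REML") "REML" else "ML")
    ll <- logLik(g)
    .sd_fit(label, g, ll, nrow(d),
            list(phi = NA_real_, re_sd = NA_real_, backend = "gam",
                 ar1_dropped = TRUE, data = d, response = response))
  }
}

.prep_daily <- function(daily) {
  d <- daily
  if ("complete" %in% names(d)) d <- d[d$complete, , drop = FALSE]
  if (!"day" %in% names(d)) d$day <- as.numeric(d$date - min(d$date))
  if (!"year" %in% names(d) || !is.factor(d$year)) {
    m <- as.integer(format(d$date, "%m"))
    y <- as.integer(format(d$date, "%Y"))
    d$year <- factor(ifelse(m >= 7, y, y - 1L))
  }
  if ("id" %in% names(d)) d$id <- factor(d$id)
  d
}

#' Evaluate a fitted seasonal curve with pointwise intervals
#'
#' The 95\% pointwise band is for the population-level curve: with a random
#' animal intercept the fixed curve is only estimable up to the realised mean
#' of the sampled animals' offsets, so the band adds the between-animal
#' variance contribution `re_sd^2 / n_animals` to the smooth's standard
#' error.
#'
#' @param fit `sd_fit` from [fit_seasonal_gamm()].
#' @param newdata data frame with `day` and `year` (and any linear terms);
#'   defaults to the fitting data's grid.
#' @return data frame `day`, `year`, `fit`, `se`, `lo`, `hi` (95\% pointwise).
#' @export
predict_seasonal <- function(fit, newdata = NULL) {
  d <- fit$data
  if (is.null(newdata)) {
    newdata <- unique(d[, c("day", "year")])
    newdata$id <- d$id[1]
  }
  if (!"id" %in% names(newdata)) newdata$id <- d$id[1]
  if (fit$backend == "gamm") {
    pr <- predict(fit$fit$gam, newdata = newdata, se.fit = TRUE,
                  newdata.guaranteed = TRUE)
    se_extra <- if (is.finite(fit$re_sd)) {
      fit$re_sd / sqrt(nlevels(droplevels(d$id)))
    } else 0
  } else {
    pr <- predict(fit$fit, newdata = newdata, se.fit = TRUE,
                  exclude = "s(id)", newdata.guaranteed = TRUE)
    se_extra <- 0
  }
  out <- newdata
  out$fit <- as.numeric(pr$fit)
  out$se <- sqrt(as.numeric(pr$se.fit)^2 + se_extra^2)
  out$lo <- out$fit - 1.96 * out$se
  out$hi <- out$fit + 1.96 * out$se
  out
}

#' Rank candidate fits by BIC
#'
#' All candidates must be fitted on the same observation set; BIC weights are
#' normalised over the full candidate set before any display filtering.
#'
#' @param fits list of `sd_fit` objects (same data rows).
#' @param bicw_min display filter: rows with smaller weight are marked
#'   `shown = FALSE` but retained.
#' @return data frame `label`, `bic`, `dbic`, `bicw`, `df`, `shown`, ranked
#'   by ascending BIC.
#' @export
select_models <- function(fits, bicw_min = 0.01) {
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("select_models: candidates were fitted on differing row sets")
  }
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  lab <- vapply(fits, function(f) f$label, character(1))
  w <- bic_weights(bic)
  out <- data.frame(label = lab, bic = bic, dbic = bic - min(bic), bicw = w,
                    df = vapply(fits, function(f) f$df, numeric(1)))
  out <- out[order(out$bic), ]
  out$shown <- out$bicw >= bicw_min
  rownames(out) <- NULL
  out
}

#' Monthly diel linear mixed model
#'
#' Within one month's 6-h records, fits a linear mixed model (animal random
#' intercept, AR(1) within-animal residuals) of a log-transformed response on
#' a candidate fixed structure, by maximum likelihood for BIC comparability.
#'
#' @param data6h data frame of 6-h records with `id`, `period_start` and the
#'   response; a diel `period` factor (day/night) is derived if absent.
#' @param response response column; log-transformed when `log_response`.
#' @param fixed right-hand-side formula string, e.g. `"period + year"` or
#'   `"1"` for the null model.
#' @param log_response apply `log()` to the response.
#' @param label optional label.
#' @return `sd_fit` (backend `lme`).
#' @export
fit_diel_lme <- function(data6h, response, fixed = "1", log_response = TRUE,
                         label = NULL) {
  d <- data6h
  if (!"period" %in% names(d)) d$period <- diel_bin(d$period_start, collapse = TRUE)
  if (length(unique(d$period)) < 2 && grepl("period", fixed)) {
    stop("fit_diel_lme: single diel level present")
  }
  d$id <- factor(d$id)
  y <- d[[response]]
  if (log_response) {
    if (any(y <= 0)) stop("fit_diel_lme: nonpositive response under log")
    if (var(y) == 0) stop("fit_diel_lme: zero-variance response")
    d$.y <- log(y)
  } else {
    d$.y <- y
  }
  fml <- as.formula(paste(".y ~", fixed))
  fit <- nlme::lme(fml, random = ~ 1 | id,
                   correlation = nlme::corAR1(form = ~ 1 | id),
                   data = d, method = "ML",
                   control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                              msMaxIter = 200))
  if (is.null(label)) label <- fixed
  phi <- as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE)[1])
  .sd_fit(label, fit, logLik(fit), nrow(d), list(phi = phi, backend = "lme"))
}

#' Diel candidate structures for a month
#'
#' The candidate fixed structures are the null model, `period`, `year`,
#' `period + year` and `period * year`; sex main effect and interactions are
#' added only for September-December months (females transmit too briefly
#' later in the season for the contrast to be estimable).
#'
#' @param month integer month (1-12).
#' @param years number of distinct years in the data.
#' @param with_sex whether a `sex` column is available.
#' @return character vector of fixed structures.
#' @export
diel_candidates <- function(month, years = 2, with_sex = FALSE) {
  cand <- c("1", "period")
  if (years > 1) cand <- c(cand, "year", "period + year", "period * year")
  if (with_sex && month %in% 9:12) {
    cand <- c(cand, "period + sex", "period * sex")
  }
  cand
}

#' Multinomial dive-type model
#'
#' Fits multinomial logistic models of the dive-type category (coastal,
#' benthic, pelagic) on month/year/age structures, compares them by BIC, and
#' returns per-month predicted category probabilities for the best model.
#' Sparse category-month cells are stabilised with a small ridge penalty
#' (`decay`) and flagged.
#'
#' @param divetype data frame with `class` (factor), `month` (factor),
#'   `year` (factor) and optionally `age`.
#' @param candidates character vector of right-hand sides.
#' @param decay ridge penalty passed to `nnet::multinom`.
#' @return list: `selection` (BIC table), `fits`, `best`, `probs` (predicted
#'   category probabilities per month/year), `sparse_cells` flag.
#' @export
fit_dive_type_multinomial <- function(divetype,
                                      candidates = c("1", "month",
                                                     "month + year",
                                                     "month * year"),
                                      decay = 1e-4) {
  d <- divetype[!is.na(divetype$class), , drop = FALSE]
  d$class <- droplevels(factor(d$class))
  if (nlevels(d$class) < 2) {
    stop("fit_dive_type_multinomial: need >= 2 observed categories")
  }
  if ("age" %in% names(d) && !"month * year + age" %in% candidates) {
    candidates <- c(candidates, "month * year + age")
  }
  # drop candidates that reference single-level factors (e.g. a one-year
  # deployment): their design matrices are rank-deficient
  single <- names(Filter(function(col) is.factor(col) && nlevels(droplevels(factor(col))) < 2,
                         d[, setdiff(names(d), "class"), drop = FALSE]))
  keep <- vapply(candidates, function(rhs) {
    vars <- all.vars(as.formula(paste("~", rhs)))
    !any(vars %in% single)
  }, logical(1))
  if (!all(keep)) {
    message("fit_dive_type_multinomial: dropped candidate(s) with single-level factors: ",
            paste(candidates[!keep], collapse = "; "))
    candidates <- candidates[keep]
  }
  if (!length(candidates)) candidates <- "1"
  tab <- table(d$class, d$month)
  sparse <- any(tab == 0)
  fits <- lapply(candidates, function(rhs) {
    fml <- as.formula(paste("class ~", rhs))
    fit <- nnet::multinom(fml, data = d, trace = FALSE, maxit = 500,
                          decay = decay, model = TRUE)
    .sd_fit(rhs, fit, logLik(fit), nrow(d), list(backend = "multinom"))
  })
  sel <- select_models(fits)
  best <- fits[[which.min(vapply(fits, function(f) f$bic, numeric(1)))]]
  grid <- unique(d[, intersect(c("month", "year", "age"), names(d)),
                   drop = FALSE])
  pr <- predict(best$fit, newdata = grid, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # 2-category case
  probs <- cbind(grid, as.data.frame(pr))
  list(selection = sel, fits = fits, best = best, probs = probs,
       sparse_cells = sparse)
}

#' Wind-lag additive models
#'
#' For a daily response, fits the candidate additive structures
#' date-only, `+North` (linear), `+f(North)`, `+f(North, by=year)` and the
#' three north-easterly analogues, across a grid of covariate lags, all by ML
#' for BIC comparability. Returns the full structure-by-lag grid, the
#' selection table at the best lag and the best lag itself (chosen by BIC over
#' every wind-bearing candidate).
#'
#' @param daily data frame with `date`, the response, and covariate columns
#'   `North_<k>` / `NorthEast_<k>` from [wind_covariate_grid()].
#' @param response response column name.
#' @param lags lags (days) to scan.
#' @param k_date,k_wind basis dimensions.
#' @return list: `grid` (label, lag, bic), `selection` (Table-5-style
#'   candidate table at the best lag, BIC weights over those candidates),
#'   `best_lag`, `best_label`, `fits` at the best lag.
#' @export
fit_wind_gam <- function(daily, response, lags = 1:7, k_date = 10, k_wind = 5) {
  d <- .prep_daily(daily)
  d <- d[!is.na(d[[response]]), , drop = FALSE]
  ny <- nlevels(droplevels(d$year))
  date_sm <- if (ny > 1) {
    sprintf("s(day, by = year, bs = 'cr', k = %d) + year", k_date)
  } else {
    sprintf("s(day, bs = 'cr', k = %d)", k_date)
  }
  structures <- function(w) {
    out <- c(
      setNames(sprintf("%s + %s", date_sm, w), sprintf("+ %s", w)),
      setNames(sprintf("%s + s(%s, k = %d, bs = 'cr')", date_sm, w, k_wind),
               sprintf("+ f(%s)", w)))
    if (ny > 1) {
      out <- c(out, setNames(
        sprintf("%s + s(%s, by = year, k = %d, bs = 'cr')", date_sm, w, k_wind),
        sprintf("+ f(%s, by=year)", w)))
    }
    out
  }
  fit_one <- function(rhs, label, lag) {
    fml <- as.formula(paste(response, "~", rhs))
    g <- mgcv::gam(fml, data = d, method = "ML")
    .sd_fit(label, g, logLik(g), nrow(d), list(lag = lag, backend = "gam"))
  }
  rows <- list(); fits <- list()
  base_fit <- fit_one(date_sm, "f(date, by=year)", NA_integer_)
  rows[[1]] <- data.frame(label = base_fit$label, lag = NA_integer_,
                          bic = base_fit$bic)
  fits[["f(date, by=year)|NA"]] <- base_fit
  for (lag in lags) {
    for (w in c("North", "NorthEast")) {
      col <- paste0(w, "_", lag)
      if (is.null(d[[col]])) next
      if (all(d[[col]] == 0)) {
        warning(sprintf("fit_wind_gam: covariate %s all zero; dropped", col))
        next
      }
      dd <- d; dd[[w]] <- dd[[col]]
      for (nm in names(structures(w))) {
        rhs <- structures(w)[[nm]]
        fml <- as.formula(paste(response, "~", rhs))
        g <- mgcv::gam(fml, data = dd, method = "ML")
        f <- .sd_fit(paste0("f(date, by=year) ", nm), g, logLik(g), nrow(dd),
                     list(lag = lag, backend = "gam"))
        key <- paste0(f$label, "|", lag)
        rows[[length(rows) + 1]] <- data.frame(label = f$label, lag = lag,
                                               bic = f$bic)
        fits[[key]] <- f
      }
    }
  }
  grid <- do.call(rbind, rows)
  windy <- grid[!is.na(grid$lag), ]
  best_row <- windy[which.min(windy$bic), ]
  best_lag <- best_row$lag
  at_best <- c(fits["f(date, by=year)|NA"],
               fits[grid$lag == best_lag & !is.na(grid$lag)])
  at_best <- Filter(Negate(is.null), at_best)
  sel <- select_models(unname(at_best))
  list(grid = grid, selection = sel, best_lag = best_lag,
       best_label = best_row$label, fits = at_best)
}

#' Estimate the AR(1) coefficient of a residual series
#'
#' Lag-1 autocorrelation estimator used for diagnostics and parameter
#' recovery checks.
#'
#' @param x numeric series.
#' @return estimated phi.
#' @export
ar1_phi <- function(x) {
  x <- x[!is.na(x)]
  x <- x - mean(x)
  sum(x[-1] * x[-length(x)]) / sum(x^2)
}
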