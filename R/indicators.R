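#' Crop-cycle periods used for environmental characterization
#'
#' Indicator computation slices the daily series into the key periods of the
#' winter oilseed rape cycle: fall (F), climatic winter (CW), bolting (B),
#' flowering (FLO), seed number fixation (P300), reserve allocation to the
#' pod (P600) and seed growth (P1000).
#' @export
CROP_PERIODS <- c("F", "CW", "B", "FLO", "P300", "P600", "P1000")

#' Describe one trial environment
#'
#' An environment is one `year x location x nitrogen regime` combination,
#' carrying the dated boundaries of its crop-cycle periods and the maximal
#' water holding capacity of its soil.
#'
#' @param environment_id unique identifier string.
#' @param year harvest year.
#' @param location location code.
#' @param n_regime `"N+"` (optimal fertilization) or `"N-"` (reduced).
#' @param periods named list over [CROP_PERIODS]; each element a length-2
#'   `Date` vector `(start, end)`. Periods must be ordered and
#'   non-overlapping.
#' @param wsc_max maximal soil water capacity in mm (> 0).
#' @return an object of class `env_record`.
#' @export
env_record <- function(environment_id, year, location, n_regime, periods, wsc_max) {
  if (!all(CROP_PERIODS %in% names(periods)))
    stop_field("periods", paste("must define", paste(CROP_PERIODS, collapse = ", ")))
  periods <- periods[CROP_PERIODS]
  for (p in CROP_PERIODS) {
    b <- periods[[p]]
    if (length(b) != 2L || !inherits(b, "Date") || b[2] < b[1])
      stop_field("periods", sprintf("period %s must be an ordered Date pair", p))
  }
  starts <- as.numeric(vapply(periods, function(b) as.numeric(b[1]), 0))
  ends   <- as.numeric(vapply(periods, function(b) as.numeric(b[2]), 0))
  if (any(diff(starts) <= 0) || any(starts[-1] <= ends[-length(ends)]))
    stop_field("periods", "periods must be ordered F < CW < B < FLO < P300 < P600 < P1000 and non-overlapping")
  if (!is.numeric(wsc_max) || wsc_max <= 0) stop_field("wsc_max", "must be > 0")
  if (!n_regime %in% c("N+", "N-")) stop_field("n_regime", "must be \"N+\" or \"N-\"")
  structure(
    list(environment_id = as.character(environment_id), year = year,
         location = location, n_regime = n_regime, periods = periods,
         wsc_max = as.numeric(wsc_max)),
    class = "env_record")
}

#' Daily single-bucket soil water balance
#'
#' Tracks soil water content (WSC) forward from field capacity with
#' `WSC_t = clamp(WSC_{t-1} + rain_t - et0_t, 0, wsc_max)`. A day is flagged
#' as a leaching day when the pre-clamp content exceeds `wsc_max` (drainage
#' out of the bucket).
#'
#' @param weather data frame with contiguous daily rows and columns `date`,
#'   `rain_mm`, `et0_mm`.
#' @param wsc_max bucket capacity in mm.
#' @return data frame with columns `date`, `wsc` (mm) and `leaching`
#'   (logical).
#' @export
daily_water_balance <- function(weather, wsc_max) {
  if (!is.numeric(wsc_max) || wsc_max <= 0) stop_field("wsc_max", "must be > 0")
  need <- c("date", "rain_mm", "et0_mm")
  if (!all(need %in% names(weather)))
    stop_field("weather", paste("must contain", paste(need, collapse = ", ")))
  d <- as.numeric(weather$date)
  if (nrow(weather) > 1 && any(diff(d) != 1))
    stop_field("weather", "daily series has gaps; dates must be contiguous")
  n <- nrow(weather)
  wsc <- numeric(n)
  leach <- logical(n)
  prev <- wsc_max
  for (t in seq_len(n)) {
    raw <- prev + weather$rain_mm[t] - weather$et0_mm[t]
    leach[t] <- raw > wsc_max
    prev <- min(max(raw, 0), wsc_max)
    wsc[t] <- prev
  }
  data.frame(date = weather$date, wsc = wsc, leaching = leach)
}

#' Specify a period-level indicator
#'
#' @param name indicator name (e.g. `"HT_FLO"`).
#' @param period one of [CROP_PERIODS].
#' @param statistic one of `"mean"`, `"min"`, `"max"`, `"count_above"`,
#'   `"count_below"`, `"sum"`, `"count_zero_wsc"`.
#' @param variable column of the daily series the statistic applies to
#'   (`tmean`, `tmax`, `tmin`, `rain_mm`, `radiation_MJ_m2`, `wsc`, ...).
#' @param threshold threshold for the counting statistics (e.g. 25 degC for
#'   high-temperature days).
#' @return an `indicator_spec` object.
#' @export
indicator_spec <- function(name, period, statistic, variable, threshold = NA_real_) {
  stats_ok <- c("mean", "min", "max", "count_above", "count_below", "sum",
                "count_zero_wsc")
  if (!statistic %in% stats_ok)
    stop_field("statistic", paste("must be one of", paste(stats_ok, collapse = ", ")))
  if (!period %in% CROP_PERIODS) stop_field("period", "unknown crop period")
  if (statistic %in% c("count_above", "count_below") && is.na(threshold))
    stop_field("threshold", paste("required for statistic", statistic))
  structure(list(name = name, period = period, statistic = statistic,
                 variable = variable, threshold = threshold),
            class = "indicator_spec")
}

#' Compute one period statistic for one environment
#'
#' The statistic is evaluated over the closed date interval of the period as
#' defined in the environment record.
#'
#' @param series daily data frame with a `date` column and the variable named
#'   in `spec` (weather columns and/or the `wsc` column from
#'   [daily_water_balance()]).
#' @param spec an [indicator_spec()].
#' @param env an [env_record()].
#' @return a single numeric value.
#' @export
period_statistic <- function(series, spec, env) {
  stopifnot(inherits(spec, "indicator_spec"), inherits(env, "env_record"))
  b <- env$periods[[spec$period]]
  if (is.null(b)) stop_field("spec", sprintf("period %s not defined for %s",
                                             spec$period, env$environment_id))
  sel <- series$date >= b[1] & series$date <= b[2]
  if (!any(sel))
    stop_field("period", sprintf("period %s covers zero days of the series", spec$period))
  if (!spec$variable %in% names(series))
    stop_field("variable", sprintf("column %s absent from series", spec$variable))
  x <- series[[spec$variable]][sel]
  switch(spec$statistic,
    mean = mean(x),
    min = min(x),
    max = max(x),
    sum = sum(x),
    count_above = sum(x > spec$threshold),
    count_below = sum(x < spec$threshold),
    count_zero_wsc = sum(x == 0))
}

# Trace threshold: a day counts as rain-free when rain < 0.1 mm, which keeps
# the dryness indicators insensitive to float noise in the rain column.
RAIN_TRACE_MM <- 0.1

#' Water regime around one nitrogen supply
#'
#' Computes the five per-supply water indicators: DBI (maximum run of
#' consecutive rain-free days within the 10 days before the supply), DAI
#' (number of rain-free days in the 10 days after), RF (total rainfall in the
#' 10 days after), RO (number of leaching days in the 10 days after) and
#' WSC_I (mean soil water content from 3 days before through 10 days after,
#' as a percentage of `wsc_max`). The supply day itself belongs to the
#' "after" window; windows are closed, day-resolved intervals.
#'
#' @param supply_date date of the N application.
#' @param weather daily weather with `date` and `rain_mm`.
#' @param wsc daily water-balance output of [daily_water_balance()].
#' @param wsc_max bucket capacity in mm.
#' @return named numeric vector `c(DBI, DAI, RF, RO, WSC_I)`.
#' @export
per_supply_water_indicators <- function(supply_date, weather, wsc, wsc_max) {
  d <- weather$date
  if (!supply_date %in% d) stop_field("supply_date", "not within the weather series")
  i <- match(supply_date, d)
  if (i - 10 < 1 || i + 9 > length(d))
    stop_field("supply_date", "fewer than 10 days of data on one side of the supply")
  before <- weather$rain_mm[(i - 10):(i - 1)]
  after  <- weather$rain_mm[i:(i + 9)]
  dry_before <- before < RAIN_TRACE_MM
  runs <- rle(dry_before)
  dbi <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
  dai <- sum(after < RAIN_TRACE_MM)
  rf <- sum(after)
  ro <- sum(wsc$leaching[i:(i + 9)])
  if (i - 3 < 1) stop_field("supply_date", "fewer than 3 days of data before the supply")
  wsc_i <- mean(wsc$wsc[(i - 3):(i + 9)]) / wsc_max * 100
  c(DBI = dbi, DAI = dai, RF = rf, RO = ro, WSC_I = wsc_i)
}

#' Aggregate per-supply indicator values into one trial-level indicator
#'
#' Nitrogen is supplied in one to three applications; per-supply values are
#' combined as a supply-weighted mean, `sum_i value_i * N_i / N_total`. With
#' no fertilization at all the final indicator is fixed to 0.
#'
#' @param values per-supply indicator values.
#' @param amounts per-supply N amounts (kg/ha), same length as `values`.
#' @return the aggregated indicator value.
#' @export
aggregate_supply_indicator <- function(values, amounts) {
  if (length(values) != length(amounts))
    stop_field("amounts", "length must match `values`")
  if (length(amounts) && any(amounts < 0)) stop_field("amounts", "must be >= 0")
  n_total <- sum(amounts)
  if (length(values) == 0L || n_total == 0) return(0)
  sum(values * amounts / n_total)
}

#' Vernalization fulfilment indicator
#'
#' Fraction of the vernalization requirement met: the number of days with
#' mean temperature in `[t_lo, t_hi]` degC over fall and climatic winter,
#' divided by the requirement in days and capped at 1.
#'
#' @param weather daily weather with `date` and `tmean`.
#' @param env an [env_record()].
#' @param t_lo,t_hi vernalizing temperature band in degC.
#' @param requirement_days days of vernalizing temperature needed for full
#'   fulfilment.
#' @return value in `[0, 1]`.
#' @export
vernalization_indicator <- function(weather, env, t_lo = 0, t_hi = 7,
                                    requirement_days = 40) {
  span <- c(env$periods[["F"]][1], env$periods[["CW"]][2])
  sel <- weather$date >= span[1] & weather$date <= span[2]
  days <- sum(weather$tmean[sel] >= t_lo & weather$tmean[sel] <= t_hi)
  min(days / requirement_days, 1)
}

#' Default seed-yield limiting indicator specifications
#'
#' The 13 limiting indicators retained for winter oilseed rape seed yield:
#' six temperature indicators (TMN_CW, TMAX_B, TMAX_FLO, HT_FLO, TMAX_P300,
#' TMIN_P600), two water-status indicators (WSC_MAX, WD_P600), radiation at
#' flowering (SSR_FLO), vernalization conditions (VERN) and three nitrogen
#' indicators (NNI, N_total, DAI). The period-statistic members are returned
#' as [indicator_spec()] objects; WSC_MAX, VERN, NNI, N_total and DAI are
#' handled specially by [build_indicator_matrix()].
#' @return named list of `indicator_spec` objects.
#' @export
limiting_indicator_specs <- function() {
  specs <- list(
    indicator_spec("TMN_CW",    "CW",   "mean",        "tmean"),
    indicator_spec("TMAX_B",    "B",    "max",         "tmax"),
    indicator_spec("TMAX_FLO",  "FLO",  "max",         "tmax"),
    indicator_spec("HT_FLO",    "FLO",  "count_above", "tmax", threshold = 25),
    indicator_spec("TMAX_P300", "P300", "max",         "tmax"),
    indicator_spec("TMIN_P600", "P600", "min",         "tmin"),
    indicator_spec("WD_P600",   "P600", "count_zero_wsc", "wsc"),
    indicator_spec("SSR_FLO",   "FLO",  "sum",         "radiation_MJ_m2"))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# Names of the full limiting-factor set in canonical order.
LIMITING_INDICATORS <- c("TMN_CW", "TMAX_B", "TMAX_FLO", "HT_FLO", "TMAX_P300",
                         "TMIN_P600", "WD_P600", "WSC_MAX", "SSR_FLO", "VERN",
                         "NNI", "N_total", "DAI")

#' Build the environments x indicators matrix
#'
#' Computes, for every environment, the period statistics requested in
#' `specs` plus the management-derived indicators: WSC_MAX (soil), VERN
#' (vernalization fulfilment), NNI/ADB/AN (measured plant N status, missing
#' marker when not measured), N_total (total fertilization) and the five
#' Eq.-style supply-aggregated water indicators (DBI, DAI, RF, RO, WSC_I).
#'
#' @param environments list of [env_record()] objects.
#' @param weather daily weather data frame for all environments
#'   (`environment_id`, `date`, `tmin`, `tmean`, `tmax`, `rain_mm`,
#'   `et0_mm`, `radiation_MJ_m2`).
#' @param management list with elements `supplies` (data frame
#'   `environment_id`, `supply_date`, `n_amount_kg_ha`) and `measured` (data
#'   frame `environment_id`, `nni`, `adb`, `an`; may omit environments).
#' @param specs list of [indicator_spec()] objects; defaults to
#'   [limiting_indicator_specs()].
#' @param columns which indicator columns to keep, in order; defaults to the
#'   13 limiting indicators.
#' @return data frame, one row per environment, first column
#'   `environment_id`, remaining columns named indicators (`NA` = missing).
#' @export
build_indicator_matrix <- function(environments, weather, management,
                                   specs = limiting_indicator_specs(),
                                   columns = LIMITING_INDICATORS) {
  supply_names <- c("DBI", "DAI", "RF", "RO", "WSC_I")
  known <- c(vapply(specs, `[[`, "", "name"), "WSC_MAX", "VERN", "NNI", "ADB",
             "AN", "N_total", supply_names)
  bad <- setdiff(columns, known)
  if (length(bad))
    stop_field("columns", paste("unknown indicator name(s):", paste(bad, collapse = ", ")))
  rows <- lapply(environments, function(env) {
    id <- env$environment_id
    w <- weather[weather$environment_id == id, , drop = FALSE]
    if (!nrow(w)) stop_field("weather", paste("no weather rows for", id))
    w <- w[order(w$date), , drop = FALSE]
    bal <- daily_water_balance(w, env$wsc_max)
    series <- cbind(w, wsc = bal$wsc)
    vals <- vapply(specs, period_statistic, 0, series = series, env = env)
    names(vals) <- vapply(specs, `[[`, "", "name")
    vals["WSC_MAX"] <- env$wsc_max
    vals["VERN"] <- vernalization_indicator(w, env)
    sup <- management$supplies
    sup <- sup[sup$environment_id == id, , drop = FALSE]
    vals["N_total"] <- sum(sup$n_amount_kg_ha)
    if (nrow(sup)) {
      per <- t(vapply(seq_len(nrow(sup)), function(i) {
        per_supply_water_indicators(sup$supply_date[i], w, bal, env$wsc_max)
      }, structure(numeric(5), names = supply_names)))
      for (nm in supply_names)
        vals[nm] <- aggregate_supply_indicator(per[, nm], sup$n_amount_kg_ha)
    } else {
      vals[supply_names] <- 0
    }
    meas <- management$measured
    m <- meas[meas$environment_id == id, , drop = FALSE]
    vals["NNI"] <- if (nrow(m)) m$nni[1] else NA_real_
    vals["ADB"] <- if (nrow(m)) m$adb[1] else NA_real_
    vals["AN"]  <- if (nrow(m)) m$an[1] else NA_real_
    vals
  })
  out <- as.data.frame(do.call(rbind, rows))[, columns, drop = FALSE]
  ids <- vapply(environments, `[[`, "", "environment_id")
  if (anyDuplicated(ids)) stop_field("environments", "duplicated environment_id")
  cbind(data.frame(environment_id = ids), out)
}

#' Impute missing indicator values by iterative low-rank reconstruction
#'
#' Missing cells are filled by a regularized iterative principal-component
#' reconstruction: columns are centred and scaled, missing entries
#' initialized at 0 (the column mean), and the rank-`n_components` truncated
#' SVD reconstruction is re-imputed into the missing cells until the change
#' falls below `tol` (max 500 iterations). Observed cells are never altered.
#'
#' @param X data frame or matrix of indicators; an `environment_id` first
#'   column is carried through untouched.
#' @param n_components reconstruction rank.
#' @param tol convergence tolerance on the missing-cell update.
#' @param max_iter iteration cap.
#' @return completed object of the same shape.
#' @export
impute_indicator_matrix <- function(X, n_components = 2, tol = 1e-6,
                                    max_iter = 500) {
  id_col <- NULL
  if (is.data.frame(X) && names(X)[1] == "environment_id") {
    id_col <- X[[1]]
    X <- X[, -1, drop = FALSE]
  }
  M <- as.matrix(X)
  if (!is.numeric(M)) stop_field("X", "must be numeric")
  miss <- is.na(M)
  if (any(colSums(!miss) < 2))
    stop_field("X", paste("column(s) with <2 observed values:",
                          paste(colnames(M)[colSums(!miss) < 2], collapse = ", ")))
  if (any(miss)) {
    k <- max(min(n_components, dim(M) - 1L), 1L)
    mu <- colMeans(M, na.rm = TRUE)
    sdev <- apply(M, 2, stats::sd, na.rm = TRUE)
    sdev[sdev == 0 | is.na(sdev)] <- 1
    M[miss] <- mu[col(M)[miss]]
    for (it in seq_len(max_iter)) {
      # means and scales re-estimated from the completed matrix so the
      # centring is self-consistent at convergence
      mu <- colMeans(M)
      Z <- sweep(sweep(M, 2, mu), 2, sdev, "/")
      s <- svd(Z, nu = k, nv = k)
      rec <- s$u %*% (s$d[seq_len(k)] * t(s$v))
      new_vals <- (rec * rep(sdev, each = nrow(M)) +
                     rep(mu, each = nrow(M)))[miss]
      delta <- max(abs(new_vals - M[miss]))
      M[miss] <- new_vals
      if (delta < tol) break
    }
  }
  out <- as.data.frame(M)
  if (!is.null(id_col)) out <- cbind(data.frame(environment_id = id_col), out)
  out
}
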