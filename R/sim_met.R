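# Baseline values and between-envirotype spreads of the 13 limiting
# indicators used to build envirotype templates. Units are native indicator
# units (degC, days, mm, MJ/m2, kg/ha, dimensionless).
TEMPLATE_BASE <- c(
  TMN_CW = 4, TMAX_B = 16, TMAX_FLO = 24, HT_FLO = 3, TMAX_P300 = 24,
  TMIN_P600 = 8, WD_P600 = 5, WSC_MAX = 120, SSR_FLO = 450, VERN = 1,
  NNI = 1.05, N_total = 165, DAI = 4)
TEMPLATE_SPREAD <- c(
  TMN_CW = 2, TMAX_B = 2.5, TMAX_FLO = 3, HT_FLO = 3, TMAX_P300 = 3,
  TMIN_P600 = 2, WD_P600 = 4, WSC_MAX = 35, SSR_FLO = 80, VERN = 0,
  NNI = 0.18, N_total = 35, DAI = 3)

# Fixed period boundaries of the simulated season (sowing-year Sep 1 to
# harvest-year Jul 10).
season_periods <- function(harvest_year) {
  y0 <- harvest_year - 1
  mk <- function(a, b) as.Date(c(a, b))
  list(
    "F"    = mk(sprintf("%d-09-01", y0), sprintf("%d-11-30", y0)),
    CW     = mk(sprintf("%d-12-01", y0), sprintf("%d-02-15", harvest_year)),
    B      = mk(sprintf("%d-02-16", harvest_year), sprintf("%d-03-31", harvest_year)),
    FLO    = mk(sprintf("%d-04-01", harvest_year), sprintf("%d-04-30", harvest_year)),
    P300   = mk(sprintf("%d-05-01", harvest_year), sprintf("%d-05-20", harvest_year)),
    P600   = mk(sprintf("%d-05-21", harvest_year), sprintf("%d-06-15", harvest_year)),
    P1000  = mk(sprintf("%d-06-16", harvest_year), sprintf("%d-07-10", harvest_year)))
}

#' Generate a synthetic multi-environment trial design
#'
#' Builds the environments of a MET (year x location x N regime), their
#' daily weather and their nitrogen management so that environments of the
#' same envirotype share a template over the 13 limiting indicators, with
#' within-envirotype noise. Weather is generated backwards from the
#' template: period temperatures, flowering heat days and radiation,
#' post-pod-set dryness, and the rain pattern around N supplies are
#' adjusted so that the indicator stage recovers the planted envirotype
#' structure. Low-N regimes receive 80-100 kg/ha less nitrogen than
#' high-N regimes.
#'
#' @param config a [sim_config()].
#' @return list with `environments` (list of [env_record()]),
#'   `weather` (daily data frame over all environments), `management`
#'   (list of `supplies` and `measured` data frames) and `truth`
#'   (`envirotype` assignment data frame, `templates` matrix,
#'   `env_targets` matrix of per-environment indicator targets).
#' @export
generate_met <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 101L), {
    k <- config$n_envirotypes
    n <- config$n_environments
    ind <- names(TEMPLATE_BASE)
    p_ind <- length(ind)
    # contrasting templates: envirotype offset directions are drawn as
    # random *orthogonal* unit vectors in indicator space (scaled so each
    # indicator moves by about one TEMPLATE_SPREAD unit on average), which
    # guarantees equidistant, well-separated limiting-factor profiles
    if (k > 1 && k <= p_ind) {
      Zr <- matrix(stats::rnorm(p_ind * k), p_ind, k)
      Qo <- qr.Q(qr(Zr))                      # p_ind x k, orthonormal columns
      offsets <- t(Qo) * sqrt(p_ind) * config$envirotype_separation
    } else {
      offsets <- matrix(stats::rnorm(k * p_ind), k, p_ind) *
        config$envirotype_separation
    }
    templates <- sweep(sweep(offsets, 2, TEMPLATE_SPREAD, "*"), 2,
                       TEMPLATE_BASE, "+")
    rownames(templates) <- paste0("E", seq_len(k))
    colnames(templates) <- ind

    envirotype_of <- rep_len(seq_len(k), n)
    # N fertilization is itself part of the limiting-factor pattern, so each
    # envirotype leans toward one regime (3 of 4 environments share the
    # majority regime, as observed in real envirotyped METs) without being
    # pure
    within_idx <- stats::ave(seq_len(n), envirotype_of, FUN = seq_along)
    majority <- ifelse(envirotype_of %% 2 == 1, "N+", "N-")
    minority <- ifelse(majority == "N+", "N-", "N+")
    regimes <- ifelse(within_idx %% 4 == 0, minority, majority)
    years <- 2014 + (seq_len(n) - 1) %/% 2 %% 2
    ids <- sprintf("L%02dy%02d_%s", seq_len(n), years %% 100, regimes)

    env_targets <- matrix(0, n, length(ind), dimnames = list(ids, ind))
    environments <- vector("list", n)
    weather_rows <- vector("list", n)
    supply_rows <- vector("list", n)
    measured_rows <- vector("list", n)

    for (i in seq_len(n)) {
      tgt <- templates[envirotype_of[i], ] +
        TEMPLATE_SPREAD * config$envirotype_sd * stats::rnorm(length(ind))
      tgt["WSC_MAX"] <- max(tgt["WSC_MAX"], 40)
      tgt["HT_FLO"] <- min(max(tgt["HT_FLO"], 0), 20)
      tgt["WD_P600"] <- min(max(tgt["WD_P600"], 0), 20)
      tgt["DAI"] <- min(max(tgt["DAI"], 0), 10)
      tgt["N_total"] <- max(tgt["N_total"], 120)
      tgt["NNI"] <- max(tgt["NNI"], 0.5)
      env_targets[i, ] <- tgt

      periods <- season_periods(years[i])
      dates <- seq(periods[["F"]][1], periods[["P1000"]][2], by = "day")
      nd <- length(dates)
      period_of <- character(nd)
      for (p in CROP_PERIODS)
        period_of[dates >= periods[[p]][1] & dates <= periods[[p]][2]] <- p

      tmean <- numeric(nd)
      doy <- as.integer(format(dates, "%j"))
      base_season <- 11 - 9 * cos(2 * pi * (doy - 20) / 365)   # min ~Jan 20
      tmean <- base_season + stats::rnorm(nd, 0, 1.2)
      sel <- period_of == "CW"
      tmean[sel] <- tgt["TMN_CW"] + stats::rnorm(sum(sel), 0, 3)
      tmax <- tmean + 5.5 + stats::rnorm(nd, 0, 1.5)
      tmin <- tmean - 5 + stats::rnorm(nd, 0, 1.2)

      # bolting / pod-fill period maxima pinned to the template
      for (p in c("B", "P300")) {
        sel <- which(period_of == p)
        key <- if (p == "B") "TMAX_B" else "TMAX_P300"
        tmax[sel] <- tgt[key] - stats::runif(length(sel), 2, 8)
        tmax[sample(sel, 1)] <- tgt[key] + stats::rnorm(1, 0, 0.3)
      }
      # flowering: heat-day count and max temperature
      sel <- which(period_of == "FLO")
      ht <- round(min(max(tgt["HT_FLO"], 0), length(sel) - 1))
      tmax[sel] <- 21 + stats::rnorm(length(sel), 0, 1.2)
      tmax[sel][tmax[sel] >= 24.5] <- 24.4
      if (ht > 0) {
        hot <- sample(sel, ht)
        tmax[hot] <- 26.5 + abs(stats::rnorm(ht, 0, 1))
      }
      peak <- max(tgt["TMAX_FLO"], if (ht > 0) max(tmax[sel]) + 0.5 else 24.8)
      tmax[sample(sel, 1)] <- peak
      # pod growth: minimum temperature pinned
      sel <- which(period_of == "P600")
      tmin[sel] <- tgt["TMIN_P600"] + stats::runif(length(sel), 1, 5)
      tmin[sample(sel, 1)] <- tgt["TMIN_P600"] + stats::rnorm(1, 0, 0.3)

      # radiation: flowering sum pinned, seasonal elsewhere
      rad <- pmax(2, 10 - 8 * cos(2 * pi * (doy - 20) / 365) + stats::rnorm(nd, 0, 1.5))
      sel <- which(period_of == "FLO")
      rad[sel] <- pmax(1, tgt["SSR_FLO"] / length(sel) + stats::rnorm(length(sel), 0, 0.8))

      # reference evapotranspiration: seasonal
      et0 <- pmax(0.2, 2.8 - 2.2 * cos(2 * pi * (doy - 20) / 365) +
                    stats::rnorm(nd, 0, 0.3))

      # rain: wet-day process, dried down during P600 according to WD target
      rain <- ifelse(stats::runif(nd) < 0.35, stats::rgamma(nd, 2, 2 / 5), 0)
      sel <- which(period_of == "P600")
      p_dry <- min(max(0.25 + 0.035 * tgt["WD_P600"], 0.3), 0.95)
      rain[sel] <- ifelse(stats::runif(length(sel)) < p_dry, 0,
                          stats::rgamma(length(sel), 2, 2 / 4))

      # nitrogen supplies: two applications during bolting
      b_start <- periods[["B"]][1]
      supply_dates <- c(b_start + 5, b_start + 30)
      n_plus_total <- tgt["N_total"]
      reduction <- stats::runif(1, 80, 100)
      total <- if (regimes[i] == "N+") n_plus_total else max(n_plus_total - reduction, 20)
      amounts <- total * c(0.6, 0.4)
      # pin the dry-day count after each supply to the DAI target
      dai_n <- round(min(max(tgt["DAI"], 0), 10))
      for (sd_ in supply_dates) {
        win <- which(dates >= sd_ & dates <= sd_ + 9)
        rain[win] <- stats::rgamma(length(win), 2, 2 / 4) + RAIN_TRACE_MM
        if (dai_n > 0) rain[sample(win, dai_n)] <- 0
      }

      environments[[i]] <- env_record(ids[i], years[i],
                                      sprintf("L%02d", i), regimes[i],
                                      periods, tgt["WSC_MAX"])
      weather_rows[[i]] <- data.frame(
        environment_id = ids[i], date = dates, tmin = tmin, tmean = tmean,
        tmax = tmax, rain_mm = rain, et0_mm = et0, radiation_MJ_m2 = rad)
      supply_rows[[i]] <- data.frame(
        environment_id = ids[i], supply_date = supply_dates,
        n_amount_kg_ha = amounts)
      nni <- tgt["NNI"] + (if (regimes[i] == "N-") -0.12 else 0.03) +
        stats::rnorm(1, 0, 0.04)
      measured_rows[[i]] <- data.frame(
        environment_id = ids[i], nni = nni,
        adb = 6 + 2.5 * (nni - 1) + stats::rnorm(1, 0, 0.4),
        an = 120 * nni + stats::rnorm(1, 0, 6))
    }
    list(environments = environments,
         weather = do.call(rbind, weather_rows),
         management = list(supplies = do.call(rbind, supply_rows),
                           measured = do.call(rbind, measured_rows)),
         truth = list(
           envirotype = data.frame(environment_id = ids,
                                   envirotype = paste0("E", envirotype_of),
                                   stringsAsFactors = FALSE),
           templates = templates,
           env_targets = env_targets))
  })
}
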