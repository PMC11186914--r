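test_that("water balance follows the clamp recursion", {
  # linear drawdown: zero rain at 2 mm/day from a 10 mm bucket
  w <- flat_weather(8, rain = 0, et0 = 2)
  bal <- daily_water_balance(w, wsc_max = 10)
  expect_equal(bal$wsc, c(8, 6, 4, 2, 0, 0, 0, 0))
  expect_false(any(bal$leaching))

  # a 50 mm downpour on a 10 mm bucket leaches and caps
  w$rain_mm[3] <- 50
  bal <- daily_water_balance(w, wsc_max = 10)
  expect_true(bal$leaching[3])
  expect_equal(bal$wsc[3], 10)

  # 30-day mixed fixture equals a hand recursion
  w <- flat_weather(30)
  withr::with_seed(4, {
    w$rain_mm <- ifelse(runif(30) < 0.5, rgamma(30, 2, 0.3), 0)
    w$et0_mm <- runif(30, 0.5, 4)
  })
  bal <- daily_water_balance(w, 60)
  prev <- 60
  for (t in 1:30) {
    raw <- prev + w$rain_mm[t] - w$et0_mm[t]
    expect_identical(bal$leaching[t], raw > 60)
    prev <- min(max(raw, 0), 60)
    expect_equal(bal$wsc[t], prev)
  }
  # clamp invariant
  expect_true(all(bal$wsc >= 0 & bal$wsc <= 60))

  # gaps are rejected
  expect_error(daily_water_balance(w[-3, ], 60), "gaps")
})

test_that("period statistics honour the closed period interval", {
  env <- toy_env()
  w <- toy_season_weather(env)
  w$tmean[w$date >= env$periods$CW[1] & w$date <= env$periods$CW[2]] <- 5
  spec <- indicator_spec("TMN_CW", "CW", "mean", "tmean")
  expect_equal(period_statistic(w, spec, env), 5)

  # threshold count: exactly 3 hot days in FLO
  sel <- which(w$date >= env$periods$FLO[1] & w$date <= env$periods$FLO[2])
  w$tmax[sel] <- 20
  w$tmax[sel[c(2, 10, 17)]] <- c(26, 28, 30)
  ht <- indicator_spec("HT_FLO", "FLO", "count_above", "tmax", threshold = 25)
  expect_equal(period_statistic(w, ht, env), 3)

  # radiation sum equals hand arithmetic
  ssr <- indicator_spec("SSR_FLO", "FLO", "sum", "radiation_MJ_m2")
  expect_equal(period_statistic(w, ssr, env), sum(w$radiation_MJ_m2[sel]))

  # splitting the series and recombining leaves the statistic unchanged
  shuffled <- w[sample(nrow(w)), ]
  expect_equal(period_statistic(shuffled, ssr, env),
               period_statistic(w, ssr, env))

  # a period with no days in the series is rejected
  w2 <- w[w$date > env$periods$FLO[2], ]
  expect_error(period_statistic(w2, ht, env), "zero days")
})

test_that("per-supply water indicators scan the 10-day windows", {
  env <- toy_env()
  w <- flat_weather(40, start = as.Date("2014-03-01"), rain = 0, et0 = 1)
  bal <- daily_water_balance(w, 100)
  supply <- as.Date("2014-03-15")

  # bone-dry on both sides
  v <- per_supply_water_indicators(supply, w, bal, 100)
  expect_equal(unname(v[c("DBI", "DAI", "RF")]), c(10, 10, 0))

  # 5 mm every post-supply day
  w2 <- w; w2$rain_mm[w2$date >= supply & w2$date <= supply + 9] <- 5
  bal2 <- daily_water_balance(w2, 100)
  v2 <- per_supply_water_indicators(supply, w2, bal2, 100)
  expect_equal(unname(v2[c("DAI", "RF")]), c(0, 50))

  # mixed fixture: all five values equal a brute-force window scan
  withr::with_seed(8, {
    w3 <- flat_weather(40, start = as.Date("2014-03-01"))
    w3$rain_mm <- ifelse(runif(40) < 0.5, rgamma(40, 2, 0.2), 0)
    w3$et0_mm <- runif(40, 1, 4)
  })
  bal3 <- daily_water_balance(w3, 30)
  v3 <- per_supply_water_indicators(supply, w3, bal3, 30)
  i <- match(supply, w3$date)
  before_dry <- w3$rain_mm[(i - 10):(i - 1)] < 0.1
  runs <- rle(before_dry)
  expect_equal(unname(v3["DBI"]),
               if (any(runs$values)) max(runs$lengths[runs$values]) else 0)
  expect_equal(unname(v3["DAI"]), sum(w3$rain_mm[i:(i + 9)] < 0.1))
  expect_equal(unname(v3["RF"]), sum(w3$rain_mm[i:(i + 9)]))
  expect_equal(unname(v3["RO"]), sum(bal3$leaching[i:(i + 9)]))
  expect_equal(unname(v3["WSC_I"]), mean(bal3$wsc[(i - 3):(i + 9)]) / 30 * 100)

  # too close to the series edge
  expect_error(per_supply_water_indicators(w3$date[3], w3, bal3, 30), "10 days")
})

test_that("supply-weighted aggregation matches the stated weighting", {
  expect_equal(aggregate_supply_indicator(7.3, 120), 7.3)
  expect_equal(aggregate_supply_indicator(numeric(0), numeric(0)), 0)
  expect_equal(aggregate_supply_indicator(c(10, 20), c(60, 120)), 50 / 3)
  expect_error(aggregate_supply_indicator(c(1, 2), c(-1, 3)), ">= 0")
  # output bounded by the per-supply values; weights sum to 1
  withr::with_seed(11, {
    for (i in 1:20) {
      v <- runif(3, 0, 50); a <- runif(3, 0, 100)
      out <- aggregate_supply_indicator(v, a)
      expect_gte(out, min(v) - 1e-12)
      expect_lte(out, max(v) + 1e-12)
    }
  })
})

test_that("indicator matrix assembles per-environment values", {
  cfg <- sim_config(n_environments = 4, n_envirotypes = 2, n_accessions = 10,
                    n_snps = 200, seed = 9, replicates_per_env = 2)
  met <- generate_met(cfg)
  X <- build_indicator_matrix(met$environments, met$weather, met$management)
  expect_equal(nrow(X), 4)
  expect_equal(names(X)[1], "environment_id")
  expect_equal(ncol(X) - 1, 13)

  # element-wise oracle: recompute two indicators for one environment
  env <- met$environments[[2]]
  w <- met$weather[met$weather$environment_id == env$environment_id, ]
  bal <- daily_water_balance(w, env$wsc_max)
  series <- cbind(w, wsc = bal$wsc)
  expect_equal(X$TMN_CW[2], period_statistic(
    series, indicator_spec("TMN_CW", "CW", "mean", "tmean"), env))
  expect_equal(X$WD_P600[2], period_statistic(
    series, indicator_spec("WD_P600", "P600", "count_zero_wsc", "wsc"), env))
  sup <- met$management$supplies
  sup <- sup[sup$environment_id == env$environment_id, ]
  per <- sapply(sup$supply_date, function(d)
    per_supply_water_indicators(d, w, bal, env$wsc_max)["DAI"])
  expect_equal(X$DAI[2], aggregate_supply_indicator(per, sup$n_amount_kg_ha))
  expect_equal(X$N_total[2], sum(sup$n_amount_kg_ha))

  # an environment without an NNI measurement yields NA, not zero
  met$management$measured <- met$management$measured[-1, ]
  X2 <- build_indicator_matrix(met$environments, met$weather, met$management)
  expect_true(is.na(X2$NNI[1]))
  expect_false(is.na(X2$NNI[2]))

  expect_error(build_indicator_matrix(met$environments, met$weather,
                                      met$management, columns = c("TMN_CW", "BOGUS")),
               "BOGUS")
})

test_that("low-rank imputation completes without touching observed cells", {
  withr::with_seed(13, {
    u <- rnorm(12); v <- rnorm(6)
    M <- outer(u, v)                       # exact rank 1
  })
  colnames(M) <- paste0("I", 1:6)
  # complete matrix returned unchanged
  expect_equal(as.matrix(impute_indicator_matrix(M, 1)), M,
               ignore_attr = TRUE)
  # a single masked cell of a rank-1 matrix is recovered
  M2 <- M; M2[3, 4] <- NA
  imp <- impute_indicator_matrix(M2, 1)
  expect_equal(unname(imp[3, 4]), unname(M[3, 4]), tolerance = 1e-5)
  expect_equal(as.matrix(imp)[-3, ], M[-3, ], ignore_attr = TRUE)
  # constant column with one missing imputes to the constant
  M3 <- M; M3 <- cbind(M3, CONST = 7); M3[5, "CONST"] <- NA
  imp3 <- impute_indicator_matrix(M3, 1)
  expect_equal(unname(imp3[5, "CONST"]), 7, tolerance = 1e-8)
  # idempotence on a complete matrix
  expect_equal(impute_indicator_matrix(imp, 1), imp)
  # all-missing column rejected
  M4 <- M; M4[, 2] <- NA
  expect_error(impute_indicator_matrix(M4, 1), "observed")
})
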