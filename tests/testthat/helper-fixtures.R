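# Shared fixtures and independent oracles used across the suite.

# Adjusted Rand index between two labelings (independent of the package).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# A flat daily weather series of n days starting at `start`.
flat_weather <- function(n, start = as.Date("2014-01-01"), tmean = 5,
                         rain = 0, et0 = 2, rad = 8) {
  data.frame(date = start + seq_len(n) - 1,
             tmin = tmean - 4, tmean = tmean, tmax = tmean + 5,
             rain_mm = rep_len(rain, n), et0_mm = rep_len(et0, n),
             radiation_MJ_m2 = rep_len(rad, n))
}

# A minimal environment record whose periods tile `dates`.
toy_env <- function(id = "ENV1", year = 2014, wsc_max = 100) {
  periods <- list(
    "F"   = as.Date(c("2013-09-01", "2013-11-30")),
    CW    = as.Date(c("2013-12-01", "2014-02-15")),
    B     = as.Date(c("2014-02-16", "2014-03-31")),
    FLO   = as.Date(c("2014-04-01", "2014-04-30")),
    P300  = as.Date(c("2014-05-01", "2014-05-20")),
    P600  = as.Date(c("2014-05-21", "2014-06-15")),
    P1000 = as.Date(c("2014-06-16", "2014-07-10")))
  env_record(id, year, "LOC", "N+", periods, wsc_max)
}

# Full-season weather covering the toy_env periods.
toy_season_weather <- function(env, seed = 1) {
  withr::with_seed(seed, {
    dates <- seq(env$periods[["F"]][1], env$periods[["P1000"]][2], by = "day")
    n <- length(dates)
    data.frame(date = dates,
               tmin = rnorm(n, 3, 2), tmean = rnorm(n, 8, 3),
               tmax = rnorm(n, 13, 3),
               rain_mm = ifelse(runif(n) < 0.4, rgamma(n, 2, 0.5), 0),
               et0_mm = pmax(0.1, rnorm(n, 2, 0.5)),
               radiation_MJ_m2 = pmax(1, rnorm(n, 10, 2)))
  })
}

# Balanced one-way random-groups data: g groups x r observations.
one_way_data <- function(g = 6, r = 4, sigma_g = 2, sigma_e = 1, seed = 1) {
  withr::with_seed(seed, {
    eff <- rnorm(g, 0, sigma_g)
    data.frame(group = factor(rep(seq_len(g), each = r)),
               y = rep(eff, each = r) + rnorm(g * r, 0, sigma_e))
  })
}

# Independent REML profile log-likelihood for the one-way random-intercept
# model y = mu + group + e, parameterized by theta = sigma2_g / sigma2_e.
# Direct dense-matrix evaluation, no lme4.
one_way_reml_ll <- function(theta, y, group) {
  Z <- stats::model.matrix(~ 0 + group)
  n <- length(y)
  V <- diag(n) + theta * tcrossprod(Z)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / (n - 1)
  -0.5 * ((n - 1) * log(s2) + determinant(V)$modulus + log(det(XtVX)))
}

# Dense two-stage grid search for the REML-optimal variance ratio.
one_way_grid_ratio <- function(y, group, coarse = seq(0, 20, by = 0.01)) {
  ll <- vapply(coarse, one_way_reml_ll, 0, y = y, group = group)
  best <- coarse[which.max(ll)]
  fine <- seq(max(0, best - 0.02), best + 0.02, by = 1e-5)
  llf <- vapply(fine, one_way_reml_ll, 0, y = y, group = group)
  fine[which.max(llf)]
}

# Exact dense-matrix GLS association oracle: the null variance components
# are REML-estimated by direct optimization of the dense restricted
# likelihood (no eigendecomposition, no code shared with the scan), then
# every SNP is tested by an explicit GLS solve at those components.
dense_gls_scan_oracle <- function(y, D, K) {
  n <- length(y)
  X0 <- matrix(1, n, 1)
  reml_ll <- function(log_delta) {
    V <- K + exp(log_delta) * diag(n)
    Vi <- solve(V)
    XtViX <- t(X0) %*% Vi %*% X0
    beta <- solve(XtViX, t(X0) %*% Vi %*% y)
    r <- y - X0 %*% beta
    s2 <- drop(t(r) %*% Vi %*% r) / (n - 1)
    -0.5 * ((n - 1) * log(s2) + determinant(V)$modulus +
              determinant(XtViX)$modulus)
  }
  opt <- stats::optimize(reml_ll, interval = log(c(1e-5, 1e5)), maximum = TRUE)
  V <- K + exp(opt$maximum) * diag(n)
  Vi <- solve(V)
  apply(D, 2, function(x) {
    X <- cbind(1, x)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
    se <- sqrt(s2 * solve(XtViX)[2, 2])
    -log10(stats::pf((beta[2] / se)^2, 1, n - 2, lower.tail = FALSE))
  })
}

# Per-SNP full-REML association oracle: delta re-estimated for every SNP
# separately (unlike the scan's null-based delta).
full_reml_scan_oracle <- function(y, D, K) {
  eg <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  n <- length(y)
  ones_t <- drop(crossprod(U, rep(1, n)))
  apply(D, 2, function(x) {
    xt <- drop(crossprod(U, x))
    Xt <- cbind(ones_t, xt)
    ll <- function(log_delta) {
      delta <- exp(log_delta)
      w <- 1 / (lambda + delta)
      XtWX <- crossprod(Xt * w, Xt)
      beta <- solve(XtWX, crossprod(Xt * w, yt))
      r <- yt - Xt %*% beta
      s2 <- sum(w * r * r) / (n - 2)
      -0.5 * ((n - 2) * log(s2) + sum(log(lambda + delta)) +
                determinant(XtWX)$modulus)
    }
    opt <- stats::optimize(ll, interval = log(c(1e-5, 1e5)), maximum = TRUE)
    delta <- exp(opt$maximum)
    w <- 1 / (lambda + delta)
    XtWX <- crossprod(Xt * w, Xt)
    beta <- solve(XtWX, crossprod(Xt * w, yt))
    r <- yt - Xt %*% beta
    s2 <- sum(w * r * r) / (n - 2)
    se <- sqrt(s2 * solve(XtWX)[2, 2])
    -log10(stats::pf((beta[2] / se)^2, 1, n - 2, lower.tail = FALSE))
  })
}

# Small MET with planted QTL used by the GWAS-pipeline tests.
demo_qtl_specs <- function() {
  list(qtl_spec(1, 250 * 12500, 0.12, "stable"),
       qtl_spec(2, 250 * 12500, 0.20, "interactive", "E4"))
}

demo_config <- function(seed, qtls = demo_qtl_specs(), n_accessions = 150,
                        n_snps = 2000) {
  sim_config(n_environments = 16, n_envirotypes = 4,
             n_accessions = n_accessions, n_snps = n_snps, seed = seed,
             replicates_per_env = 2, qtl_specs = qtls)
}

# Run the multi-scale scan stack on a generated MET and return the
# classified region table plus the scans and threshold.
run_multiscale_scan <- function(cfg, trait = "sy") {
  met <- generate_met(cfg)
  G <- generate_genotypes(cfg)
  phen <- generate_phenotypes(G, met$truth$envirotype, cfg)$phenotypes
  phen$sn <- seed_number(phen$sy, phen$tsw)
  Gf <- impute_dosages(filter_snps(G))
  kin <- loco_kinships(Gf)
  thr <- significance_threshold(0.1, effective_tests(Gf))
  units <- scale_dispatch(unique(phen$environment), met$truth$envirotype)
  rows <- lapply(seq_len(nrow(units)), function(u) {
    sub <- phen[phen$environment %in% units$environments[[u]], ]
    b <- if (units$scale[u] == "environment") {
      blues_single_env(sub, trait)
    } else {
      blues_group(sub, trait, compute_components = FALSE)
    }
    sc <- lmm_scan(b$blues, Gf, kin)
    sc$scale <- units$scale[u]
    sc$group <- units$group[u]
    sc$trait <- trait
    sc
  })
  scans <- do.call(rbind, rows)
  list(met = met, scans = scans, threshold = thr,
       regions = classify_regions(merge_qtl_regions(scans, thr)))
}
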