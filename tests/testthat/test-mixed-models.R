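test_that("REML on balanced one-way data matches the ANOVA closed forms", {
  d <- one_way_data(g = 6, r = 4, sigma_g = 2, sigma_e = 1, seed = 31)
  fit <- reml_fit(d, model_spec("y", random = "group"))
  av <- stats::anova(stats::lm(y ~ group, d))
  ms_b <- av$`Mean Sq`[1]; ms_w <- av$`Mean Sq`[2]
  expect_equal(unname(fit$components["group"]), (ms_b - ms_w) / 4,
               tolerance = 1e-6)
  expect_equal(unname(fit$components["residual"]), ms_w, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("a null variance component is pinned at the zero boundary", {
  withr::with_seed(32, {
    d <- data.frame(group = factor(rep(1:8, each = 5)), y = rnorm(40))
    d$y <- d$y - stats::ave(d$y, d$group) + mean(d$y)  # no group signal at all
  })
  fit <- reml_fit(d, model_spec("y", random = "group"))
  expect_equal(unname(fit$components["group"]), 0, tolerance = 1e-8)
})

test_that("the REML optimum matches a dense profile grid search", {
  d <- one_way_data(g = 5, r = 3, sigma_g = 1.5, sigma_e = 1, seed = 33)
  fit <- reml_fit(d, model_spec("y", random = "group"))
  ratio_fit <- fit$components[["group"]] / fit$components[["residual"]]
  ratio_grid <- one_way_grid_ratio(d$y, d$group)
  expect_equal(ratio_fit, ratio_grid, tolerance = 1e-4)
})

test_that("confounded random terms are rejected with the pair named", {
  d <- one_way_data(g = 4, r = 3, seed = 34)
  d$copy <- factor(paste0("c", as.integer(d$group)))
  expect_error(reml_fit(d, model_spec("y", random = c("group", "copy"))),
               "group and copy are confounded")
})

test_that("REML components are recentring-invariant and scale equivariant", {
  d <- one_way_data(g = 6, r = 3, seed = 35)
  f1 <- reml_fit(d, model_spec("y", random = "group"))
  d2 <- d; d2$y <- d2$y + 100
  f2 <- reml_fit(d2, model_spec("y", random = "group"))
  expect_equal(f1$components, f2$components, tolerance = 1e-6)
  d3 <- d; d3$y <- 3 * d3$y
  f3 <- reml_fit(d3, model_spec("y", random = "group"))
  expect_equal(9 * f1$components, f3$components, tolerance = 1e-5)
})

test_that("single-environment BLUEs equal genotype means on balanced blocks", {
  withr::with_seed(36, {
    d <- expand.grid(genotype = paste0("g", 1:12), replicate = paste0("R", 1:3),
                     stringsAsFactors = FALSE)
    geff <- rnorm(12, 0, 2); reff <- rnorm(3, 0, 1)
    d$value <- 30 + geff[match(d$genotype, paste0("g", 1:12))] +
      reff[match(d$replicate, paste0("R", 1:3))] + rnorm(nrow(d), 0, 0.7)
  })
  b_auto <- blues_single_env(d)
  gm <- tapply(d$value, d$genotype, mean)
  expect_equal(b_auto$blues$blue, as.numeric(gm[b_auto$blues$genotype]),
               tolerance = 1e-8)
  # REML route agrees with the closed form on the balanced design
  b_reml <- blues_single_env(d, method = "reml")
  expect_equal(b_reml$blues$blue, b_auto$blues$blue, tolerance = 1e-6)
  expect_true(b_auto$h2 > 0 && b_auto$h2 <= 1)
})

test_that("unbalanced single-environment BLUEs match a GLS oracle", {
  withr::with_seed(37, {
    d <- expand.grid(genotype = paste0("g", 1:10), replicate = paste0("R", 1:3),
                     stringsAsFactors = FALSE)
    d$value <- 30 + rnorm(10, 0, 2)[match(d$genotype, paste0("g", 1:10))] +
      rnorm(3, 0, 1)[match(d$replicate, paste0("R", 1:3))] + rnorm(nrow(d), 0, 0.7)
    d <- d[-5, ]  # one missing plot
  })
  b <- blues_single_env(d)
  # explicit GLS at the fitted variance components
  fit <- lme4::lmer(value ~ 0 + genotype + (1 | replicate), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2r <- vc$vcov[vc$grp == "replicate"]; s2e <- vc$vcov[vc$grp == "Residual"]
  Z <- stats::model.matrix(~ 0 + replicate, d)
  V <- s2e * diag(nrow(d)) + s2r * tcrossprod(Z)
  X <- stats::model.matrix(~ 0 + genotype, d)
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, d$value))
  expect_equal(b$blues$blue, unname(drop(beta)), tolerance = 1e-6)
})

test_that("a genotype seen once gets its observation back as BLUE", {
  d <- data.frame(genotype = c("g1", "g2", "g3"), replicate = "R1",
                  value = c(28, 31, 35))
  b <- blues_single_env(d)
  expect_equal(b$blues$blue, c(28, 31, 35))
  expect_error(blues_single_env(d[1, ]), "one observation")
})

test_that("heritability formulas reproduce their arithmetic", {
  expect_equal(heritability_env(3, 2, 2), 0.75)
  expect_equal(heritability_env(5, 0, 3), 1)
  expect_equal(heritability_env(0, 2, 2), 0)
  expect_equal(heritability_group(2, 2, 8, e = 4, r = 2), 2 / 3.5)
  expect_error(heritability_env(0, 0, 2), "zero")
  # h2 bounded in [0, 1] for nonnegative components
  withr::with_seed(38, {
    for (i in 1:20) {
      h <- heritability_group(runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 5),
                              e = sample(2:10, 1), r = sample(1:4, 1))
      expect_gte(h, 0); expect_lte(h, 1)
    }
  })
})

test_that("group BLUEs equal grand means on complete balanced METs", {
  withr::with_seed(39, {
    d <- expand.grid(genotype = paste0("g", 1:15), environment = c("e1", "e2"),
                     replicate = paste0("R", 1:2), stringsAsFactors = FALSE)
    d$value <- 30 + rnorm(15, 0, 2)[match(d$genotype, paste0("g", 1:15))] +
      c(-3, 3)[match(d$environment, c("e1", "e2"))] + rnorm(nrow(d))
  })
  b <- blues_group(d, compute_components = FALSE)
  gm <- tapply(d$value, d$genotype, mean)
  expect_equal(b$blues$blue, as.numeric(gm[b$blues$genotype]), tolerance = 1e-8)
  # REML route gives the same adjusted means here
  b2 <- blues_group(d, method = "reml", compute_components = FALSE)
  expect_equal(sort(b2$blues$blue), sort(b$blues$blue), tolerance = 1e-6)
  expect_error(blues_group(d[d$environment == "e1", ]), "single environment")
})

test_that("group variance percentages recover the simulated profile", {
  targets <- model5_variance_targets(G = 0.247, E = 0.555, GxE = 0.058,
                                     R = 0.038, eps = 0.101,
                                     n_environments = 16, n_envirotypes = 4)
  cfg <- sim_config(n_environments = 16, n_envirotypes = 4, n_accessions = 100,
                    n_snps = 200, seed = 41, replicates_per_env = 2,
                    variance_targets = targets)
  met <- generate_met(cfg)
  ph <- generate_phenotypes(generate_genotypes(cfg), met$truth$envirotype, cfg)
  bg <- blues_group(ph$phenotypes, trait = "sy")
  expected <- c(G = 0.247, E = 0.555, GxE = 0.058, R = 0.038, eps = 0.101)
  expected <- expected / sum(expected)
  expect_equal(unname(bg$percentages / 100), unname(expected), tolerance = 0.05)
  expect_equal(unname(sum(bg$percentages)), 100, tolerance = 0.01)
  expect_true(bg$h2 > 0.9)  # a high-heritability MET at these targets
})

test_that("envirotype partition reports the derived environmental share", {
  cfg <- sim_config(n_environments = 16, n_envirotypes = 4, n_accessions = 80,
                    n_snps = 200, seed = 42, replicates_per_env = 2)
  met <- generate_met(cfg)
  ph <- generate_phenotypes(generate_genotypes(cfg), met$truth$envirotype, cfg)
  part <- envirotype_partition(ph$phenotypes, met$truth$envirotype, trait = "sy")
  targ <- 100 * met_variance_profile()
  expect_true(all(abs(part$percentages - targ) <= 5))
  expect_equal(unname(sum(part$percentages)), 100, tolerance = 0.01)
  expect_equal(part$env_share,
               100 * part$components[["En"]] /
                 (part$components[["En"]] + part$components[["EnxE"]]))
  # printed-profile arithmetic: En = 44.4, EnxE = 19.2 gives a ~70% share
  expect_equal(round(100 * 44.4 / (44.4 + 19.2)), 70)
})

test_that("dominant envirotype variance drives the share toward one", {
  targets <- c(G = 0.2, En = 0.55, EnxE = 0.005, GxEn = 0.01, GxEnxE = 0.05,
               R = 0.035, eps = 0.15)
  cfg <- sim_config(n_environments = 12, n_envirotypes = 4, n_accessions = 50,
                    n_snps = 200, seed = 43, replicates_per_env = 2,
                    variance_targets = targets)
  met <- generate_met(cfg)
  ph <- generate_phenotypes(generate_genotypes(cfg), met$truth$envirotype, cfg)
  part <- envirotype_partition(ph$phenotypes, met$truth$envirotype, trait = "sy")
  expect_gte(part$env_share, 90)
})

test_that("QTL-by-environment partition separates null and loaded markers", {
  cfg <- sim_config(n_environments = 8, n_envirotypes = 4, n_accessions = 80,
                    n_snps = 200, seed = 44, replicates_per_env = 2)
  met <- generate_met(cfg)
  G <- generate_genotypes(cfg)
  ph <- generate_phenotypes(G, met$truth$envirotype, cfg)
  d <- ph$phenotypes
  # markers independent of the phenotype: interaction share stays small
  shares <- sapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      mk <- sample(0:2, 80, replace = TRUE)
    })
    names(mk) <- sprintf("A%03d", 1:80)
    qtl_by_env_partition(d, mk, trait = "sy")$percentages[["QTLxTrial"]]
  })
  expect_lte(max(shares), 2)

  # a marker constructed to carry the whole genotype-by-environment signal
  withr::with_seed(45, {
    mk <- sample(0:2, 80, replace = TRUE)
    names(mk) <- sprintf("A%03d", 1:80)
    env_eff <- rnorm(8, 0, 4)
    names(env_eff) <- unique(d$environment)
    d2 <- d
    d2$sy <- d2$sy + mk[d2$genotype] * env_eff[d2$environment]
  })
  part <- qtl_by_env_partition(d2, mk, trait = "sy")
  expect_gte(part$percentages[["QTLxTrial"]], 25)

  expect_error(qtl_by_env_partition(d[d$environment == d$environment[1], ],
                                    mk, trait = "sy"), "single environment")
  expect_error(qtl_by_env_partition(d, rep(1, 80), trait = "sy"), "monomorphic")
})

test_that("seed number follows the printed formula", {
  expect_equal(seed_number(35, 5), 700000)
  expect_equal(seed_number(0, 4.2), 0)
  expect_equal(seed_number(30.35, 4.34), 30.35 * 100000 / 4.34)
  expect_error(seed_number(30, 0), "> 0")
})
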