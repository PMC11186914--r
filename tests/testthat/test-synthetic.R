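test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_environments = 0), "n_environments")
  expect_error(sim_config(n_envirotypes = 9, n_environments = 4), "n_envirotypes")
  expect_error(sim_config(maf_range = c(0.3, 0.6)), "maf_range")
  expect_error(sim_config(ld_block_size = 5000), "ld_block_size")
  bad <- met_variance_profile(); bad["G"] <- bad["G"] + 0.01
  expect_error(sim_config(variance_targets = bad), "sum to 1")
  expect_error(qtl_spec(1, 100, 1.2, "stable"), "effect_size")
  expect_error(qtl_spec(1, 100, 0.1, "interactive"), "target_envirotype")
})

test_that("the MET generator is a pure function of configuration and seed", {
  cfg <- sim_config(n_environments = 8, n_envirotypes = 2, n_accessions = 20,
                    n_snps = 200, seed = 71, replicates_per_env = 2)
  a <- generate_met(cfg)
  b <- generate_met(cfg)
  expect_identical(a, b)
  g1 <- generate_genotypes(cfg)
  g2 <- generate_genotypes(cfg)
  expect_identical(g1, g2)
  p1 <- generate_phenotypes(g1, a$truth$envirotype, cfg)
  p2 <- generate_phenotypes(g2, b$truth$envirotype, cfg)
  expect_identical(p1, p2)
  # a different seed changes the data
  cfg2 <- sim_config(n_environments = 8, n_envirotypes = 2, n_accessions = 20,
                     n_snps = 200, seed = 72, replicates_per_env = 2)
  expect_false(identical(generate_met(cfg2)$weather, a$weather))
})

test_that("the MET design respects counts, regimes and period ordering", {
  cfg <- sim_config(n_environments = 8, n_envirotypes = 2, n_accessions = 20,
                    n_snps = 200, seed = 73, replicates_per_env = 2)
  met <- generate_met(cfg)
  expect_length(met$environments, 8)
  expect_equal(length(unique(met$truth$envirotype$envirotype)), 2)
  # N- environments receive 80-100 kg/ha less than their envirotype's N+ target
  totals <- tapply(met$management$supplies$n_amount_kg_ha,
                   met$management$supplies$environment_id, sum)
  ids <- met$truth$envirotype$environment_id
  regimes <- vapply(met$environments, `[[`, "", "n_regime")
  tgt <- met$truth$env_targets[, "N_total"]
  for (i in seq_along(ids)) {
    if (regimes[i] == "N-") {
      red <- tgt[i] - totals[ids[i]]
      expect_gte(red, 80 - 1e-9); expect_lte(red, 100 + 1e-9)
    } else {
      expect_equal(unname(totals[ids[i]]), unname(tgt[i]))
    }
  }
  # period boundaries ordered and non-overlapping (enforced by env_record)
  for (e in met$environments) {
    starts <- vapply(CROP_PERIODS, function(p) as.numeric(e$periods[[p]][1]), 0)
    expect_true(all(diff(starts) > 0))
  }
  # weather covers every environment daily without gaps
  for (e in met$environments) {
    w <- met$weather[met$weather$environment_id == e$environment_id, ]
    expect_equal(as.numeric(diff(w$date)), rep(1, nrow(w) - 1))
  }
})

test_that("genotypes are inbred, block-structured and bounded in frequency", {
  cfg <- sim_config(n_environments = 4, n_envirotypes = 2, n_accessions = 200,
                    n_snps = 400, n_chromosomes = 2, seed = 1,
                    missing_rate = 0, maf_range = c(0.3, 0.5))
  G <- generate_genotypes(cfg)
  expect_false(anyNA(G$dosages))
  # heterozygote rate of line material stays at or below 2%
  expect_lte(mean(G$dosages == 1), 0.02)
  # realized MAF never collapses far below the configured range
  expect_true(all(snp_maf(G) >= 0.2))
  # within-block LD high, adjacent-block LD low (seed 1, default blocks)
  cfg2 <- sim_config(n_environments = 4, n_envirotypes = 2, n_accessions = 200,
                     n_snps = 400, n_chromosomes = 2, seed = 1,
                     missing_rate = 0)
  G2 <- generate_genotypes(cfg2)
  blk <- 20
  r2_within <- r2_between <- c()
  for (b in 0:4) {
    cols <- b * blk + seq_len(blk)
    C <- stats::cor(G2$dosages[, cols])^2
    r2_within <- c(r2_within, mean(C[upper.tri(C)]))
    C2 <- stats::cor(G2$dosages[, cols], G2$dosages[, cols + blk])^2
    r2_between <- c(r2_between, mean(C2))
  }
  expect_gte(mean(r2_within), 0.5)
  expect_lte(mean(r2_between), 0.1)
  # missingness honoured
  cfg3 <- sim_config(n_environments = 4, n_envirotypes = 2, n_accessions = 50,
                     n_snps = 200, seed = 2, missing_rate = 0.05)
  G3 <- generate_genotypes(cfg3)
  expect_gt(mean(is.na(G3$dosages)), 0.03)
  expect_lt(mean(is.na(G3$dosages)), 0.07)
})

test_that("an all-noise variance profile yields a null genotypic variance", {
  targets <- c(G = 0, En = 0, EnxE = 0, GxEn = 0, GxEnxE = 0, R = 0, eps = 1)
  cfg <- sim_config(n_environments = 6, n_envirotypes = 2, n_accessions = 40,
                    n_snps = 200, seed = 74, replicates_per_env = 2,
                    variance_targets = targets)
  met <- generate_met(cfg)
  ph <- generate_phenotypes(generate_genotypes(cfg), met$truth$envirotype, cfg)
  fit <- reml_fit(ph$phenotypes,
                  model_spec("sy", random = c("genotype", "environment")))
  expect_lt(fit$components[["genotype"]] / sum(fit$components), 0.02)
})

test_that("realized variance fractions stay on the configured targets", {
  cfg <- sim_config(n_environments = 16, n_envirotypes = 4, n_accessions = 80,
                    n_snps = 200, seed = 75, replicates_per_env = 2)
  met <- generate_met(cfg)
  ph <- generate_phenotypes(generate_genotypes(cfg), met$truth$envirotype, cfg)
  expect_equal(unname(ph$truth$realized_fractions),
               unname(met_variance_profile()), tolerance = 1e-6)
})

test_that("a planted stable QTL tops the MET-scale scan", {
  cfg <- demo_config(seed = 1)
  met <- generate_met(cfg)
  G <- generate_genotypes(cfg)
  ph <- generate_phenotypes(G, met$truth$envirotype, cfg)
  b <- blues_group(ph$phenotypes, trait = "sy", compute_components = FALSE)
  Gf <- impute_dosages(filter_snps(G))
  sc <- lmm_scan(b$blues, Gf, loco_kinships(Gf))
  peak <- sc[which.max(sc$neglog10p), ]
  causal <- ph$truth$qtl[[1]]
  expect_equal(peak$chromosome, causal$chromosome)
  # peak falls inside the causal haplotype block
  expect_lt(abs(peak$position - causal$position), 20 * 12500)
})

test_that("QTL positions must exist in the simulated map", {
  cfg <- sim_config(n_environments = 4, n_envirotypes = 2, n_accessions = 30,
                    n_snps = 200, seed = 76, replicates_per_env = 2,
                    qtl_specs = list(qtl_spec(1, 999, 0.1, "stable")))
  met <- generate_met(cfg)
  expect_error(generate_phenotypes(generate_genotypes(cfg),
                                   met$truth$envirotype, cfg),
               "absent from the map")
})

test_that("divergent populations behave at the no-differentiation limit", {
  ps <- generate_divergent_populations(40, 40, 1500, 0.001, seed = 1)
  D <- rbind(ps$pop1$dosages, ps$pop2$dosages)
  sp <- data.frame(accession_id = rownames(D),
                   population = rep(c("P1", "P2"), each = 40))
  fst <- windowed_mean_fst(geno_matrix(D, ps$pop1$map), sp)
  expect_lt(abs(fst$genome$mean_fst), 0.01)
  # seeded determinism
  ps2 <- generate_divergent_populations(40, 40, 1500, 0.001, seed = 1)
  expect_identical(ps, ps2)
  expect_error(generate_divergent_populations(40, 40, 100, 1.2), "F")
})
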