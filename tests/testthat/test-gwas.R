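toy_geno <- function(D, chrom = NULL, pos = NULL) {
  m <- ncol(D)
  if (is.null(rownames(D))) rownames(D) <- sprintf("A%03d", seq_len(nrow(D)))
  map <- data.frame(snp_id = paste0("S", seq_len(m)),
                    chromosome = if (is.null(chrom)) rep(1L, m) else chrom,
                    position = if (is.null(pos)) seq_len(m) * 1000 else pos)
  colnames(D) <- map$snp_id
  geno_matrix(D, map)
}

test_that("SNP filtering applies the MAF and missingness thresholds", {
  # hand fixture: 6 SNPs with known fates across 20 accessions
  D <- cbind(
    ok1  = rep(c(0, 2), 10),             # MAF 0.5
    rare = c(2, rep(0, 19)),             # MAF 0.05, kept at default
    mono = c(rep(0, 19), 1),             # MAF 0.025 boundary (>= kept)
    low  = c(1, rep(0, 19)),             # MAF 0.025 boundary too
    gone = rep(0, 20),                   # MAF 0 -> removed
    holey = c(rep(NA, 3), rep(c(0, 2), 8), 0)  # 15% missing -> removed
  )
  G <- toy_geno(D)
  f <- filter_snps(G)
  expect_setequal(colnames(f$dosages), c("S1", "S2", "S3", "S4"))
  # a stricter MAF cut removes the rare SNPs as well
  f2 <- filter_snps(G, maf_min = 0.10)
  expect_equal(ncol(f2$dosages), 1)
  expect_error(filter_snps(G, maf_min = 0.6), "no SNP passes")
})

test_that("mean imputation fills missing dosages and preserves column means", {
  D <- cbind(a = c(0, 2, 2, NA), b = c(0, 1, 2, 1))
  G <- toy_geno(D)
  imp <- impute_dosages(G)
  expect_equal(unname(imp$dosages[4, 1]), 4 / 3)
  expect_equal(colMeans(imp$dosages), colMeans(D, na.rm = TRUE),
               ignore_attr = TRUE)
  # no missing -> identity
  G2 <- toy_geno(cbind(a = c(0, 2, 2, 0), b = c(0, 1, 2, 1)))
  expect_identical(impute_dosages(G2)$dosages, G2$dosages)
})

test_that("kinship matches its standardized cross-product definition", {
  D <- cbind(s1 = c(0, 2, 2), s2 = c(1, 1, 2))
  G <- toy_geno(D)
  K <- kinship(G)
  # hand arithmetic
  p <- colMeans(D) / 2
  Z <- sweep(D, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(K, tcrossprod(Z) / 2, ignore_attr = TRUE)
  # identical accessions give identical rows
  D2 <- rbind(D, D[2, ])
  K2 <- kinship(toy_geno(D2))
  expect_equal(K2[2, ], K2[4, ], ignore_attr = TRUE)
  # PSD on random fixtures
  withr::with_seed(51, {
    Dr <- matrix(sample(0:2, 30 * 20, replace = TRUE), 30, 20)
  })
  Kr <- kinship(toy_geno(Dr))
  expect_equal(Kr, t(Kr))
  expect_gte(min(eigen(Kr, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # monomorphic SNPs are skipped with a warning
  expect_warning(kinship(toy_geno(cbind(Dr, mono = 0))), "monomorphic")
})

test_that("LOCO kinships exclude the focal chromosome and recombine", {
  withr::with_seed(52, {
    D <- matrix(sample(0:2, 40 * 30, replace = TRUE), 40, 30)
  })
  chrom <- rep(1:3, each = 10)
  G <- toy_geno(D, chrom = chrom, pos = rep(1:10 * 1000, 3))
  ks <- loco_kinships(G)
  # marker-count-weighted average of LOCO kinships reconstructs the genome
  M <- ncol(D)
  recon <- Reduce(`+`, lapply(names(ks$loco), function(ch)
    ks$loco[[ch]] * ks$n_snps[[ch]]))
  expect_equal(recon / (2 * M), ks$genome, tolerance = 1e-8)
  # two-chromosome case: leaving chromosome 1 out IS chromosome 2
  G2 <- toy_geno(D[, 1:20], chrom = rep(1:2, each = 10),
                 pos = rep(1:10 * 1000, 2))
  ks2 <- loco_kinships(G2)
  expect_equal(ks2$loco[["1"]], kinship(G2, 11:20))
  expect_error(loco_kinships(toy_geno(D, chrom = rep(1, 30))), "2 chromosomes")
})

test_that("the scan reduces to simple regression under an identity kinship", {
  withr::with_seed(53, {
    D <- matrix(sample(0:2, 60 * 25, replace = TRUE), 60, 25)
    rownames(D) <- sprintf("A%03d", 1:60)
    y <- rnorm(60) + 0.8 * D[, 7]
  })
  G <- toy_geno(D)
  blues <- data.frame(genotype = rownames(D), blue = y)
  K <- diag(60); dimnames(K) <- list(rownames(D), rownames(D))
  sc <- lmm_scan(blues, G, K)
  for (j in c(1, 7, 20)) {
    ols <- summary(stats::lm(y ~ D[, j]))$coefficients
    expect_equal(sc$beta[j], ols[2, 1], tolerance = 1e-6)
    expect_equal(10^-sc$neglog10p[j], ols[2, 4], tolerance = 1e-6)
  }
})

test_that("the spectral scan matches an independent dense GLS oracle", {
  cfg <- sim_config(n_environments = 4, n_envirotypes = 2, n_accessions = 50,
                    n_snps = 200, n_chromosomes = 2, ld_block_size = 5,
                    seed = 54, missing_rate = 0)
  G <- generate_genotypes(cfg)
  ks <- loco_kinships(G)
  withr::with_seed(54, {
    # phenotype drawn from the mixed model itself (kinship-shaped
    # polygenic part plus iid noise)
    L <- t(chol(ks$genome + diag(1e-6, 50)))
    y <- drop(L %*% rnorm(50)) + rnorm(50, 0, 1)
  })
  blues <- data.frame(genotype = rownames(G$dosages), blue = y)
  sc <- lmm_scan(blues, G, ks)
  for (ch in 1:2) {
    idx <- which(G$map$chromosome == ch)
    oracle <- dense_gls_scan_oracle(y, G$dosages[, idx, drop = FALSE],
                                    ks$loco[[as.character(ch)]])
    expect_lt(max(abs(sc$neglog10p[idx] - oracle)), 0.2)
  }
})

test_that("the null-delta approximation stays close to per-SNP REML", {
  cfg <- sim_config(n_environments = 4, n_envirotypes = 2, n_accessions = 50,
                    n_snps = 200, n_chromosomes = 2, ld_block_size = 5,
                    seed = 54, missing_rate = 0)
  G <- generate_genotypes(cfg)
  ks <- loco_kinships(G)
  withr::with_seed(54, {
    L <- t(chol(ks$genome + diag(1e-6, 50)))
    y <- drop(L %*% rnorm(50)) + rnorm(50, 0, 1)
  })
  blues <- data.frame(genotype = rownames(G$dosages), blue = y)
  sc <- lmm_scan(blues, G, ks)
  diffs <- unlist(lapply(1:2, function(ch) {
    idx <- which(G$map$chromosome == ch)
    abs(sc$neglog10p[idx] -
          full_reml_scan_oracle(y, G$dosages[, idx, drop = FALSE],
                                ks$loco[[as.character(ch)]]))
  }))
  # re-estimating delta per SNP moves individual p-values a little on a
  # 50-genotype panel; the bulk of the scan is unaffected
  expect_lte(median(diffs), 0.05)
})

test_that("effective test counts follow the block eigenvalue rule", {
  withr::with_seed(55, {
    base <- sample(0:2, 40, replace = TRUE)
  })
  # all SNPs identical within the (single) block
  G_same <- toy_geno(matrix(base, 40, 8))
  expect_equal(effective_tests(G_same), 1L)
  # exactly orthogonal columns require every eigenvalue at C = 0.995
  Q <- qr.Q(qr(scale(matrix(rnorm(400), 40, 10), scale = FALSE)))
  G_orth <- toy_geno((Q - min(Q)) / (max(Q) - min(Q)) * 2)
  expect_equal(effective_tests(G_orth), 10L)
  # 5 identical pairs -> 5 effective tests
  withr::with_seed(56, {
    P <- matrix(sample(0:2, 40 * 5, replace = TRUE), 40, 5)
  })
  G_pairs <- toy_geno(P[, rep(1:5, each = 2)])
  expect_equal(effective_tests(G_pairs), 5L)
  # M_eff never exceeds M and shrinks when duplicates are appended
  withr::with_seed(57, {
    D <- matrix(sample(0:2, 40 * 12, replace = TRUE), 40, 12)
  })
  m1 <- effective_tests(toy_geno(D))
  expect_lte(m1, 12L)
  m2 <- effective_tests(toy_geno(cbind(D, D)[, rep(1:12, each = 2)]))
  expect_lte(m2, m1)
  expect_error(effective_tests(toy_geno(cbind(D, mono = 0L))), "zero-variance")
})

test_that("orthogonal columns in effective_tests really are orthogonal", {
  # guards the construction used above
  Q <- qr.Q(qr(scale(matrix(rnorm(400), 40, 10), scale = FALSE)))
  expect_equal(crossprod(Q), diag(10), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the significance threshold is the corrected Bonferroni bound", {
  expect_equal(significance_threshold(0.1, 19886), 5.30, tolerance = 5e-3)
  expect_equal(significance_threshold(1, 1), 0)
  expect_equal(significance_threshold(0.05, 1000), 4.301, tolerance = 5e-4)
  expect_error(significance_threshold(0, 10), "0, 1")
  expect_error(significance_threshold(0.1, 0.5), ">= 1")
})

make_scan_df <- function(positions, neglog10p, scale, group, chrom = 1,
                         trait = "sy") {
  data.frame(snp_id = paste0("S", seq_along(positions)), chromosome = chrom,
             position = positions, neglog10p = neglog10p, scale = scale,
             group = group, trait = trait)
}

test_that("region merging chains significant SNPs and unions scans", {
  # two significant SNPs 10 kb apart form one region
  s1 <- make_scan_df(c(1e6, 1.01e6, 5e6), c(6, 7, 1), "MET", "MET")
  r1 <- merge_qtl_regions(s1, t = 5)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start, 1e6); expect_equal(r1$end, 1.01e6)
  expect_equal(r1$peak_snp, "S2")

  # different chromosomes stay distinct
  s2 <- rbind(make_scan_df(1e6, 6, "MET", "MET", chrom = 1),
              make_scan_df(1e6, 6, "MET", "MET", chrom = 2))
  expect_equal(nrow(merge_qtl_regions(s2, t = 5)), 2)

  # overlapping intervals from different scales merge with 2 detections
  sa <- make_scan_df(c(1.0e6, 1.4e6), c(6, 6), "envirotype", "E1")
  sb <- make_scan_df(c(1.2e6, 2.0e6), c(6, 8), "environment", "env7")
  r3 <- merge_qtl_regions(list(sa, sb), t = 5, gap_bp = 900000)
  expect_equal(nrow(r3), 1)
  expect_equal(c(r3$start, r3$end), c(1.0e6, 2.0e6))
  expect_equal(r3$n_detections, 2)

  # merging is idempotent and independent of scan order
  r3b <- merge_qtl_regions(list(sb, sa), t = 5, gap_bp = 900000)
  expect_equal(r3b[, c("start", "end", "n_detections")],
               r3[, c("start", "end", "n_detections")])

  # empty result allowed
  expect_equal(nrow(merge_qtl_regions(s1, t = 99)), 0)
})

test_that("stability classification follows the multi-scale detection rule", {
  # MET + two envirotypes + environments -> stable
  det_stable <- data.frame(
    scale = c("MET", "envirotype", "envirotype", rep("environment", 6)),
    group = c("MET", "EA", "ED", paste0("env", 1:6)))
  expect_equal(classify_stability(det_stable), "stable")
  # two envirotypes without MET is still stable
  expect_equal(classify_stability(data.frame(scale = c("envirotype", "envirotype"),
                                             group = c("EA", "EB"))), "stable")
  # one envirotype and no MET -> interactive
  det_int <- data.frame(scale = c("envirotype", "environment", "environment"),
                        group = c("ED", "LR15_N+", "Pre14_N-"))
  expect_equal(classify_stability(det_int), "interactive")
  # environment only -> environment-specific
  expect_equal(classify_stability(data.frame(scale = "environment",
                                             group = "Pre15_N+")),
               "environment-specific")
  expect_error(classify_stability(data.frame(scale = character(),
                                             group = character())), "non-empty")
})
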