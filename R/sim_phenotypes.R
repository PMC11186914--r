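# Rescale an (already projected / centred) effect so that its mean square
# per model degree of freedom equals target_var exactly; this is the
# quantity a variance-component estimator recovers for the corresponding
# term, so realized components land on their targets up to estimation
# noise. Zero target gives zeros.
scale_to_var <- function(x, target_var, df = length(x) - 1L) {
  if (target_var <= 0 || df < 1) return(x * 0)
  ss <- sum(x^2)
  if (ss == 0) stop("cannot scale a null component to a positive variance")
  x * sqrt(target_var * df / ss)
}

double_center <- function(M) {
  M - outer(rowMeans(M), rep(1, ncol(M))) -
    outer(rep(1, nrow(M)), colMeans(M)) + mean(M)
}

#' Generate plot-level phenotypes with a planted variance structure
#'
#' Builds seed yield as the sum of independent components - genotype
#' (polygenic plus stable QTL), envirotype, environment within envirotype,
#' genotype x envirotype (interactive QTL plus noise), genotype x
#' environment, replicate within environment and residual - each rescaled
#' so its realized sample variance matches the configured fraction of the
#' total variance. Stable QTL contribute `effect_size` of the genotypic
#' variance everywhere; interactive QTL act only inside their target
#' envirotype, where they carry `effect_size` of the genotypic variance.
#' Thousand-seed weight is drawn lognormal around 4.5 g so that the seed
#' number trait `SN = SY * 100000 / TSW` is exercised.
#'
#' @param genotypes a [geno_matrix()] from [generate_genotypes()] (missing
#'   dosages are mean-imputed for effect construction).
#' @param envirotype_assignment data frame `environment_id`, `envirotype`
#'   (the generator truth from [generate_met()]).
#' @param config a [sim_config()].
#' @return list with `phenotypes` (data frame `genotype`, `environment`,
#'   `replicate`, `sy`, `tsw`) and `truth` (genotypic values, per-QTL
#'   effects, realized variance fractions).
#' @export
generate_phenotypes <- function(genotypes, envirotype_assignment, config) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 303L), {
    acc <- rownames(genotypes$dosages)
    n_acc <- length(acc)
    env_ids <- envirotype_assignment$environment_id
    env_of <- envirotype_assignment$envirotype
    if (anyNA(env_of) || !length(env_ids))
      stop_field("envirotype_assignment", "environments must carry envirotype labels")
    n_env <- length(env_ids)
    etypes <- sort(unique(env_of))
    k <- length(etypes)
    reps <- config$replicates_per_env
    tv <- config$total_variance
    tg <- config$variance_targets * tv

    D <- impute_dosages(genotypes)$dosages

    # --- genotype main effects: polygenic + stable QTL ---------------------
    snp_at <- function(q) {
      hit <- which(genotypes$map$chromosome == q$chromosome &
                     genotypes$map$position == q$position)
      if (!length(hit))
        stop_field("qtl_specs", sprintf(
          "QTL position %d on chromosome %d absent from the map",
          q$position, q$chromosome))
      hit
    }
    stable <- Filter(function(q) q$mode == "stable", config$qtl_specs)
    interactive <- Filter(function(q) q$mode == "interactive", config$qtl_specs)
    es_stable <- sum(vapply(stable, `[[`, 0, "effect_size"))
    if (es_stable >= 1)
      stop_field("qtl_specs", "stable effect sizes must sum to < 1")
    std <- function(v) {
      s <- stats::sd(v)
      if (s == 0) stop_field("qtl_specs", "QTL SNP is monomorphic in the panel")
      (v - mean(v)) / s
    }
    qtl_truth <- list()
    stable_x <- matrix(0, n_acc, 0)
    for (q in stable) {
      j <- snp_at(q)
      stable_x <- cbind(stable_x, std(D[, j]))
      qtl_truth[[length(qtl_truth) + 1L]] <- c(q, list(snp_id = genotypes$map$snp_id[j]))
    }
    poly <- stats::rnorm(n_acc)
    if (ncol(stable_x)) {
      # orthogonalize the polygenic background against the planted QTL so
      # each stable QTL explains exactly its specified share of Var(G)
      poly <- stats::lm.fit(cbind(1, stable_x), poly)$residuals
    }
    g_raw <- sqrt(1 - es_stable) * std(poly)
    for (i in seq_along(stable))
      g_raw <- g_raw + sqrt(stable[[i]]$effect_size) * stable_x[, i]
    g <- scale_to_var(g_raw - mean(g_raw), tg[["G"]], n_acc - 1L)

    # --- environmental terms ----------------------------------------------
    en_raw <- stats::rnorm(k)
    en_lv <- scale_to_var(en_raw - mean(en_raw), tg[["En"]], k - 1L)
    names(en_lv) <- etypes
    ene_raw <- stats::rnorm(n_env)
    ene_raw <- ene_raw - stats::ave(ene_raw, env_of)      # nested: centred per envirotype
    ene_lv <- scale_to_var(ene_raw, tg[["EnxE"]], n_env - k)
    names(ene_lv) <- env_ids

    # --- genotype x envirotype: interactive QTL plus noise -----------------
    Q <- matrix(0, n_acc, k, dimnames = list(acc, etypes))
    vg <- tg[["G"]]
    df_gxen <- (n_acc - 1L) * (k - 1L)
    for (q in interactive) {
      j <- snp_at(q)
      if (!q$target_envirotype %in% etypes)
        stop_field("qtl_specs", sprintf("target envirotype %s absent from assignment",
                                        q$target_envirotype))
      Q[, q$target_envirotype] <- Q[, q$target_envirotype] +
        sqrt(q$effect_size * vg) * std(D[, j])
      qtl_truth[[length(qtl_truth) + 1L]] <- c(q, list(snp_id = genotypes$map$snp_id[j]))
    }
    var_q <- sum(Q^2) / df_gxen
    noise_var <- max(tg[["GxEn"]] - var_q, 0)
    GxEn <- Q + scale_to_var(double_center(
      matrix(stats::rnorm(n_acc * k), n_acc, k)), noise_var, df_gxen)

    # --- genotype x environment (within envirotype) ------------------------
    GxE <- matrix(stats::rnorm(n_acc * n_env), n_acc, n_env,
                  dimnames = list(acc, env_ids))
    # project onto the nested-interaction subspace: double-centre each
    # envirotype's accession x environment block (orthogonal to G, En,
    # En(E) and G x En)
    for (et in etypes) {
      cols <- which(env_of == et)
      if (length(cols) > 1) {
        GxE[, cols] <- double_center(GxE[, cols, drop = FALSE])
      } else {
        GxE[, cols] <- 0
      }
    }
    GxE <- scale_to_var(GxE, tg[["GxEnxE"]], (n_acc - 1L) * (n_env - k))

    # --- replicate and residual -------------------------------------------
    Rm <- matrix(stats::rnorm(n_env * reps), n_env, reps,
                 dimnames = list(env_ids, NULL))
    if (reps > 1) Rm <- Rm - rowMeans(Rm)
    Rm <- scale_to_var(Rm, tg[["R"]], n_env * (reps - 1L))

    plots <- expand.grid(genotype = acc, environment = env_ids,
                         replicate = paste0("R", seq_len(reps)),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ia <- match(plots$genotype, acc)
    ie <- match(plots$environment, env_ids)
    it <- match(env_of[ie], etypes)
    ir <- as.integer(sub("^R", "", plots$replicate))
    e_raw <- stats::rnorm(nrow(plots))
    eps <- scale_to_var(e_raw - mean(e_raw), tg[["eps"]], nrow(plots) - 1L)

    comp <- cbind(G = g[ia], En = en_lv[it], EnxE = ene_lv[ie],
                  GxEn = GxEn[cbind(ia, it)], GxEnxE = GxE[cbind(ia, ie)],
                  R = Rm[cbind(ie, ir)], eps = eps)
    plots$sy <- config$mean_sy + rowSums(comp)
    plots$tsw <- stats::rlnorm(nrow(plots), log(4.5), 0.05)

    # realized per-term variances on the mean-square-per-df scale the
    # variance-component estimators recover
    dfs <- c(G = n_acc - 1, En = k - 1, EnxE = n_env - k,
             GxEn = df_gxen, GxEnxE = (n_acc - 1) * (n_env - k),
             R = n_env * (reps - 1), eps = nrow(plots) - 1)
    quad <- c(G = sum(g^2), En = sum(en_lv^2), EnxE = sum(ene_lv^2),
              GxEn = sum(GxEn^2), GxEnxE = sum(GxE^2), R = sum(Rm^2),
              eps = sum(eps^2))
    realized <- ifelse(dfs > 0, quad / pmax(dfs, 1), 0)
    realized <- realized / sum(realized)
    list(phenotypes = plots,
         truth = list(genotypic_value = structure(g, names = acc),
                      qtl = qtl_truth,
                      realized_fractions = realized))
  })
}

#' Generate two populations differentiated at a target F_ST
#'
#' Sub-population allele frequencies are drawn from a Balding-Nichols
#' distribution around shared ancestral frequencies: for ancestral
#' frequency `p` and differentiation `F`, each population's frequency is
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`. Diploid genotypes are then
#' sampled in Hardy-Weinberg proportions within populations.
#'
#' @param n1,n2 diploid sample sizes of the two populations.
#' @param n_snps number of independent SNPs (single chromosome, 1 kb
#'   spacing).
#' @param F differentiation parameter in (0, 1).
#' @param seed RNG seed.
#' @return list of two [geno_matrix()] objects (`pop1`, `pop2`) sharing one
#'   map.
#' @export
generate_divergent_populations <- function(n1, n2, n_snps, F, seed = 1) {
  n1 <- check_count(n1, "n1", 2L); n2 <- check_count(n2, "n2", 2L)
  n_snps <- check_count(n_snps, "n_snps")
  check_fraction(F, "F", 0, 1, open_lo = TRUE, open_hi = TRUE)
  with_seed(derive_seed(seed, 404L), {
    p_anc <- stats::runif(n_snps, 0.05, 0.95)
    shape <- (1 - F) / F
    p1 <- stats::rbeta(n_snps, p_anc * shape, (1 - p_anc) * shape)
    p2 <- stats::rbeta(n_snps, p_anc * shape, (1 - p_anc) * shape)
    draw <- function(n, p) {
      t(vapply(seq_len(n_snps), function(j) stats::rbinom(n, 2, p[j]),
               numeric(n)))
    }
    map <- data.frame(snp_id = sprintf("D%05d", seq_len(n_snps)),
                      chromosome = 1L, position = seq_len(n_snps) * 1000L)
    D1 <- t(draw(n1, p1)); rownames(D1) <- sprintf("P1_%03d", seq_len(n1))
    D2 <- t(draw(n2, p2)); rownames(D2) <- sprintf("P2_%03d", seq_len(n2))
    colnames(D1) <- colnames(D2) <- map$snp_id
    list(pop1 = geno_matrix(D1, map), pop2 = geno_matrix(D2, map))
  })
}
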