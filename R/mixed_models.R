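#' Specify a linear mixed model
#'
#' @param response response column name.
#' @param fixed character vector of fixed terms (may be empty).
#' @param random character vector of random terms; interactions/nestings
#'   written with `:` (e.g. `"genotype:environment"`).
#' @param scale analysis scale label: `"environment"`, `"envirotype"` or
#'   `"MET"`.
#' @return a `model_spec` object.
#' @export
model_spec <- function(response, fixed = character(), random = character(),
                       scale = c("MET", "envirotype", "environment")) {
  scale <- match.arg(scale)
  structure(list(response = response, fixed = fixed, random = random,
                 scale = scale), class = "model_spec")
}

# Grouping factor for a (possibly interaction) term.
term_factor <- function(data, term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  interaction(data[parts], drop = TRUE, lex.order = TRUE)
}

#' Fit a mixed model by REML and extract variance components
#'
#' Thin wrapper around [lme4::lmer()] that builds the formula from a
#' [model_spec()], constrains variance components to be nonnegative
#' (lmer's boundary behaviour), and returns the component table plus the
#' fixed-effect estimates from generalized least squares at the REML
#' optimum. Random terms whose grouping structures are confounded (one is a
#' relabeling of the other) are rejected up front, naming the pair.
#'
#' @param data data frame with the model columns.
#' @param spec a [model_spec()].
#' @return list with `components` (named vector of variance estimates in
#'   trait units squared, including `"residual"`), `fixed` (named vector),
#'   `logLik`, `converged`, `fit` (the `lmerMod`/`lm` object).
#' @export
reml_fit <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- unique(c(spec$response,
                   unlist(strsplit(c(spec$fixed, spec$random), ":", fixed = TRUE))))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop_field("data", paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  for (rt in spec$random) {
    if (nlevels(term_factor(data, rt)) < 2)
      stop_field("spec", paste("random term", rt, "has fewer than 2 levels"))
  }
  if (length(spec$random) > 1) {
    fs <- lapply(spec$random, term_factor, data = data)
    for (i in seq_along(fs)) for (j in seq_len(i - 1L)) {
      gi <- as.integer(fs[[i]]); gj <- as.integer(fs[[j]])
      if (nlevels(fs[[i]]) == nlevels(fs[[j]]) &&
          all(tapply(gj, gi, function(v) length(unique(v))) == 1L))
        stop_field("spec", sprintf("random terms %s and %s are confounded",
                                   spec$random[j], spec$random[i]))
    }
  }
  fixed_part <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  rand_part <- paste(sprintf("(1 | %s)", spec$random), collapse = " + ")
  if (!length(spec$random)) {
    fit <- stats::lm(stats::reformulate(spec$fixed, response = spec$response),
                     data = data)
    return(list(components = c(residual = summary(fit)$sigma^2),
                fixed = stats::coef(fit), logLik = as.numeric(stats::logLik(fit)),
                converged = TRUE, fit = fit))
  }
  form <- stats::as.formula(paste(spec$response, "~", fixed_part, "+", rand_part))
  fit <- lme4::lmer(form, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- vc$vcov
  names(comp) <- ifelse(vc$grp == "Residual", "residual", vc$grp)
  # normalize lmer's interaction naming (A:B) back to the spec's terms
  for (rt in spec$random) {
    alt <- paste(strsplit(rt, ":", fixed = TRUE)[[1]], collapse = ":")
    if (!rt %in% names(comp) && alt %in% names(comp))
      names(comp)[names(comp) == alt] <- rt
  }
  list(components = comp, fixed = lme4::fixef(fit),
       logLik = as.numeric(stats::logLik(fit)),
       converged = length(fit@optinfo$conv$lme4$messages) == 0,
       fit = fit)
}

# TRUE when every genotype x unit cell holds exactly the same number of
# observations (complete balanced design); such designs admit closed-form
# BLUEs (arithmetic means).
is_balanced <- function(data, rows, cols) {
  tab <- table(data[[rows]], data[[cols]])
  all(tab == tab[1])
}

# Median number of replicates per genotype(-environment) cell, the `r` used
# by the heritability formulas on unbalanced data.
median_reps <- function(data, genotype = "genotype", environment = NULL) {
  if (is.null(environment)) {
    counts <- table(data[[genotype]])
  } else {
    tab <- table(data[[genotype]], data[[environment]])
    counts <- tab[tab > 0]
  }
  stats::median(as.numeric(counts))
}

#' Plot-level heritability at the single-environment scale
#'
#' `h2 = sigma2_G / (sigma2_G + sigma2_e / r)` where `r` is the number of
#' replicates per genotype.
#'
#' @param sigma2_g genotypic variance.
#' @param sigma2_e residual variance.
#' @param r replicates per genotype.
#' @return heritability in `[0, 1]`.
#' @export
heritability_env <- function(sigma2_g, sigma2_e, r) {
  if (any(c(sigma2_g, sigma2_e) < 0)) stop_field("sigma2", "components must be >= 0")
  if (r < 1) stop_field("r", "must be >= 1")
  denom <- sigma2_g + sigma2_e / r
  if (denom <= 0) stop_field("sigma2", "all components are zero")
  sigma2_g / denom
}

#' Heritability at the envirotype or MET scale
#'
#' `h2 = sigma2_G / (sigma2_G + sigma2_GxE / e + sigma2_e / (r * e))`, with
#' `e` the number of environments in the group and `r` the replicates per
#' genotype and environment. The divisor of the interaction term is taken
#' equal to `e`.
#'
#' @param sigma2_g,sigma2_gxe,sigma2_e variance components.
#' @param e number of environments.
#' @param r replicates per genotype and environment.
#' @return heritability in `[0, 1]`.
#' @export
heritability_group <- function(sigma2_g, sigma2_gxe, sigma2_e, e, r) {
  if (any(c(sigma2_g, sigma2_gxe, sigma2_e) < 0))
    stop_field("sigma2", "components must be >= 0")
  if (e < 1 || r < 1) stop_field("e", "e and r must be >= 1")
  denom <- sigma2_g + sigma2_gxe / e + sigma2_e / (r * e)
  if (denom <= 0) stop_field("sigma2", "all components are zero")
  sigma2_g / denom
}

#' Genotype BLUEs and heritability for one environment
#'
#' Fits the single-environment model (genotype fixed; replicate and residual
#' random) to obtain adjusted genotype means, and the all-random refit of
#' the same data for the variance components entering the
#' plot-level heritability. On complete balanced data the closed forms are
#' used (BLUE = genotype mean; ANOVA mean squares for the components),
#' which REML reproduces exactly.
#'
#' @param data plot data for one environment with columns `genotype`,
#'   `replicate` and the trait.
#' @param trait trait column name.
#' @param method `"auto"` (closed form on complete balanced designs,
#'   REML otherwise) or `"reml"`.
#' @return list with `blues` (data frame `genotype`, `blue`, `se`),
#'   `h2`, `components` (all-random fit), `r`.
#' @export
blues_single_env <- function(data, trait = "value", method = c("auto", "reml")) {
  method <- match.arg(method)
  if (nrow(data) < 2) stop_field("data", "needs more than one observation")
  data$genotype <- factor(data$genotype)
  data$replicate <- factor(data$replicate)
  y <- data[[trait]]
  g <- nlevels(data$genotype); r_lev <- nlevels(data$replicate)
  balanced <- r_lev >= 1 && is_balanced(data, "genotype", "replicate") &&
    nrow(data) == g * r_lev
  r <- median_reps(data)
  if (method == "auto" && balanced) {
    gm <- tapply(y, data$genotype, mean)
    if (r_lev >= 2 && g >= 2) {
      rm_ <- tapply(y, data$replicate, mean)
      mu <- mean(y)
      resid <- y - gm[data$genotype] - rm_[data$replicate] + mu
      ms_e <- sum(resid^2) / ((g - 1) * (r_lev - 1))
      ms_g <- r_lev * sum((gm - mu)^2) / (g - 1)
      sg2 <- max((ms_g - ms_e) / r_lev, 0)
      blues <- data.frame(genotype = names(gm), blue = as.numeric(gm),
                          se = sqrt(ms_e / r_lev))
      h2 <- heritability_env(sg2, ms_e, r_lev)
      comps <- c(genotype = sg2, residual = ms_e)
    } else {
      blues <- data.frame(genotype = names(gm), blue = as.numeric(gm),
                          se = NA_real_)
      h2 <- NA_real_
      comps <- c(genotype = NA_real_, residual = NA_real_)
    }
    return(list(blues = blues, h2 = h2, components = comps, r = r))
  }
  use_rep <- r_lev >= 2
  fml <- if (use_rep) stats::as.formula(paste(trait, "~ 0 + genotype + (1 | replicate)"))
         else stats::as.formula(paste(trait, "~ 0 + genotype"))
  if (use_rep) {
    fit <- lme4::lmer(fml, data = data, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    sig_e <- stats::sigma(fit)^2
  } else {
    fit <- stats::lm(fml, data = data)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    sig_e <- summary(fit)$sigma^2
  }
  blues <- data.frame(genotype = sub("^genotype", "", names(est)),
                      blue = as.numeric(est), se = as.numeric(se))
  if (use_rep && g >= 2) {
    rand <- reml_fit(data, model_spec(trait, random = c("genotype", "replicate"),
                                      scale = "environment"))
    sg2 <- rand$components[["genotype"]]
    se2 <- rand$components[["residual"]]
    h2 <- heritability_env(sg2, se2, r)
    comps <- rand$components
  } else {
    h2 <- NA_real_
    comps <- c(residual = sig_e)
  }
  list(blues = blues, h2 = h2, components = comps, r = r)
}

#' Genotype BLUEs, heritability and variance percentages for a group of
#' environments
#'
#' For an envirotype or the whole MET: adjusted genotype means come from the
#' fixed-genotype model (genotype and environment fixed, replicate within
#' environment random; the genotype-by-environment term is not separable
#' from the error in the fixed-effect fit and is left in the residual). The
#' variance-percentage table and the heritability use the all-random refit
#' (genotype, environment, genotype x environment, replicate within
#' environment, residual). On complete balanced data the BLUEs are the
#' genotype grand means.
#'
#' @param data plot data with columns `genotype`, `environment`,
#'   `replicate` and the trait.
#' @param trait trait column name.
#' @param method `"auto"` or `"reml"` for the BLUE computation.
#' @param compute_components fit the all-random model for the percentage
#'   table and heritability (set `FALSE` to return BLUEs only).
#' @return list with `blues`, `h2`, `components`, `percentages`
#'   (named, summing to 100), `e`, `r`.
#' @export
blues_group <- function(data, trait = "value", method = c("auto", "reml"),
                        compute_components = TRUE) {
  method <- match.arg(method)
  data$genotype <- factor(data$genotype)
  data$environment <- factor(data$environment)
  data$replicate <- factor(data$replicate)
  e <- nlevels(data$environment)
  if (e < 2)
    stop_field("data", "group has a single environment; use blues_single_env()")
  y <- data[[trait]]
  g <- nlevels(data$genotype)
  cell <- table(data$genotype, data$environment)
  balanced <- all(cell == cell[1])
  r <- median_reps(data, environment = "environment")
  if (method == "auto" && balanced) {
    gm <- tapply(y, data$genotype, mean)
    blues <- data.frame(genotype = names(gm), blue = as.numeric(gm),
                        se = NA_real_)
  } else {
    fit <- lme4::lmer(
      stats::as.formula(paste(trait, "~ 0 + genotype + environment + (1 | environment:replicate)")),
      data = data, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))
    est <- lme4::fixef(fit)
    keep <- grepl("^genotype", names(est))
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[keep]
    # report on the mu + g_i scale: add the mean environment effect
    # (treatment contrasts: the first environment's effect is 0)
    env_eff <- est[grepl("^environment", names(est))]
    env_mean <- mean(c(0, env_eff))
    blues <- data.frame(genotype = sub("^genotype", "", names(est)[keep]),
                        blue = as.numeric(est[keep]) + env_mean,
                        se = as.numeric(se))
  }
  out <- list(blues = blues, e = e, r = r)
  if (compute_components) {
    rand <- reml_fit(data, model_spec(
      trait,
      random = c("genotype", "environment", "genotype:environment",
                 "environment:replicate"),
      scale = "MET"))
    comp <- rand$components
    pretty <- c(genotype = "G", environment = "E",
                "genotype:environment" = "GxE",
                "environment:replicate" = "R", residual = "residual")
    names(comp) <- pretty[names(comp)]
    comp <- comp[c("G", "E", "GxE", "R", "residual")]
    out$components <- comp
    out$percentages <- comp / sum(comp) * 100
    out$h2 <- heritability_group(comp[["G"]], comp[["GxE"]], comp[["residual"]],
                                 e = e, r = r)
  }
  out
}

#' Variance repartition of the envirotype-aware MET model
#'
#' All-random fit of
#' `mu + G + En + En(E) + G x En + G x En x E + R(En x E) + eps`, i.e. the
#' MET-scale model with the environment term split into envirotype and
#' environment-within-envirotype parts. Returns the percentage of total
#' variance per term plus the derived shares `En / (En + EnxE)` (how much of
#' the environmental variance the envirotyping explains) and
#' `GxEn / (GxEn + GxEnxE)`.
#'
#' @param data plot data (`genotype`, `environment`, `replicate`, trait).
#' @param assignment data frame `environment_id`, `envirotype` covering
#'   every environment.
#' @param trait trait column name.
#' @return list with `components`, `percentages` (named `G`, `En`, `EnxE`,
#'   `GxEn`, `GxEnxE`, `R`, `residual`; sums to 100), `env_share`,
#'   `gxe_share`, `warning_single_env` (TRUE when some envirotype holds one
#'   environment).
#' @export
envirotype_partition <- function(data, assignment, trait = "value") {
  data$envirotype <- assignment$envirotype[
    match(as.character(data$environment), assignment$environment_id)]
  if (anyNA(data$envirotype))
    stop_field("assignment", "every environment must be assigned an envirotype")
  data$genotype <- factor(data$genotype)
  data$environment <- factor(data$environment)
  data$envirotype <- factor(data$envirotype)
  data$replicate <- factor(data$replicate)
  per_env <- table(assignment$envirotype)
  warn_single <- any(per_env == 1)
  if (warn_single)
    warning("envirotype(s) with a single environment: En(E) partially confounded")
  rand <- reml_fit(data, model_spec(
    trait,
    random = c("genotype", "envirotype", "envirotype:environment",
               "genotype:envirotype", "genotype:envirotype:environment",
               "envirotype:environment:replicate"),
    scale = "MET"))
  comp <- rand$components
  pretty <- c(genotype = "G", envirotype = "En",
              "envirotype:environment" = "EnxE",
              "genotype:envirotype" = "GxEn",
              "genotype:envirotype:environment" = "GxEnxE",
              "envirotype:environment:replicate" = "R",
              residual = "residual")
  names(comp) <- pretty[names(comp)]
  comp <- comp[c("G", "En", "EnxE", "GxEn", "GxEnxE", "R", "residual")]
  pct <- comp / sum(comp) * 100
  list(components = comp, percentages = pct,
       env_share = 100 * comp[["En"]] / (comp[["En"]] + comp[["EnxE"]]),
       gxe_share = 100 * comp[["GxEn"]] / (comp[["GxEn"]] + comp[["GxEnxE"]]),
       warning_single_env = warn_single)
}

#' Variance partition of the QTL-by-environment model
#'
#' All-random fit of `mu + G + E + marker x E + R(E) + eps` at the MET
#' scale, testing how much of the total variance the interaction between
#' one marker's dosage and the environment explains.
#'
#' @param data plot data (`genotype`, `environment`, `replicate`, trait).
#' @param marker named numeric vector of dosages (names = genotype ids), or
#'   a vector aligned with `levels(factor(data$genotype))`.
#' @param trait trait column name.
#' @return list with `components` and `percentages` over
#'   `G`, `Trial`, `BlockxTrial`, `QTLxTrial`, `residual`.
#' @export
qtl_by_env_partition <- function(data, marker, trait = "value") {
  data$genotype <- factor(data$genotype)
  data$environment <- factor(data$environment)
  data$replicate <- factor(data$replicate)
  if (nlevels(data$environment) < 2)
    stop_field("data", "single environment input; QTL x E requires >= 2 environments")
  if (is.null(names(marker))) names(marker) <- levels(data$genotype)
  mk <- marker[as.character(data$genotype)]
  if (anyNA(mk)) stop_field("marker", "dosage missing for some genotypes")
  if (length(unique(round(mk, 6))) < 2)
    stop_field("marker", "monomorphic marker")
  data$marker <- factor(round(mk, 6))
  rand <- reml_fit(data, model_spec(
    trait,
    random = c("genotype", "environment", "marker:environment",
               "environment:replicate"),
    scale = "MET"))
  comp <- rand$components
  pretty <- c(genotype = "G", environment = "Trial",
              "marker:environment" = "QTLxTrial",
              "environment:replicate" = "BlockxTrial",
              residual = "residual")
  names(comp) <- pretty[names(comp)]
  comp <- comp[c("G", "Trial", "BlockxTrial", "QTLxTrial", "residual")]
  list(components = comp, percentages = comp / sum(comp) * 100)
}

#' Seed number from seed yield and thousand-seed weight
#'
#' `SN = SY * 100000 / TSW`, with SY in q/ha, TSW in g and SN in seeds/m2.
#'
#' @param sy seed yield (q/ha).
#' @param tsw thousand-seed weight (g), > 0.
#' @return seed number per square metre.
#' @export
seed_number <- function(sy, tsw) {
  if (any(tsw <= 0)) stop_field("tsw", "must be > 0")
  sy * 100000 / tsw
}
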