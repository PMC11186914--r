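#' Variance profile of the envirotype-aware MET model
#'
#' Default simulation targets for the fraction of total phenotypic variance
#' carried by each term of the envirotype-aware model: genotype (G),
#' envirotype (En), environment within envirotype (EnxE), genotype x
#' envirotype (GxEn), genotype x environment within envirotype (GxEnxE),
#' replicate within environment (R) and residual (eps). The default profile
#' reflects a typical winter oilseed rape MET in which the environment
#' dominates (~64% of total variance, ~70% of it between envirotypes),
#' genotype carries ~20-25% and genotype-by-environment ~5%.
#'
#' @return named numeric vector summing to 1.
#' @export
met_variance_profile <- function() {
  c(G = 0.200, En = 0.444, EnxE = 0.192, GxEn = 0.012, GxEnxE = 0.039,
    R = 0.031, eps = 0.082)
}

#' Split a compact variance profile into envirotype-aware targets
#'
#' Converts a profile stated on the scale of the plain MET model (G, E,
#' GxE, R, eps) into the envirotype-aware terms by splitting the
#' environmental variance between envirotype and environment-within-
#' envirotype, and the interaction between GxEn and GxEnxE.
#'
#' @param G,E,GxE,R,eps fractions of total variance (should sum to 1).
#' @param env_split fraction of `E` attributed to the envirotype term.
#' @param gxe_split fraction of `GxE` attributed to genotype x envirotype.
#' @return named vector as in [met_variance_profile()].
#' @export
split_variance_profile <- function(G, E, GxE, R, eps,
                                   env_split = 0.444 / (0.444 + 0.192),
                                   gxe_split = 0.012 / (0.012 + 0.039)) {
  out <- c(G = G, En = E * env_split, EnxE = E * (1 - env_split),
           GxEn = GxE * gxe_split, GxEnxE = GxE * (1 - gxe_split),
           R = R, eps = eps)
  out / sum(out)
}

#' Generator targets that reproduce a plain MET-model variance profile
#'
#' The generator parameterizes the environment as envirotype plus
#' environment-within-envirotype effects. Because the envirotype values are
#' shared across the environments of a type, the variance the *plain* MET
#' model (G, E, GxE, R, residual) recovers for its E and GxE terms is a
#' known linear combination of the two nested components, with coefficients
#' set by the design size. This helper inverts that relation: given a
#' target profile on the plain-model scale (e.g. a published MET variance
#' table) and the design dimensions, it returns 7-term generator targets
#' whose fitted plain-model percentages land on the requested profile.
#'
#' @param G,E,GxE,R,eps target fractions on the plain-model scale.
#' @param n_environments,n_envirotypes design dimensions of the simulated
#'   MET (environments assumed spread evenly over envirotypes).
#' @param env_split fraction of the environmental variance attributed to
#'   the envirotype term (level scale).
#' @param gxe_split fraction of the interaction variance attributed to
#'   genotype x envirotype.
#' @return named 7-term vector summing to 1, for
#'   [sim_config()]'s `variance_targets`.
#' @export
model5_variance_targets <- function(G, E, GxE, R, eps,
                                    n_environments, n_envirotypes,
                                    env_split = 0.444 / (0.444 + 0.192),
                                    gxe_split = 0.012 / (0.012 + 0.039)) {
  n <- n_environments; k <- n_envirotypes
  c1 <- (n / k) * (k - 1) / (n - 1)   # envirotype-term weight in the plain model
  c2 <- (n - k) / (n - 1)             # nested-term weight in the plain model
  t_e <- E / (env_split * c1 + (1 - env_split) * c2)
  t_g <- GxE / (gxe_split * c1 + (1 - gxe_split) * c2)
  out <- c(G = G, En = env_split * t_e, EnxE = (1 - env_split) * t_e,
           GxEn = gxe_split * t_g, GxEnxE = (1 - gxe_split) * t_g,
           R = R, eps = eps)
  out / sum(out)
}

#' Specify a simulated QTL
#'
#' @param chromosome chromosome index (1-based).
#' @param position position in bp; must coincide with a simulated SNP.
#' @param effect_size fraction of the genotypic variance explained, in
#'   (0, 1). For interactive QTL the fraction applies within the target
#'   envirotype.
#' @param mode `"stable"` (same effect everywhere) or `"interactive"`
#'   (effect only in `target_envirotype`).
#' @param target_envirotype envirotype label (e.g. `"E4"`); required when
#'   `mode = "interactive"`.
#' @return a `qtl_spec` object.
#' @export
qtl_spec <- function(chromosome, position, effect_size,
                     mode = c("stable", "interactive"),
                     target_envirotype = NULL) {
  mode <- match.arg(mode)
  check_count(chromosome, "chromosome")
  check_count(position, "position")
  check_fraction(effect_size, "effect_size", 0, 1, open_lo = TRUE, open_hi = TRUE)
  if (mode == "interactive" && is.null(target_envirotype))
    stop_field("target_envirotype", "required when mode is \"interactive\"")
  structure(list(chromosome = as.integer(chromosome),
                 position = as.integer(position),
                 effect_size = effect_size, mode = mode,
                 target_envirotype = target_envirotype),
            class = "qtl_spec")
}

#' Configuration of a synthetic multi-environment trial
#'
#' Defines the full study design of a simulated MET: environments grouped
#' into envirotypes with contrasting limiting-factor profiles, a panel of
#' mostly-homozygous accessions genotyped at LD-block-structured SNPs, and
#' plot-level phenotypes built from the envirotype-aware variance profile
#' with planted stable and/or interactive QTL.
#'
#' @param n_environments number of environments (year x location x N
#'   regime combinations).
#' @param n_envirotypes number of envirotype templates.
#' @param n_accessions panel size.
#' @param n_snps total SNP count.
#' @param n_chromosomes chromosomes the SNPs are spread over.
#' @param ld_block_size SNPs per haplotype block.
#' @param maf_range pair of fractions in (0, 0.5]: range of the block
#'   founder-haplotype frequencies.
#' @param missing_rate fraction of dosage entries set missing.
#' @param variance_targets named fractions per model term (see
#'   [met_variance_profile()]); must sum to 1.
#' @param qtl_specs list of [qtl_spec()] objects.
#' @param replicates_per_env complete blocks per environment.
#' @param seed master seed; every generated object is a pure function of
#'   the configuration including this seed.
#' @param mean_sy grand mean seed yield (q/ha).
#' @param total_variance total phenotypic variance ((q/ha)^2) distributed
#'   over the variance targets.
#' @param envirotype_sd within-envirotype indicator variability, as a
#'   multiple of the between-envirotype template spread (smaller = more
#'   contrasted envirotypes).
#' @param envirotype_separation scale of the envirotype contrast
#'   directions, in template-spread units per indicator; with the default
#'   within-envirotype variability this keeps template pairs several
#'   within-type standard deviations apart even on indicators whose
#'   weather realization is noisy.
#' @param het_rate residual heterozygosity of the inbred panel.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_environments = 22, n_envirotypes = 4,
                       n_accessions = 150, n_snps = 2000, n_chromosomes = 4,
                       ld_block_size = 20, maf_range = c(0.1, 0.5),
                       missing_rate = 0.01,
                       variance_targets = met_variance_profile(),
                       qtl_specs = list(), replicates_per_env = 3, seed = 1,
                       mean_sy = 30.35, total_variance = 60,
                       envirotype_sd = 0.25, envirotype_separation = 1.75,
                       het_rate = 0.02) {
  n_environments <- check_count(n_environments, "n_environments")
  n_envirotypes <- check_count(n_envirotypes, "n_envirotypes")
  if (n_envirotypes > n_environments)
    stop_field("n_envirotypes", "cannot exceed n_environments")
  n_accessions <- check_count(n_accessions, "n_accessions")
  n_snps <- check_count(n_snps, "n_snps")
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  ld_block_size <- check_count(ld_block_size, "ld_block_size")
  if (ld_block_size > ceiling(n_snps / n_chromosomes))
    stop_field("ld_block_size", "exceeds the SNPs available per chromosome")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_field("maf_range", "must be an ordered pair within (0, 0.5]")
  check_fraction(missing_rate, "missing_rate", 0, 1)
  terms <- c("G", "En", "EnxE", "GxEn", "GxEnxE", "R", "eps")
  if (!all(terms %in% names(variance_targets)))
    stop_field("variance_targets", paste("must name all of",
                                         paste(terms, collapse = ", ")))
  variance_targets <- variance_targets[terms]
  if (any(variance_targets < 0))
    stop_field("variance_targets", "fractions must be >= 0")
  if (abs(sum(variance_targets) - 1) > 1e-9)
    stop_field("variance_targets", "must sum to 1 (tolerance 1e-9)")
  for (q in qtl_specs) {
    if (!inherits(q, "qtl_spec")) stop_field("qtl_specs", "must be qtl_spec objects")
    if (q$chromosome > n_chromosomes)
      stop_field("qtl_specs", "chromosome index exceeds n_chromosomes")
    if (q$mode == "interactive" &&
        !q$target_envirotype %in% paste0("E", seq_len(n_envirotypes)))
      stop_field("qtl_specs", sprintf("target_envirotype %s not among the %d envirotypes",
                                      q$target_envirotype, n_envirotypes))
  }
  replicates_per_env <- check_count(replicates_per_env, "replicates_per_env")
  check_count(seed, "seed", min = 0L)
  if (total_variance <= 0) stop_field("total_variance", "must be > 0")
  check_fraction(het_rate, "het_rate", 0, 1)
  structure(list(
    n_environments = n_environments, n_envirotypes = n_envirotypes,
    n_accessions = n_accessions, n_snps = n_snps,
    n_chromosomes = n_chromosomes, ld_block_size = ld_block_size,
    maf_range = as.numeric(maf_range), missing_rate = missing_rate,
    variance_targets = variance_targets, qtl_specs = qtl_specs,
    replicates_per_env = replicates_per_env, seed = as.integer(seed),
    mean_sy = mean_sy, total_variance = total_variance,
    envirotype_sd = envirotype_sd,
    envirotype_separation = envirotype_separation, het_rate = het_rate),
    class = "sim_config")
}
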