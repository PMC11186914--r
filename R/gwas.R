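#' Genotype dosage matrix with map
#'
#' Container for a SNP panel: an accessions x SNPs dosage matrix (counts of
#' the alternate allele in `{0, 1, 2}`, `NA` = missing) and its genetic map.
#'
#' @param dosages numeric matrix, accessions in rows (rownames = accession
#'   ids), SNPs in columns (colnames = SNP ids).
#' @param map data frame with columns `snp_id`, `chromosome`, `position`
#'   (bp), one row per SNP column, positions strictly increasing within
#'   chromosome.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, map) {
  dosages <- as.matrix(dosages)
  if (!all(c("snp_id", "chromosome", "position") %in% names(map)))
    stop_field("map", "must have columns snp_id, chromosome, position")
  if (nrow(map) != ncol(dosages))
    stop_field("map", "one row per SNP column required")
  if (is.null(colnames(dosages))) colnames(dosages) <- map$snp_id
  if (!identical(colnames(dosages), as.character(map$snp_id)))
    stop_field("map", "snp_id must match the dosage column names")
  for (ch in unique(map$chromosome)) {
    pos <- map$position[map$chromosome == ch]
    if (any(diff(pos) <= 0))
      stop_field("map", sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  ok <- is.na(dosages) | (dosages >= 0 & dosages <= 2)
  if (!all(ok)) stop_field("dosages", "must lie in [0, 2] or be NA")
  structure(list(dosages = dosages, map = map), class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Per-SNP minor allele frequency
#' @param G a [geno_matrix()].
#' @return numeric vector in `[0, 0.5]`, computed on non-missing dosages.
#' @export
snp_maf <- function(G) {
  p <- colMeans(G$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-SNP missing fraction
#' @param G a [geno_matrix()].
#' @export
snp_missing <- function(G) colMeans(is.na(G$dosages))

#' Filter SNPs on minor allele frequency and missingness
#'
#' @param G a [geno_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.025).
#' @param missing_max maximum missing fraction (default 0.10).
#' @return the filtered `geno_matrix`.
#' @export
filter_snps <- function(G, maf_min = 0.025, missing_max = 0.10) {
  stopifnot(inherits(G, "geno_matrix"))
  maf <- snp_maf(G)
  miss <- snp_missing(G)
  fail_maf <- maf < maf_min
  fail_miss <- miss > missing_max
  keep <- !(fail_maf | fail_miss)
  if (!any(keep))
    stop_field("G", sprintf(
      "no SNP passes filtering (%d fail MAF < %g, %d fail missing > %g)",
      sum(fail_maf), maf_min, sum(fail_miss), missing_max))
  geno_matrix(G$dosages[, keep, drop = FALSE], G$map[keep, , drop = FALSE])
}

#' Impute missing dosages with the per-SNP mean
#'
#' @param G a filtered [geno_matrix()].
#' @return a complete `geno_matrix` (real-valued dosages).
#' @export
impute_dosages <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  D <- G$dosages
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  out <- G
  out$dosages <- D
  out
}

#' Genomic kinship (allele-frequency standardized)
#'
#' `K = (1/M) sum_m (x_m - 2 p_m)(x_m - 2 p_m)' / (2 p_m (1 - p_m))` over
#' the chosen SNPs, with `p_m` the alternate allele frequency. Monomorphic
#' SNPs in the subset are skipped with a warning.
#'
#' @param G a complete [geno_matrix()].
#' @param snp_subset SNP ids or column indices; defaults to all SNPs.
#' @return symmetric positive semidefinite accession x accession matrix.
#' @export
kinship <- function(G, snp_subset = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  D <- G$dosages
  if (!is.null(snp_subset)) {
    D <- D[, snp_subset, drop = FALSE]
  }
  if (ncol(D) < 2) stop_field("snp_subset", "needs at least 2 SNPs")
  p <- colMeans(D) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sprintf("skipping %d monomorphic SNP(s) in kinship", sum(mono)))
    D <- D[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  Z <- sweep(D, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  tcrossprod(Z) / ncol(Z)
}

#' Genome-wide and leave-one-chromosome-out kinships
#'
#' The kinship used to test SNPs on chromosome `c` is computed from all SNPs
#' **not** on `c`, so the tested chromosome's own signal is not absorbed by
#' the polygenic term.
#'
#' @param G a complete [geno_matrix()].
#' @return list with `genome` (matrix), `loco` (named list of matrices, one
#'   per chromosome), `n_snps` (markers used per LOCO matrix).
#' @export
loco_kinships <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  chroms <- unique(G$map$chromosome)
  if (length(chroms) < 2)
    stop_field("G", "leave-one-chromosome-out requires >= 2 chromosomes")
  loco <- lapply(chroms, function(ch) {
    kinship(G, which(G$map$chromosome != ch))
  })
  names(loco) <- as.character(chroms)
  n_snps <- vapply(chroms, function(ch) sum(G$map$chromosome != ch), 0L)
  names(n_snps) <- as.character(chroms)
  list(genome = kinship(G), loco = loco, n_snps = n_snps)
}

# REML log-likelihood profile in delta = sigma2_e / sigma2_g for the
# intercept-only null model, on the eigenbasis of the kinship.
null_delta_reml <- function(y, lambda, U) {
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, length(y))))
  n <- length(y); p <- 1L
  ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (lambda + delta)
    xx <- sum(w * xt * xt)
    beta <- sum(w * xt * yt) / xx
    r <- yt - xt * beta
    s2 <- sum(w * r * r) / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(lambda + delta)) + log(xx))
  }
  opt <- stats::optimize(ll, interval = log(c(1e-5, 1e5)), maximum = TRUE)
  exp(opt$maximum)
}

#' Mixed-model association scan with spectral decomposition
#'
#' For each chromosome, the leave-one-chromosome-out kinship is
#' eigendecomposed once, the variance ratio `delta = sigma2_e / sigma2_g`
#' is estimated by REML under the null (intercept-only) model, and every
#' SNP is tested by weighted least squares in the rotated space at that
#' fixed `delta` (the fast single-estimation mode of spectral mixed-model
#' association). Per-SNP p-values come from the squared Wald statistic
#' referred to an F(1, n - 2) distribution, so that with an identity
#' kinship the scan reduces exactly to ordinary simple regression.
#'
#' @param blues data frame with columns `genotype` and `blue` (one adjusted
#'   mean per genotype).
#' @param G a complete [geno_matrix()]; rownames of the dosages must
#'   contain the genotype ids.
#' @param kinships result of [loco_kinships()] on (at least) the scanned
#'   accessions, or a single kinship matrix used for every chromosome.
#' @param min_genotypes minimum number of phenotyped, genotyped accessions.
#' @return data frame (class `gwas_scan`): `snp_id`, `chromosome`,
#'   `position`, `beta` (trait units per alternate allele), `se`,
#'   `neglog10p`, `r2` (proportion of BLUE variance explained), `maf`.
#' @export
lmm_scan <- function(blues, G, kinships = NULL, min_genotypes = 30) {
  stopifnot(inherits(G, "geno_matrix"))
  acc <- intersect(rownames(G$dosages), blues$genotype[!is.na(blues$blue)])
  if (length(acc) < min_genotypes)
    stop_field("blues", sprintf("only %d genotypes with phenotype and genotype (min %d)",
                                length(acc), min_genotypes))
  y <- blues$blue[match(acc, blues$genotype)]
  D <- G$dosages[acc, , drop = FALSE]
  if (anyNA(D)) stop_field("G", "dosages must be imputed before scanning")
  n <- length(y)
  if (is.null(kinships)) kinships <- loco_kinships(geno_matrix(D, G$map))
  single_k <- is.matrix(kinships)
  chroms <- unique(G$map$chromosome)
  vy <- stats::var(y)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    K <- if (single_k) kinships else kinships$loco[[as.character(ch)]]
    K <- K[acc, acc]
    eg <- eigen(K, symmetric = TRUE)
    lambda <- pmax(eg$values, 0)
    U <- eg$vectors
    delta <- null_delta_reml(y, lambda, U)
    w <- 1 / (lambda + delta)
    yt <- drop(crossprod(U, y))
    ot <- drop(crossprod(U, rep(1, n)))
    idx <- which(G$map$chromosome == ch)
    Xt <- crossprod(U, D[, idx, drop = FALSE])
    a11 <- sum(w * ot * ot)
    a12 <- drop(crossprod(Xt * w, ot))
    a22 <- colSums(w * Xt * Xt)
    b1 <- sum(w * ot * yt)
    b2 <- drop(crossprod(Xt * w, yt))
    det_ <- a11 * a22 - a12^2
    det_[det_ <= 1e-12] <- NA          # monomorphic in the scanned subset
    beta <- (a11 * b2 - a12 * b1) / det_
    alpha <- (b1 - a12 * beta) / a11
    yy <- sum(w * yt * yt)
    rss <- yy - alpha * b1 - beta * b2
    rss <- pmax(rss, 0)
    s2 <- rss / (n - 2)
    se <- sqrt(s2 * a11 / det_)
    chi <- (beta / se)^2
    p <- stats::pf(chi, 1, n - 2, lower.tail = FALSE)
    vx <- apply(D[, idx, drop = FALSE], 2, stats::var)
    out[[ci]] <- data.frame(
      snp_id = G$map$snp_id[idx], chromosome = ch,
      position = G$map$position[idx],
      beta = beta, se = se,
      neglog10p = -log10(pmax(p, .Machine$double.xmin)),
      r2 = beta^2 * vx / vy,
      alt_freq = colMeans(D[, idx, drop = FALSE]) / 2,
      maf = pmin(colMeans(D[, idx, drop = FALSE]) / 2,
                 1 - colMeans(D[, idx, drop = FALSE]) / 2),
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("gwas_scan", class(res))
  attr(res, "n_genotypes") <- n
  res
}

#' Effective number of independent tests (eigenvalue-based)
#'
#' Within each chromosome, consecutive blocks of at most `block_size` SNPs
#' are formed; for each block the composite-LD correlation matrix (Pearson
#' correlation of dosage columns) is eigendecomposed and the smallest
#' number of top eigenvalues whose sum reaches `C` times the trace is
#' counted. The effective test count is the sum over blocks.
#'
#' @param G a complete [geno_matrix()] (no missing, no zero-variance SNP).
#' @param block_size maximum SNPs per block.
#' @param C fraction of the eigenvalue mass to capture (default 0.995).
#' @return integer `M_eff`.
#' @export
effective_tests <- function(G, block_size = 1000, C = 0.995) {
  stopifnot(inherits(G, "geno_matrix"))
  D <- G$dosages
  if (anyNA(D)) stop_field("G", "impute before computing effective tests")
  v <- apply(D, 2, stats::var)
  if (any(v == 0))
    stop_field("G", paste("zero-variance SNP(s); filter first:",
                          paste(utils::head(colnames(D)[v == 0], 5), collapse = ", ")))
  meff <- 0L
  for (ch in unique(G$map$chromosome)) {
    idx <- which(G$map$chromosome == ch)
    starts <- seq(1L, length(idx), by = block_size)
    for (s in starts) {
      block <- idx[s:min(s + block_size - 1L, length(idx))]
      if (length(block) == 1L) { meff <- meff + 1L; next }
      ev <- eigen(stats::cor(D[, block, drop = FALSE]), symmetric = TRUE,
                  only.values = TRUE)$values
      ev <- pmax(ev, 0)
      cum <- cumsum(ev)
      meff <- meff + which(cum >= C * length(block))[1]
    }
  }
  as.integer(meff)
}

#' Genome-wide significance threshold from the effective test count
#'
#' `t = -log10(alpha_G / M_eff)`: the Bonferroni threshold on the -log10
#' p-value scale, corrected for the effective number of independent tests
#' rather than the raw SNP count.
#'
#' @param alpha_g genome-wide type-I error rate, in `(0, 1]`.
#' @param m_eff effective number of independent tests, >= 1.
#' @return the threshold on the -log10 p-value scale.
#' @export
significance_threshold <- function(alpha_g, m_eff) {
  if (!is.numeric(alpha_g) || alpha_g <= 0 || alpha_g > 1)
    stop_field("alpha_g", "must lie in (0, 1]")
  if (!is.numeric(m_eff) || m_eff < 1) stop_field("m_eff", "must be >= 1")
  -log10(alpha_g / m_eff)
}
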