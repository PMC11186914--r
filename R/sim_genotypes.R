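# Fixed inter-SNP spacing of the simulated map (bp); deterministic positions
# let QTL specifications address SNPs by coordinate.
SNP_SPACING_BP <- 12500L

#' Generate an LD-block-structured genotype panel of inbred lines
#'
#' SNPs are laid out on `n_chromosomes` chromosomes at fixed spacing and
#' organized in haplotype blocks of `ld_block_size` SNPs. Each block
#' carries two complementary founder haplotypes at a frequency drawn from
#' `maf_range`; accessions copy one founder per block (two independent
#' copies with probability `het_rate`, giving the residual heterozygosity
#' of line material), and per-SNP mutation noise (rare flips to the
#' opposite homozygote) decays the within-block LD slightly below 1.
#' Entries are set missing at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return a [geno_matrix()] with accession ids `A001, A002, ...`.
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 202L), {
    n_acc <- config$n_accessions
    per_chrom <- rep(config$n_snps %/% config$n_chromosomes, config$n_chromosomes)
    extra <- config$n_snps %% config$n_chromosomes
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    if (config$ld_block_size > max(per_chrom))
      stop_field("ld_block_size", "exceeds the SNPs on a chromosome")
    acc_ids <- sprintf("A%03d", seq_len(n_acc))
    maps <- list(); chunks <- list()
    mu_flip <- 0.01
    for (ch in seq_len(config$n_chromosomes)) {
      m <- per_chrom[ch]
      map <- data.frame(
        snp_id = sprintf("S%02d_%04d", ch, seq_len(m)),
        chromosome = ch,
        position = seq_len(m) * SNP_SPACING_BP)
      D <- matrix(0L, n_acc, m)
      starts <- seq(1L, m, by = config$ld_block_size)
      for (s in starts) {
        cols <- s:min(s + config$ld_block_size - 1L, m)
        f <- stats::runif(1, config$maf_range[1], config$maf_range[2])
        orient <- stats::rbinom(length(cols), 1, 0.5)   # founder 1's allele per SNP
        hap1 <- orient
        hap2 <- 1L - orient
        pick1 <- stats::rbinom(n_acc, 1, f)             # founder of first copy
        hetero <- stats::runif(n_acc) < config$het_rate
        pick2 <- ifelse(hetero, stats::rbinom(n_acc, 1, f), pick1)
        block <- outer(pick1, rep(1L, length(cols))) * rep(hap1, each = n_acc) +
          outer(1L - pick1, rep(1L, length(cols))) * rep(hap2, each = n_acc) +
          outer(pick2, rep(1L, length(cols))) * rep(hap1, each = n_acc) +
          outer(1L - pick2, rep(1L, length(cols))) * rep(hap2, each = n_acc)
        D[, cols] <- block
      }
      flip <- matrix(stats::runif(n_acc * m) < mu_flip, n_acc, m)
      D[flip] <- 2L - D[flip]
      maps[[ch]] <- map
      chunks[[ch]] <- D
    }
    D <- do.call(cbind, chunks)
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(D)) < config$missing_rate,
                     nrow(D), ncol(D))
      D[miss] <- NA
    }
    rownames(D) <- acc_ids
    map <- do.call(rbind, maps)
    colnames(D) <- map$snp_id
    geno_matrix(D, map)
  })
}
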