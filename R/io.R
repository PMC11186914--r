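# Readers and writers for the plain-text interchange formats of the
# pipeline: weather / management / phenotype CSVs, dosage + map TSVs, VCF,
# indicator TSVs and ground-truth YAML.

#' Write the environment table (design, periods, soil) as CSV
#' @param environments list of [env_record()] objects.
#' @param path output CSV path.
#' @export
write_environments_csv <- function(environments, path) {
  rows <- lapply(environments, function(e) {
    per <- unlist(lapply(CROP_PERIODS, function(p)
      stats::setNames(as.character(e$periods[[p]]),
                      paste0(p, c("_start", "_end")))))
    c(environment_id = e$environment_id, year = e$year, location = e$location,
      n_regime = e$n_regime, wsc_max = e$wsc_max, per)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an environment table written by [write_environments_csv()]
#' @param path CSV path.
#' @return list of [env_record()] objects.
#' @export
read_environments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    periods <- lapply(CROP_PERIODS, function(p)
      as.Date(c(df[[paste0(p, "_start")]][i], df[[paste0(p, "_end")]][i])))
    names(periods) <- CROP_PERIODS
    env_record(df$environment_id[i], df$year[i], df$location[i],
               df$n_regime[i], periods, df$wsc_max[i])
  })
}

#' Write plot-level phenotypes as CSV
#'
#' Columns follow the interchange schema `genotype_id, environment_id,
#' replicate, sy_q_ha, tsw_g`.
#' @param phenotypes data frame from [generate_phenotypes()].
#' @param path output CSV path.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  out <- data.frame(genotype_id = phenotypes$genotype,
                    environment_id = phenotypes$environment,
                    replicate = phenotypes$replicate,
                    sy_q_ha = phenotypes$sy, tsw_g = phenotypes$tsw)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plot-level phenotypes from CSV
#' @param path CSV path with the [write_phenotypes_csv()] schema.
#' @return data frame with columns `genotype`, `environment`, `replicate`,
#'   `sy`, `tsw`, `sn` (seed number derived as `sy * 100000 / tsw`).
#' @export
read_phenotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(genotype = df$genotype_id, environment = df$environment_id,
                    replicate = df$replicate, sy = df$sy_q_ha, tsw = df$tsw_g)
  out$sn <- seed_number(out$sy, out$tsw)
  out
}

#' Write a dosage matrix and its map as TSVs
#' @param G a [geno_matrix()].
#' @param dosage_path,map_path output TSV paths.
#' @export
write_dosage_tsv <- function(G, dosage_path, map_path) {
  D <- as.data.frame(t(G$dosages))
  D <- cbind(data.frame(snp_id = G$map$snp_id), D)
  utils::write.table(D, dosage_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(G$map, map_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dosage_path)
}

#' Read a dosage matrix + map TSV pair
#' @param dosage_path,map_path TSV paths written by [write_dosage_tsv()].
#' @return a [geno_matrix()].
#' @export
read_dosage_tsv <- function(dosage_path, map_path) {
  D <- utils::read.delim(dosage_path, check.names = FALSE)
  map <- utils::read.delim(map_path)
  M <- t(as.matrix(D[, -1, drop = FALSE]))
  colnames(M) <- D$snp_id
  geno_matrix(M, map)
}

#' Write genotypes as an uncompressed VCF (diploid GT)
#'
#' Integer dosages map to `0/0`, `0/1`, `1/1`; missing to `./.`.
#' Non-integer (imputed) dosages cannot be represented and are rejected.
#' @param G a [geno_matrix()].
#' @param path output `.vcf` path.
#' @export
write_vcf <- function(G, path) {
  D <- G$dosages
  if (any(!is.na(D) & D != round(D)))
    stop_field("G", "VCF output requires integer dosages (write before imputing)")
  gt <- matrix(c("0/0", "0/1", "1/1")[D + 1], nrow(D), ncol(D))
  gt[is.na(D)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(D)), collapse = "\t")), con)
  body <- cbind(as.character(G$map$chromosome), G$map$position,
                as.character(G$map$snp_id), "A", "T", ".", ".", ".", "GT",
                t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a VCF into a dosage matrix
#'
#' Uses \pkg{vcfR} to parse the file; the GT field is converted to counts
#' of the alternate allele.
#' @param path VCF path (may be compressed).
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    out[x %in% c("1/1", "1|1")] <- 2
    out
  }
  D <- apply(gt, 2, count_alt)
  rownames(D) <- rownames(gt)
  map <- data.frame(snp_id = rownames(gt),
                    chromosome = vcfR::getCHROM(v),
                    position = vcfR::getPOS(v))
  geno_matrix(t(D), map)
}

#' Write an indicator matrix as TSV
#' @param X data frame from [build_indicator_matrix()].
#' @param path output TSV path.
#' @export
write_indicator_tsv <- function(X, path) {
  utils::write.table(X, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an indicator matrix TSV
#' @param path TSV path.
#' @export
read_indicator_tsv <- function(path) utils::read.delim(path, check.names = FALSE)

#' Write simulation ground truth as YAML
#' @param truth list (envirotype assignment, QTL, realized fractions, ...).
#' @param path output YAML path.
#' @export
write_ground_truth_yaml <- function(truth, path) {
  # flatten data frames / matrices into plain lists for a readable dump
  simplify <- function(x) {
    if (is.data.frame(x)) return(as.list(x))
    if (is.matrix(x)) return(apply(x, 1, as.list, simplify = FALSE))
    if (is.list(x)) return(lapply(x, simplify))
    x
  }
  yaml::write_yaml(simplify(truth), path)
  invisible(path)
}

#' Write a dendrogram as Newick text
#' @param hc an `hclust` object (e.g. from [cluster_envirotypes()]).
#' @param path output path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the ape package", call. = FALSE)
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
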