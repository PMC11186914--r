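#' Split accessions by seed glucosinolate content
#'
#' Accessions with a GSL measurement strictly greater than the threshold go
#' to `"GSL+"`, the rest to `"GSL-"`. Accessions with a missing measurement
#' are excluded with a warning.
#'
#' @param metadata data frame with columns `accession_id` and
#'   `gsl_umol_g` (seed glucosinolate content in umol/g).
#' @param threshold split point in umol/g (default 18).
#' @return data frame `accession_id`, `population`.
#' @export
split_by_gsl <- function(metadata, threshold = 18) {
  if (!all(c("accession_id", "gsl_umol_g") %in% names(metadata)))
    stop_field("metadata", "needs columns accession_id, gsl_umol_g")
  miss <- is.na(metadata$gsl_umol_g)
  if (any(miss))
    warning(sprintf("%d accession(s) without GSL measurement excluded", sum(miss)))
  m <- metadata[!miss, , drop = FALSE]
  data.frame(accession_id = m$accession_id,
             population = ifelse(m$gsl_umol_g > threshold, "GSL+", "GSL-"),
             stringsAsFactors = FALSE)
}

#' Per-site nucleotide diversity
#'
#' Unbiased pairwise-difference estimator `pi = 2 p (1 - p) n / (n - 1)`
#' with `p = c / n`, where `c` is the alternate allele count and `n` the
#' number of called alleles.
#'
#' @param c alternate allele count.
#' @param n total called alleles (>= 2).
#' @return per-site pi.
#' @export
site_pi <- function(c, n) {
  if (any(n < 2)) stop_field("n", "needs at least 2 called alleles")
  p <- c / n
  2 * p * (1 - p) * n / (n - 1)
}

# Per-variant pi for a dosage matrix (rows = accessions), honouring missing
# calls: n = 2 x number of non-missing genotypes at the site.
site_pi_matrix <- function(D) {
  n_called <- 2 * colSums(!is.na(D))
  cnt <- colSums(D, na.rm = TRUE)
  ifelse(n_called >= 2, 2 * (cnt / n_called) * (1 - cnt / n_called) *
           n_called / (n_called - 1), NA_real_)
}

# Window assignment over half-open [start, end) tiles of width window_bp.
window_index <- function(position, window_bp) floor(position / window_bp)

#' Windowed nucleotide diversity
#'
#' Per-window pi is the sum of per-site pi over the variants in the window
#' divided by the window width in bp (invariant sites count as zero
#' diversity). Chromosome and genome means divide the summed site pi by the
#' total bp covered by that chromosome's windows.
#'
#' @param G a [geno_matrix()] for one population (missing calls reduce the
#'   allele count at a site).
#' @param window_bp window width in bp (> 0), default 10 kb.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   defaults to the last window containing a variant.
#' @return list with `windows` (data frame `chromosome`, `start`, `end`,
#'   `n_variants`, `pi`), `chromosomes` (`chromosome`, `covered_bp`, `pi`)
#'   and `genome` (single per-bp value).
#' @export
windowed_pi <- function(G, window_bp = 10000, chrom_lengths = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (window_bp <= 0) stop_field("window_bp", "must be > 0")
  sp <- site_pi_matrix(G$dosages)
  map <- G$map
  win_rows <- list(); chr_rows <- list()
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    len <- if (!is.null(chrom_lengths) && as.character(ch) %in% names(chrom_lengths))
      chrom_lengths[[as.character(ch)]] else max(map$position[idx]) + 1
    n_win <- ceiling(len / window_bp)
    wi <- window_index(map$position[idx], window_bp)
    pi_sum <- vapply(0:(n_win - 1), function(w) sum(sp[idx][wi == w], na.rm = TRUE), 0)
    n_var <- vapply(0:(n_win - 1), function(w) sum(wi == w), 0)
    win_rows[[as.character(ch)]] <- data.frame(
      chromosome = ch, start = (0:(n_win - 1)) * window_bp,
      end = (1:n_win) * window_bp, n_variants = as.integer(n_var),
      pi = pi_sum / window_bp)
    chr_rows[[as.character(ch)]] <- data.frame(
      chromosome = ch, covered_bp = n_win * window_bp,
      pi = sum(sp[idx], na.rm = TRUE) / (n_win * window_bp))
  }
  windows <- do.call(rbind, win_rows); rownames(windows) <- NULL
  chromosomes <- do.call(rbind, chr_rows); rownames(chromosomes) <- NULL
  genome <- sum(chromosomes$pi * chromosomes$covered_bp) / sum(chromosomes$covered_bp)
  list(windows = windows, chromosomes = chromosomes, genome = genome)
}

#' Weir-Cockerham F_ST at one site
#'
#' The two-population variance-components estimator of Weir & Cockerham
#' (1984): from per-population sample sizes, allele frequencies and
#' observed heterozygosities it forms the among-population (a), among
#' individuals within populations (b) and within-individual (c) components,
#' and `theta = a / (a + b + c)`.
#'
#' @param d1,d2 dosage vectors (0/1/2, `NA` = missing) for the two
#'   populations at one site.
#' @return list with `a`, `b`, `c`, `theta` (`theta` is `NA` when
#'   `a + b + c == 0`, i.e. the site is monomorphic overall).
#' @export
wc_fst_site <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  if (length(d1) < 2 || length(d2) < 2)
    stop_field("d1", "needs >= 2 non-missing diploid genotypes per population")
  r <- 2
  n_i <- c(length(d1), length(d2))
  p_i <- c(mean(d1) / 2, mean(d2) / 2)
  h_i <- c(mean(d1 == 1), mean(d2 == 1))
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- n_bar / n_c * (s2 - 1 / (n_bar - 1) *
                        (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (abs(denom) < 1e-300 || denom == 0) NA_real_ else a / denom)
}

#' Windowed mean Weir-Cockerham F_ST between two populations
#'
#' Per-site theta-hat is computed at every site polymorphic over the pooled
#' sample; window, chromosome and genome values are the unweighted
#' arithmetic mean of per-site estimates (the `weighted` columns give the
#' ratio-of-sums variant, `sum(a) / sum(a + b + c)`).
#'
#' @param G a [geno_matrix()] holding both populations.
#' @param split data frame `accession_id`, `population` (exactly two
#'   population labels, each with >= 2 members present in `G`).
#' @param window_bp window width in bp, default 10 kb.
#' @param chrom_lengths optional named chromosome lengths (bp).
#' @return list with `windows` (`chromosome`, `start`, `end`, `n_sites`,
#'   `mean_fst`, `weighted_fst`), `chromosomes`, `genome` (one-row data
#'   frame `mean_fst`, `weighted_fst`, `n_sites`).
#' @export
windowed_mean_fst <- function(G, split, window_bp = 10000, chrom_lengths = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  pops <- sort(unique(split$population))
  if (length(pops) != 2) stop_field("split", "exactly two populations required")
  acc <- rownames(G$dosages)
  a1 <- intersect(acc, split$accession_id[split$population == pops[1]])
  a2 <- intersect(acc, split$accession_id[split$population == pops[2]])
  if (length(a1) < 2 || length(a2) < 2)
    stop_field("split", "both populations need >= 2 genotyped members")
  D1 <- G$dosages[a1, , drop = FALSE]
  D2 <- G$dosages[a2, , drop = FALSE]
  pooled <- rbind(D1, D2)
  poly <- apply(pooled, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) >= 2 && stats::var(v) > 0
  })
  if (!any(poly)) {
    warning("no polymorphic sites; empty F_ST output")
    return(list(windows = NULL, chromosomes = NULL,
                genome = data.frame(mean_fst = NA_real_, weighted_fst = NA_real_,
                                    n_sites = 0L)))
  }
  comp <- vapply(which(poly), function(j) {
    w <- wc_fst_site(D1[, j], D2[, j])
    c(a = w$a, abc = w$a + w$b + w$c, theta = w$theta)
  }, c(a = 0, abc = 0, theta = 0))
  keep <- which(poly)[!is.na(comp["theta", ])]
  comp <- comp[, !is.na(comp["theta", ]), drop = FALSE]
  map <- G$map[keep, , drop = FALSE]
  agg <- function(sel) {
    data.frame(n_sites = length(sel),
               mean_fst = mean(comp["theta", sel]),
               weighted_fst = sum(comp["a", sel]) / sum(comp["abc", sel]))
  }
  win_rows <- list(); chr_rows <- list()
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    wi <- window_index(map$position[idx], window_bp)
    for (w in sort(unique(wi))) {
      sel <- idx[wi == w]
      win_rows[[length(win_rows) + 1L]] <- cbind(
        data.frame(chromosome = ch, start = w * window_bp,
                   end = (w + 1) * window_bp), agg(sel))
    }
    chr_rows[[length(chr_rows) + 1L]] <- cbind(data.frame(chromosome = ch),
                                               agg(idx))
  }
  windows <- do.call(rbind, win_rows)
  chromosomes <- do.call(rbind, chr_rows)
  genome <- agg(seq_len(ncol(comp)))
  list(windows = windows, chromosomes = chromosomes, genome = genome)
}

#' Per-chromosome diversity summary for two populations
#'
#' Convenience wrapper producing the per-chromosome and genome-wide table
#' of mean nucleotide diversity for the whole panel and for each
#' sub-population, together with the mean F_ST between them.
#'
#' @inheritParams windowed_mean_fst
#' @return data frame with one row per chromosome plus a `"genome"` row:
#'   `chromosome`, `pi_all`, `pi_pop1`, `pi_pop2`, `mean_fst`.
#' @export
diversity_summary <- function(G, split, window_bp = 10000, chrom_lengths = NULL) {
  pops <- sort(unique(split$population))
  acc <- rownames(G$dosages)
  sub <- function(ids) geno_matrix(G$dosages[intersect(acc, ids), , drop = FALSE], G$map)
  pi_all <- windowed_pi(G, window_bp, chrom_lengths)
  pi_1 <- windowed_pi(sub(split$accession_id[split$population == pops[1]]),
                      window_bp, chrom_lengths)
  pi_2 <- windowed_pi(sub(split$accession_id[split$population == pops[2]]),
                      window_bp, chrom_lengths)
  fst <- windowed_mean_fst(G, split, window_bp, chrom_lengths)
  chrom <- data.frame(
    chromosome = as.character(pi_all$chromosomes$chromosome),
    pi_all = pi_all$chromosomes$pi,
    pi_pop1 = pi_1$chromosomes$pi,
    pi_pop2 = pi_2$chromosomes$pi,
    mean_fst = fst$chromosomes$mean_fst[
      match(pi_all$chromosomes$chromosome, fst$chromosomes$chromosome)])
  rbind(chrom,
        data.frame(chromosome = "genome", pi_all = pi_all$genome,
                   pi_pop1 = pi_1$genome, pi_pop2 = pi_2$genome,
                   mean_fst = fst$genome$mean_fst))
}
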