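#' Merge significant SNPs across scans into QTL regions
#'
#' Within each scan (one trait at one scale/group), significant SNPs
#' (`neglog10p >= t`) on the same chromosome are chained while consecutive
#' gaps stay within `gap_bp`, forming intervals. Intervals from different
#' scans or traits that overlap on the same chromosome are merged into one
#' named region carrying the union interval and all of its detections. The
#' peak SNP is the globally most significant SNP of the region.
#'
#' @param scans a single data frame or list of [lmm_scan()] outputs, each
#'   carrying (or augmented with) columns `scale` (`"environment"`,
#'   `"envirotype"` or `"MET"`), `group` (scan unit label) and `trait`.
#' @param t significance threshold on the -log10 p scale.
#' @param gap_bp maximum gap between chained significant SNPs (default 500
#'   kb).
#' @return data frame of regions (class `qtl_regions`): `name`,
#'   `chromosome`, `start`, `end`, `traits`, `n_detections`, `peak_snp`,
#'   `peak_neglog10p`, `peak_r2`, `peak_beta`, `favorable_allele`, plus a
#'   `detections` list-column of per-region data frames
#'   (`scale`, `group`, `trait`). Empty input gives zero rows.
#' @export
merge_qtl_regions <- function(scans, t, gap_bp = 500000) {
  if (is.data.frame(scans)) scans <- list(scans)
  need <- c("snp_id", "chromosome", "position", "neglog10p", "scale", "group", "trait")
  all_hits <- do.call(rbind, lapply(scans, function(s) {
    s <- as.data.frame(s)
    miss <- setdiff(need, names(s))
    if (length(miss))
      stop_field("scans", paste("scan lacks column(s):", paste(miss, collapse = ", ")))
    s[s$neglog10p >= t, , drop = FALSE]
  }))
  empty <- data.frame(name = character(), chromosome = character(),
                      start = numeric(), end = numeric(), traits = character(),
                      n_detections = integer(), peak_snp = character(),
                      peak_neglog10p = numeric(), peak_r2 = numeric(),
                      peak_beta = numeric(), favorable_allele = character(),
                      stringsAsFactors = FALSE)
  empty$detections <- list()
  if (is.null(all_hits) || !nrow(all_hits)) return(structure(empty, class = c("qtl_regions", "data.frame")))

  # stage 1: within-scan chaining into intervals
  unit_key <- interaction(all_hits$scale, all_hits$group, all_hits$trait,
                          all_hits$chromosome, drop = TRUE)
  intervals <- do.call(rbind, lapply(split(all_hits, unit_key), function(h) {
    h <- h[order(h$position), , drop = FALSE]
    brk <- c(0, cumsum(diff(h$position) > gap_bp))
    do.call(rbind, lapply(split(h, brk), function(seg) {
      data.frame(chromosome = seg$chromosome[1],
                 start = min(seg$position), end = max(seg$position),
                 scale = seg$scale[1], group = seg$group[1],
                 trait = seg$trait[1], stringsAsFactors = FALSE)
    }))
  }))

  # stage 2: union of overlapping intervals per chromosome
  regions <- list()
  for (ch in sort(unique(as.character(intervals$chromosome)))) {
    iv <- intervals[intervals$chromosome == ch, , drop = FALSE]
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    cur_start <- iv$start[1]; cur_end <- iv$end[1]; members <- 1L
    flush <- function(s, e, m) {
      det <- unique(iv[m, c("scale", "group", "trait"), drop = FALSE])
      rownames(det) <- NULL
      hits <- all_hits[all_hits$chromosome == ch &
                       all_hits$position >= s & all_hits$position <= e, , drop = FALSE]
      peak <- hits[which.max(hits$neglog10p), , drop = FALSE]
      fav <- NA_character_
      if (nrow(peak) && !is.null(peak$beta) && !is.null(peak$alt_freq) &&
          is.finite(peak$beta) && is.finite(peak$alt_freq)) {
        # favorable allele = the trait-increasing allele; with dosages
        # coding the alternate allele, beta > 0 means the alternate allele
        # is favorable; report it as major/minor by frequency
        fav_freq <- if (peak$beta > 0) peak$alt_freq else 1 - peak$alt_freq
        fav <- if (fav_freq >= 0.5) "major" else "minor"
      }
      data.frame(chromosome = ch, start = s, end = e,
                 traits = paste(sort(unique(det$trait)), collapse = "/"),
                 n_detections = nrow(det),
                 peak_snp = if (nrow(peak)) as.character(peak$snp_id) else NA_character_,
                 peak_neglog10p = if (nrow(peak)) peak$neglog10p else NA_real_,
                 peak_r2 = if (nrow(peak) && !is.null(peak$r2)) peak$r2 else NA_real_,
                 peak_beta = if (nrow(peak) && !is.null(peak$beta)) peak$beta else NA_real_,
                 favorable_allele = fav,
                 detections = I(list(det)), stringsAsFactors = FALSE)
    }
    if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
      if (iv$start[i] <= cur_end) {
        cur_end <- max(cur_end, iv$end[i]); members <- c(members, i)
      } else {
        regions[[length(regions) + 1L]] <- flush(cur_start, cur_end, members)
        cur_start <- iv$start[i]; cur_end <- iv$end[i]; members <- i
      }
    }
    regions[[length(regions) + 1L]] <- flush(cur_start, cur_end, members)
  }
  out <- do.call(rbind, regions)
  # region names: Q<chromosome><letter> in position order within chromosome
  out <- out[order(as.character(out$chromosome), out$start), , drop = FALSE]
  idx_in_chrom <- stats::ave(seq_len(nrow(out)), as.character(out$chromosome),
                             FUN = seq_along)
  out$name <- paste0("Q", out$chromosome, letters[idx_in_chrom])
  rownames(out) <- NULL
  out <- out[, c("name", "chromosome", "start", "end", "traits",
                 "n_detections", "peak_snp", "peak_neglog10p", "peak_r2",
                 "peak_beta", "favorable_allele", "detections")]
  structure(out, class = c("qtl_regions", "data.frame"))
}

#' Classify a QTL region as stable, interactive or environment-specific
#'
#' A region is *stable* when it is detected at the MET scale or for at
#' least two envirotypes; *interactive* when it is detected for exactly one
#' envirotype and not at the MET scale; *environment-specific* when it is
#' detected only at the environment scale.
#'
#' @param detections data frame with columns `scale` and `group` (one row
#'   per detection), or a one-row slice of [merge_qtl_regions()] output.
#' @return `"stable"`, `"interactive"` or `"environment-specific"`.
#' @export
classify_stability <- function(detections) {
  if (is.data.frame(detections) && "detections" %in% names(detections)) {
    stopifnot(nrow(detections) == 1L)
    detections <- detections$detections[[1]]
  }
  if (!nrow(detections)) stop_field("detections", "must be non-empty")
  met <- any(detections$scale == "MET")
  n_envirotypes <- length(unique(detections$group[detections$scale == "envirotype"]))
  if (met || n_envirotypes >= 2) return("stable")
  if (n_envirotypes == 1) return("interactive")
  "environment-specific"
}

#' Classify every region of a merged region table
#'
#' @param regions output of [merge_qtl_regions()].
#' @return the table with a `classification` column appended.
#' @export
classify_regions <- function(regions) {
  regions$classification <- vapply(regions$detections, classify_stability, "")
  regions
}
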