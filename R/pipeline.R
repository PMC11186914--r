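#' Synthetic accession metadata (seed glucosinolate content)
#'
#' Draws a seed glucosinolate content for every accession so the
#' diversity stage can split the panel: roughly a quarter of the panel
#' (older, high-GSL material) above the 18 umol/g threshold, the rest
#' below it, mirroring the composition of a diversity panel spanning
#' pre- and post-quality-breeding germplasm.
#'
#' @param config a [sim_config()].
#' @param prop_high fraction of high-GSL accessions.
#' @return data frame `accession_id`, `gsl_umol_g`.
#' @export
generate_accession_metadata <- function(config, prop_high = 0.27) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 505L), {
    n <- config$n_accessions
    high <- stats::runif(n) < prop_high
    data.frame(accession_id = sprintf("A%03d", seq_len(n)),
               gsl_umol_g = ifelse(high, stats::runif(n, 25, 70),
                                   stats::runif(n, 4, 15)))
  })
}

#' Enumerate the scan units of a multi-scale analysis
#'
#' Yields one MET-wide unit, one unit per envirotype and one unit per
#' environment; each unit names the environments whose plots feed the BLUE
#' computation and GWAS scan at that scale.
#'
#' @param environment_ids character vector of environment ids.
#' @param assignment data frame `environment_id`, `envirotype` covering all
#'   ids.
#' @return data frame `scale`, `group` with a list-column `environments`.
#' @export
scale_dispatch <- function(environment_ids, assignment) {
  environment_ids <- sort(unique(as.character(environment_ids)))
  et <- assignment$envirotype[match(environment_ids, assignment$environment_id)]
  if (anyNA(et)) stop_field("assignment", "must cover every environment")
  units <- list(data.frame(scale = "MET", group = "MET",
                           environments = I(list(environment_ids))))
  for (e in sort(unique(et))) {
    units[[length(units) + 1L]] <- data.frame(
      scale = "envirotype", group = e,
      environments = I(list(environment_ids[et == e])))
  }
  for (id in environment_ids) {
    units[[length(units) + 1L]] <- data.frame(
      scale = "environment", group = id, environments = I(list(id)))
  }
  do.call(rbind, units)
}

#' Configure an end-to-end pipeline run
#'
#' @param sim a [sim_config()] describing the synthetic MET (simulation
#'   mode is the only input mode bundled with the package; stage inputs can
#'   also be produced externally and fed to the stage functions directly).
#' @param outdir output directory.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "indicators", "envirotype", "blues", "gwas",
#'   "classify", "diversity")`; stages depend on their predecessors.
#' @param traits traits to analyse (`"sy"` and/or `"sn"`).
#' @param maf_min,missing_max SNP filters.
#' @param alpha_g genome-wide error rate for the significance threshold.
#' @param block_size,cld_fraction effective-test computation parameters.
#' @param gap_bp chaining gap for region merging.
#' @param window_bp diversity window width.
#' @param gsl_threshold glucosinolate split point (umol/g).
#' @param k number of envirotypes for clustering (`NULL` = choose by the
#'   inertia-gain elbow).
#' @param seed master seed (overrides `sim$seed` when given).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(), outdir = tempfile("metrun"),
                            stages = c("simulate", "indicators", "envirotype",
                                       "blues", "gwas", "classify", "diversity"),
                            traits = "sy", maf_min = 0.025, missing_max = 0.10,
                            alpha_g = 0.1, block_size = 1000,
                            cld_fraction = 0.995, gap_bp = 500000,
                            window_bp = 10000, gsl_threshold = 18, k = NULL,
                            seed = NULL) {
  if (!is.null(seed)) {
    sim$seed <- check_count(seed, "seed", 0L)
  }
  known <- c("simulate", "indicators", "envirotype", "blues", "gwas",
             "classify", "diversity")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_field("stages", paste("unknown stage(s):", paste(bad, collapse = ", ")))
  structure(list(sim = sim, outdir = outdir, stages = stages, traits = traits,
                 maf_min = maf_min, missing_max = missing_max,
                 alpha_g = alpha_g, block_size = block_size,
                 cld_fraction = cld_fraction, gap_bp = gap_bp,
                 window_bp = window_bp, gsl_threshold = gsl_threshold, k = k),
            class = "pipeline_config")
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full envirotyping-to-QTL pipeline on a synthetic MET
#'
#' Executes the requested stages in dependency order - simulate the MET,
#' compute and impute environmental indicators, select limiting factors
#' and cluster envirotypes, compute BLUEs at the three scales, scan for
#' QTL with LOCO-kinship mixed models, merge and classify regions, and run
#' the glucosinolate-split diversity analysis - writing every output under
#' `config$outdir` and returning a manifest with a checksum per file.
#' Re-running with an identical configuration (including the seed)
#' reproduces identical files and checksums.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (data frame `file`, `md5`), `parameters`,
#'   and the in-memory stage results (`assignment`, `regions`, `scans`,
#'   `threshold`, `m_eff`, `diversity`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "pipeline.log")
  con <- file(logfile, "w")
  on.exit(close(con))
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)
  res <- list(parameters = unclass(config)[setdiff(names(config), "sim")])
  stages <- config$stages
  t0 <- Sys.time()

  run_stage <- function(stage, code) {
    if (!stage %in% stages) return(invisible(NULL))
    pipeline_log(con, stage, "start")
    t1 <- Sys.time()
    out <- tryCatch(code, error = function(e)
      stop(sprintf("stage %s failed: %s", stage, conditionMessage(e)), call. = FALSE))
    pipeline_log(con, stage, sprintf("done in %.1fs",
                                     as.numeric(Sys.time() - t1, units = "secs")))
    out
  }

  # --- simulate ------------------------------------------------------------
  sim_out <- run_stage("simulate", {
    met <- generate_met(config$sim)
    G <- generate_genotypes(config$sim)
    ph <- generate_phenotypes(G, met$truth$envirotype, config$sim)
    meta <- generate_accession_metadata(config$sim)
    emit(write_environments_csv(met$environments,
                                file.path(config$outdir, "environments.csv")))
    w <- met$weather
    w$date <- as.character(w$date)
    utils::write.csv(w, file.path(config$outdir, "weather.csv"),
                     row.names = FALSE, quote = FALSE)
    emit(file.path(config$outdir, "weather.csv"))
    sup <- met$management$supplies
    sup$supply_date <- as.character(sup$supply_date)
    utils::write.csv(sup, file.path(config$outdir, "management_supplies.csv"),
                     row.names = FALSE, quote = FALSE)
    emit(file.path(config$outdir, "management_supplies.csv"))
    utils::write.csv(met$management$measured,
                     file.path(config$outdir, "management_measured.csv"),
                     row.names = FALSE, quote = FALSE)
    emit(file.path(config$outdir, "management_measured.csv"))
    emit(write_phenotypes_csv(ph$phenotypes,
                              file.path(config$outdir, "phenotypes.csv")))
    emit(write_vcf(G, file.path(config$outdir, "genotypes.vcf")))
    emit(write_dosage_tsv(G, file.path(config$outdir, "dosages.tsv"),
                          file.path(config$outdir, "map.tsv")))
    emit(file.path(config$outdir, "map.tsv"))
    utils::write.csv(meta, file.path(config$outdir, "accessions.csv"),
                     row.names = FALSE, quote = FALSE)
    emit(file.path(config$outdir, "accessions.csv"))
    emit(write_ground_truth_yaml(
      list(envirotype = met$truth$envirotype,
           qtl = ph$truth$qtl,
           realized_fractions = as.list(ph$truth$realized_fractions)),
      file.path(config$outdir, "ground_truth.yaml")))
    list(met = met, G = G, ph = ph, meta = meta)
  })
  if (is.null(sim_out)) stop("run_pipeline currently requires the simulate stage")
  met <- sim_out$met; G <- sim_out$G
  phen <- sim_out$ph$phenotypes
  phen$sn <- seed_number(phen$sy, phen$tsw)

  # --- indicators ----------------------------------------------------------
  Ximp <- run_stage("indicators", {
    X <- build_indicator_matrix(met$environments, met$weather, met$management)
    emit(write_indicator_tsv(X, file.path(config$outdir, "indicators_raw.tsv")))
    Ximp <- impute_indicator_matrix(X)
    emit(write_indicator_tsv(Ximp, file.path(config$outdir, "indicators.tsv")))
    Ximp
  })

  # --- envirotype ----------------------------------------------------------
  assignment <- NULL
  if ("envirotype" %in% stages) {
    env_res <- run_stage("envirotype", {
      env_mean <- tapply(phen$sy, phen$environment, mean)
      y <- as.numeric(env_mean[Ximp$environment_id])
      # indicators constant across the MET carry no information for the
      # regression; drop them before selection
      keep <- vapply(Ximp[, -1, drop = FALSE], function(v) stats::sd(v) > 0,
                     TRUE)
      if (any(!keep))
        pipeline_log(con, "envirotype",
                     paste("dropping constant indicator(s):",
                           paste(names(keep)[!keep], collapse = ", ")))
      sel <- select_limiting_factors(Ximp[, -1, drop = FALSE][, keep, drop = FALSE],
                                     y, seed = derive_seed(config$sim$seed, 606L))
      utils::write.table(sel$trace, file.path(config$outdir, "selection_trace.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      emit(file.path(config$outdir, "selection_trace.tsv"))
      Zsel <- Ximp[, c("environment_id", sel$selected)]
      cl <- cluster_envirotypes(Zsel, k = config$k)
      utils::write.table(cl$assignment, file.path(config$outdir, "envirotypes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      emit(file.path(config$outdir, "envirotypes.tsv"))
      prof <- envirotype_profiles(Zsel, cl$assignment)
      utils::write.table(cbind(group = rownames(prof), as.data.frame(prof)),
                         file.path(config$outdir, "profiles.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      emit(file.path(config$outdir, "profiles.tsv"))
      if (requireNamespace("ape", quietly = TRUE)) {
        emit(write_dendrogram_newick(cl$hclust,
                                     file.path(config$outdir, "dendrogram.nwk")))
      }
      list(selection = sel, clustering = cl)
    })
    assignment <- env_res$clustering$assignment
    res$selection <- env_res$selection
    res$clustering <- env_res$clustering
  }
  if (is.null(assignment)) assignment <- met$truth$envirotype
  res$assignment <- assignment

  # --- blues ---------------------------------------------------------------
  blues_units <- run_stage("blues", {
    units <- scale_dispatch(unique(phen$environment), assignment)
    rows <- list()
    for (trait in config$traits) {
      for (u in seq_len(nrow(units))) {
        envs <- units$environments[[u]]
        sub <- phen[phen$environment %in% envs, , drop = FALSE]
        if (units$scale[u] == "environment") {
          b <- blues_single_env(sub, trait = trait)
          h2 <- b$h2
        } else {
          b <- blues_group(sub, trait = trait, compute_components = FALSE)
          h2 <- NA_real_
        }
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(scale = units$scale[u], group = units$group[u],
                     trait = trait), b$blues, h2 = h2)
      }
    }
    blues <- do.call(rbind, rows)
    utils::write.table(blues, file.path(config$outdir, "blues.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    emit(file.path(config$outdir, "blues.tsv"))
    blues
  })
  res$blues <- blues_units

  # --- gwas ----------------------------------------------------------------
  scans <- NULL
  if ("gwas" %in% stages) {
    gw <- run_stage("gwas", {
      Gf <- impute_dosages(filter_snps(G, config$maf_min, config$missing_max))
      kin <- loco_kinships(Gf)
      m_eff <- effective_tests(Gf, config$block_size, config$cld_fraction)
      thr <- significance_threshold(config$alpha_g, m_eff)
      units <- scale_dispatch(unique(phen$environment), assignment)
      scan_rows <- list()
      for (trait in config$traits) {
        for (u in seq_len(nrow(units))) {
          b <- blues_units[blues_units$scale == units$scale[u] &
                             blues_units$group == units$group[u] &
                             blues_units$trait == trait, ]
          sc <- lmm_scan(b, Gf, kin)
          sc$scale <- units$scale[u]; sc$group <- units$group[u]
          sc$trait <- trait
          scan_rows[[length(scan_rows) + 1L]] <- sc
        }
      }
      scans <- do.call(rbind, scan_rows)
      utils::write.table(
        scans[, c("snp_id", "chromosome", "position", "scale", "group",
                  "trait", "beta", "se", "neglog10p")],
        file.path(config$outdir, "scans.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      emit(file.path(config$outdir, "scans.tsv"))
      list(scans = scans, m_eff = m_eff, threshold = thr, G = Gf)
    })
    scans <- gw$scans
    res$m_eff <- gw$m_eff
    res$threshold <- gw$threshold
  }

  # --- classify ------------------------------------------------------------
  if ("classify" %in% stages && !is.null(scans)) {
    regions <- run_stage("classify", {
      reg <- classify_regions(merge_qtl_regions(scans, res$threshold,
                                                config$gap_bp))
      flat <- reg[, setdiff(names(reg), "detections")]
      flat$detections <- vapply(reg$detections, function(d)
        paste(paste0(d$scale, ":", d$group), collapse = ";"), "")
      utils::write.table(flat, file.path(config$outdir, "qtl_regions.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      emit(file.path(config$outdir, "qtl_regions.tsv"))
      reg
    })
    res$regions <- regions
  }

  # --- diversity -----------------------------------------------------------
  if ("diversity" %in% stages) {
    div <- run_stage("diversity", {
      split <- split_by_gsl(
        data.frame(accession_id = sim_out$meta$accession_id,
                   gsl_umol_g = sim_out$meta$gsl_umol_g),
        config$gsl_threshold)
      summ <- diversity_summary(G, split, config$window_bp)
      utils::write.table(summ, file.path(config$outdir, "diversity_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      emit(file.path(config$outdir, "diversity_summary.tsv"))
      fst <- windowed_mean_fst(G, split, config$window_bp)
      utils::write.table(fst$windows, file.path(config$outdir, "fst_windows.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      emit(file.path(config$outdir, "fst_windows.tsv"))
      list(split = split, summary = summ, fst = fst)
    })
    res$diversity <- div
  }

  pipeline_log(con, "pipeline", sprintf("finished in %.1fs",
                                        as.numeric(Sys.time() - t0, units = "secs")))
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(config$outdir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  res$manifest <- manifest
  res
}
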