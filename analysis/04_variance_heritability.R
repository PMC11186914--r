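#!/usr/bin/env Rscript
# Fit the mixed models at the three scales: the envirotype-aware variance
# partition of the whole MET, the plain MET model with heritability, the
# per-envirotype partitions, the per-environment heritabilities, and the
# genotype BLUEs that feed the association scans.

source(file.path("analysis", "_config.R"))

phen <- read_phenotypes_csv(file.path(DATA_DIR, "phenotypes.csv"))
asg <- utils::read.delim(file.path(RESULTS_DIR, "envirotypes.tsv"))

## Envirotype-aware partition of the full MET
part <- envirotype_partition(phen, asg, trait = "sy")
cat("Envirotype-aware variance partition of seed yield (% of total):\n")
print(round(part$percentages, 1))
cat(sprintf("Envirotype share of environmental variance: %.1f%%\n",
            part$env_share))
cat(sprintf("G x envirotype share of the interaction: %.1f%%\n", part$gxe_share))
write_tsv(data.frame(term = names(part$percentages),
                     pct = round(part$percentages, 2)),
          "variance_partition_envirotype_model.tsv")

## Plain MET model, per-envirotype models, heritabilities
rows <- list()
met_fit <- blues_group(phen, trait = "sy")
rows[[1]] <- data.frame(group = "MET", n_env = met_fit$e,
                        t(round(met_fit$percentages, 1)),
                        h2 = round(met_fit$h2, 2))
for (e in sort(unique(asg$envirotype))) {
  envs <- asg$environment_id[asg$envirotype == e]
  sub <- phen[phen$environment %in% envs, ]
  fit_e <- blues_group(sub, trait = "sy")
  rows[[length(rows) + 1]] <- data.frame(group = e, n_env = fit_e$e,
                                         t(round(fit_e$percentages, 1)),
                                         h2 = round(fit_e$h2, 2))
}
scale_tab <- do.call(rbind, rows)
write_tsv(scale_tab, "variance_heritability_by_scale.tsv")
cat("\nVariance percentages and h2 by scale:\n")
print(scale_tab, row.names = FALSE)

## Per-environment heritabilities and BLUEs at all scales
units <- scale_dispatch(unique(phen$environment), asg)
blue_rows <- h2_rows <- list()
for (u in seq_len(nrow(units))) {
  sub <- phen[phen$environment %in% units$environments[[u]], ]
  b <- if (units$scale[u] == "environment") blues_single_env(sub, "sy")
       else blues_group(sub, "sy", compute_components = FALSE)
  blue_rows[[u]] <- cbind(data.frame(scale = units$scale[u],
                                     group = units$group[u], trait = "sy"),
                          b$blues)
  if (units$scale[u] == "environment")
    h2_rows[[length(h2_rows) + 1]] <- data.frame(environment = units$group[u],
                                                 h2 = round(b$h2, 2))
}
write_tsv(do.call(rbind, blue_rows), "blues.tsv")
h2_env <- do.call(rbind, h2_rows)
write_tsv(h2_env, "heritability_by_environment.tsv")
cat(sprintf("\nPer-environment h2: %.2f-%.2f (median %.2f)\n",
            min(h2_env$h2), max(h2_env$h2), stats::median(h2_env$h2)))
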