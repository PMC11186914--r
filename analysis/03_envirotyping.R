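#!/usr/bin/env Rscript
# Identify the limiting factors by PLS regression of per-environment mean
# seed yield on the indicators, cluster the environments into envirotypes
# and write the assignments and the 0-10 limiting-factor profiles.

source(file.path("analysis", "_config.R"))

Xi <- read_indicator_tsv(file.path(RESULTS_DIR, "indicators.tsv"))
phen <- read_phenotypes_csv(file.path(DATA_DIR, "phenotypes.csv"))
truth <- yaml::read_yaml(file.path(DATA_DIR, "ground_truth.yaml"))

env_mean <- tapply(phen$sy, phen$environment, mean)
y <- as.numeric(env_mean[Xi$environment_id])

keep <- vapply(Xi[, -1], function(v) stats::sd(v) > 0, TRUE)
sel <- select_limiting_factors(Xi[, -1][, keep], y, seed = DEMO_SEED)
write_tsv(sel$trace, "selection_trace.tsv")
cat(sprintf("Retained %d of %d indicators (%d PLS components):\n  %s\n",
            length(sel$selected), sum(keep), sel$n_components,
            paste(sel$selected, collapse = ", ")))

fit <- fit_pls1(as.matrix(Xi[, sel$selected]), y,
                min(sel$n_components, length(sel$selected)))
cat(sprintf("PLS fit on the retained set: R2 = %.2f, RMSE = %.2f q/ha\n",
            fit$r2, fit$rmse))

Zsel <- Xi[, c("environment_id", sel$selected)]
cl <- cluster_envirotypes(Zsel)
write_tsv(cl$assignment, "envirotypes.tsv")
write_tsv(cl$inertia_gain, "inertia_gain.tsv")
if (requireNamespace("ape", quietly = TRUE))
  write_dendrogram_newick(cl$hclust, file.path(RESULTS_DIR, "dendrogram.nwk"))

prof <- envirotype_profiles(Zsel, cl$assignment)
write_tsv(cbind(group = rownames(prof), as.data.frame(prof)), "profiles.tsv")

tab <- table(cl$assignment$envirotype,
             unlist(truth$envirotype$envirotype))
cat(sprintf("Chose k = %d envirotypes; confusion against generator truth:\n",
            cl$k))
print(tab)
sy_by_env <- tapply(phen$sy, cl$assignment$envirotype[
  match(phen$environment, cl$assignment$environment_id)], mean)
cat("Mean seed yield per envirotype (q/ha):\n")
print(round(sy_by_env, 1))
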