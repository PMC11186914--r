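#!/usr/bin/env Rscript
# Simulate the demonstration MET and write every raw input to results/data/:
# trial design, daily weather, nitrogen management, plot phenotypes,
# genotypes (VCF + dosage TSV) and the generator ground truth.

source(file.path("analysis", "_config.R"))

cfg <- demo_sim_config()
met <- generate_met(cfg)
G <- generate_genotypes(cfg)
ph <- generate_phenotypes(G, met$truth$envirotype, cfg)
meta <- generate_accession_metadata(cfg)

write_environments_csv(met$environments, file.path(DATA_DIR, "environments.csv"))
w <- met$weather; w$date <- as.character(w$date)
utils::write.csv(w, file.path(DATA_DIR, "weather.csv"), row.names = FALSE,
                 quote = FALSE)
sup <- met$management$supplies; sup$supply_date <- as.character(sup$supply_date)
utils::write.csv(sup, file.path(DATA_DIR, "management_supplies.csv"),
                 row.names = FALSE, quote = FALSE)
utils::write.csv(met$management$measured,
                 file.path(DATA_DIR, "management_measured.csv"),
                 row.names = FALSE, quote = FALSE)
write_phenotypes_csv(ph$phenotypes, file.path(DATA_DIR, "phenotypes.csv"))
write_vcf(G, file.path(DATA_DIR, "genotypes.vcf"))
write_dosage_tsv(G, file.path(DATA_DIR, "dosages.tsv"),
                 file.path(DATA_DIR, "map.tsv"))
utils::write.csv(meta, file.path(DATA_DIR, "accessions.csv"),
                 row.names = FALSE, quote = FALSE)
write_ground_truth_yaml(
  list(envirotype = met$truth$envirotype, qtl = ph$truth$qtl,
       realized_fractions = as.list(ph$truth$realized_fractions)),
  file.path(DATA_DIR, "ground_truth.yaml"))

cat(sprintf(
  "Simulated %d environments (%d envirotypes), %d accessions, %d SNPs.\n",
  cfg$n_environments, cfg$n_envirotypes, cfg$n_accessions, cfg$n_snps))
cat(sprintf("Mean seed yield %.2f q/ha; realized variance fractions:\n",
            mean(ph$phenotypes$sy)))
print(round(ph$truth$realized_fractions, 3))
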