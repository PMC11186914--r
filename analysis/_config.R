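# Shared configuration of the demonstration analysis: a 16-environment MET
# in 4 envirotypes, 150 inbred accessions, 2,000 LD-block SNPs, one stable
# QTL (12% of Var(G)) and one interactive QTL (20% of Var(G), envirotype
# E4 only). Every script regenerates deterministically from this seed.

library(metenviro)

RESULTS_DIR <- file.path("results")
DATA_DIR <- file.path(RESULTS_DIR, "data")
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

DEMO_SEED <- 1

demo_sim_config <- function() {
  sim_config(
    n_environments = 16, n_envirotypes = 4, n_accessions = 150,
    n_snps = 2000, n_chromosomes = 4, ld_block_size = 20,
    replicates_per_env = 2, seed = DEMO_SEED,
    qtl_specs = list(
      qtl_spec(1, 250 * 12500, 0.12, "stable"),
      qtl_spec(2, 250 * 12500, 0.20, "interactive", "E4")))
}

write_tsv <- function(x, name) {
  utils::write.table(x, file.path(RESULTS_DIR, name), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  message("  wrote results/", name)
}
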