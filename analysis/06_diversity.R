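#!/usr/bin/env Rscript
# Diversity analysis: split the panel by seed glucosinolate content
# (> 18 umol/g), compute windowed nucleotide diversity for the whole panel
# and each sub-population, and the windowed Weir-Cockerham F_ST between
# them, genome-wide and around the detected QTL regions.

source(file.path("analysis", "_config.R"))

G <- read_dosage_tsv(file.path(DATA_DIR, "dosages.tsv"),
                     file.path(DATA_DIR, "map.tsv"))
meta <- utils::read.csv(file.path(DATA_DIR, "accessions.csv"))
regions <- utils::read.delim(file.path(RESULTS_DIR, "qtl_regions.tsv"))

split <- split_by_gsl(meta, threshold = 18)
cat(sprintf("Panel split: %d GSL+ / %d GSL- accessions.\n",
            sum(split$population == "GSL+"), sum(split$population == "GSL-")))

summ <- diversity_summary(G, split, window_bp = 10000)
write_tsv(summ, "diversity_summary.tsv")
cat("\nMean per-bp nucleotide diversity and F_ST per chromosome:\n")
print(transform(summ, pi_all = signif(pi_all, 3), pi_pop1 = signif(pi_pop1, 3),
                pi_pop2 = signif(pi_pop2, 3), mean_fst = round(mean_fst, 3)),
      row.names = FALSE)

fst <- windowed_mean_fst(G, split, window_bp = 10000)
write_tsv(fst$windows, "fst_windows.tsv")
pi_plus <- windowed_pi(geno_matrix(
  G$dosages[intersect(rownames(G$dosages),
                      split$accession_id[split$population == "GSL+"]), ],
  G$map), window_bp = 10000)
write_tsv(pi_plus$windows, "pi_windows_gslplus.tsv")

## windows overlapping the detected QTL regions
cat("\nDiversity in the 10 kb windows spanning each QTL region:\n")
for (i in seq_len(nrow(regions))) {
  w <- fst$windows[fst$windows$chromosome == regions$chromosome[i] &
                     fst$windows$end > regions$start[i] &
                     fst$windows$start <= regions$end[i], ]
  cat(sprintf("  %s (%s): %d windows, mean F_ST %.3f\n",
              regions$name[i], regions$classification[i], nrow(w),
              mean(w$mean_fst, na.rm = TRUE)))
}
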