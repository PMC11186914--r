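#!/usr/bin/env Rscript
# Compute the 13 seed-yield limiting indicators for every environment from
# the raw weather / soil / management files, then impute the missing cells.

source(file.path("analysis", "_config.R"))

environments <- read_environments_csv(file.path(DATA_DIR, "environments.csv"))
weather <- utils::read.csv(file.path(DATA_DIR, "weather.csv"))
weather$date <- as.Date(weather$date)
supplies <- utils::read.csv(file.path(DATA_DIR, "management_supplies.csv"))
supplies$supply_date <- as.Date(supplies$supply_date)
measured <- utils::read.csv(file.path(DATA_DIR, "management_measured.csv"))

X <- build_indicator_matrix(environments, weather,
                            list(supplies = supplies, measured = measured))
write_tsv(X, "indicators_raw.tsv")
n_missing <- sum(is.na(X[, -1]))
Xi <- impute_indicator_matrix(X)
write_tsv(Xi, "indicators.tsv")

cat(sprintf("Computed %d indicators for %d environments (%d missing cells imputed).\n",
            ncol(X) - 1, nrow(X), n_missing))
cat("Indicator ranges:\n")
print(t(sapply(Xi[, -1], range)))
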