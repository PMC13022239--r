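#!/usr/bin/env Rscript
# Step 1 — simulate the farm.
#
# Generates the synthetic barn dataset the rest of the analysis runs on:
# farm-realistic batches (two-peak diurnal cycle, logistic growth trend,
# persistent subset-ARMA noise, sensor corruption and non-drinking usage
# records) laid out as barns x consecutive batches.  The full study layout is
# 6 barns x 5 batches of 15 weeks; this driver uses 6 x 2 so the whole
# analysis replays in minutes — change the two constants below to scale up.
#
# Writes results/data/raw_readings.csv, clean_series.csv, covariates.csv and
# a provenance.yaml.

library(pigwater)

N_BARNS <- 6
N_BATCHES <- 2
SEED <- 20210101

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message(sprintf("simulating %d barns x %d batches (seed %d) ...",
                N_BARNS, N_BATCHES, SEED))
farm <- simulate_farm(N_BARNS, N_BATCHES, seed = SEED)

fmt <- function(df) transform(df, timestamp = format(timestamp, "%Y-%m-%d %H:%M:%S"))
raw <- do.call(rbind, lapply(farm, function(b) fmt(b$raw)))
clean <- do.call(rbind, lapply(farm, function(b) fmt(b$clean)))
cov <- do.call(rbind, lapply(farm, function(b) {
  cbind(barn_id = b$clean$barn_id[1], batch_id = b$clean$batch_id[1],
        fmt(b$covariates))
}))
ledger <- do.call(rbind, lapply(farm, function(b)
  transform(b$ledger, hour = format(hour, "%Y-%m-%d %H:%M:%S"))))

write.csv(raw, file.path(out_dir, "raw_readings.csv"), row.names = FALSE)
write.csv(clean, file.path(out_dir, "clean_series.csv"), row.names = FALSE)
write.csv(cov, file.path(out_dir, "covariates.csv"), row.names = FALSE)
write.csv(ledger, file.path(out_dir, "fault_ledger.csv"), row.names = FALSE)
yaml::write_yaml(list(n_barns = N_BARNS, n_batches = N_BATCHES, seed = SEED,
                      mode = "farm-realistic",
                      n_raw_records = nrow(raw), n_hours = nrow(clean)),
                 file.path(out_dir, "provenance.yaml"))

message(sprintf("wrote %d raw records, %d clean hours, %d injected faults",
                nrow(raw), nrow(clean), nrow(ledger)))
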