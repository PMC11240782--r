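#!/usr/bin/env Rscript
# Screen the cohort the way a reference-interval study screens a clinic
# export: keep each dog's initial presentation, then drop records with
# missing age, juveniles (< 1 year), and physiologically implausible
# temperatures (< 30.0 or > 43.0 degrees C). The tally partitions every
# input measurement under exactly one reason.
#
# Reads : scratch/cohort.csv (built by 01_simulate_cohort.R; regenerated
#         here if absent)
# Writes: results/exclusion_tally.json

suppressPackageStartupMessages(library(indirectRI))
dir.create("results", showWarnings = FALSE)

if (!file.exists("scratch/cohort.csv")) {
  message("scratch/cohort.csv missing; regenerating via 01_simulate_cohort.R")
  source("analysis/01_simulate_cohort.R")
}

records <- read_records("scratch/cohort.csv")
cat(sprintf("Read %d visit records (%d rejected at parse)\n",
            nrow(records), attr(records, "n_rejected")))

dedup <- select_first_per_patient(records)
cat(sprintf("Initial presentations: %d dogs (%d repeat visits removed)\n",
            nrow(dedup), attr(dedup, "n_duplicates_removed")))

screen <- apply_exclusions(dedup, filter_config(),
                           attr(dedup, "n_duplicates_removed"))
print(screen$tally)

jsonlite::write_json(unclass(screen$tally), "results/exclusion_tally.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("Retained %d adult dogs for analysis -> results/exclusion_tally.json\n",
            screen$tally$n_retained))
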