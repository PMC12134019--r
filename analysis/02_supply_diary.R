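#!/usr/bin/env Rscript
# Stage 2 — build supply diaries and derive the discontinuation endpoint.
#
# Coverage diaries from the dispensing records (182-day supplies, carry-over
# of the unexhausted remainder capped at 182 days), truncated at the earliest
# censoring event; early discontinuation = 182 consecutive uncovered days,
# dated at the 182nd such day, measured from tamoxifen initiation.

library(tampath)

dirc <- "results/analysis/cohort"
supplies <- read_tsv_table(file.path(dirc, "supplies.tsv"))
events <- read_tsv_table(file.path(dirc, "events.tsv"))
covariates <- read_tsv_table(file.path(dirc, "covariates.tsv"))

outcomes <- derive_cohort_outcomes(supplies, events, covariates,
                                   gap_days = 182, carryover_cap_days = 182,
                                   verbose = TRUE)
write_tsv_table(outcomes, file.path(dirc, "outcomes.tsv"))

tally <- table(outcomes$censor_reason)
message(sprintf("discontinuation: %d/%d (%.1f%%)",
                sum(outcomes$event), nrow(outcomes),
                100 * mean(outcomes$event)))
message("censoring tally: ",
        paste(names(tally), tally, sep = "=", collapse = " "))
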