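#!/usr/bin/env Rscript
# Apply the failure-to-decline rule to the eight-patient worked fixture:
# predicted absolute CRP at the assessment day versus the observed value.

suppressPackageStartupMessages({
  library(crpkin)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)

model <- published_decay_model()
rule <- ftd_rule()
fixture <- generate_worked_fixture()

rows <- bind_rows(lapply(fixture$patients$patient_id, function(id) {
  ser <- patient_series(fixture, id)
  ftd <- failure_to_decline(ser, model, rule)
  mutate(ftd, patient_id = id, .before = 1)
}))
readr::write_csv(rows, "results/worked_failure_to_decline.csv")

summary <- rows |>
  group_by(patient_id) |>
  summarise(failure_any_day = any(failure), .groups = "drop")

print(as.data.frame(rows), digits = 5)
cat("\npatients flagged as failure to decline:",
    paste(summary$patient_id[summary$failure_any_day], collapse = ", "), "\n")
cat("wrote results/worked_failure_to_decline.csv\n")
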