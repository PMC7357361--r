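#!/usr/bin/env Rscript
# Deterministic scenarios: time horizon 5 and 20 years, and a 7-year device
# replacement interval. The ICER falls as the horizon lengthens (the device's
# survival benefit keeps accruing after the up-front cost) and as
# replacements become less frequent.

suppressPackageStartupMessages(library(icdcea))
dir.create("results", showWarnings = FALSE)

scenarios <- c("base_case", "five_year", "twenty_year", "replacement_7y")
rows <- lapply(scenarios, function(s) {
  run <- run_comparison(fixture_config(s))
  data.frame(scenario = s,
             icd_cost = round(run$ICD$total_discounted_cost, 2),
             opt_cost = round(run$OPT$total_discounted_cost, 2),
             delta_cost = round(run$ce$delta_cost, 2),
             delta_qaly = round(run$ce$delta_qaly, 4),
             icer = round(run$ce$icer))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/scenarios.csv", row.names = FALSE, quote = FALSE)
write_manifest("results", "scenarios", fixture_config("base_case"))

print(tab, row.names = FALSE)
cat("\nThe horizon ordering ICER(5y) > ICER(10y) > ICER(20y) holds:",
    tab$icer[2] > tab$icer[1] && tab$icer[1] > tab$icer[3], "\n")
cat("Stretching replacement from 5 to 7 years lowers the ICER by USD",
    tab$icer[1] - tab$icer[4], "per QALY.\n")
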