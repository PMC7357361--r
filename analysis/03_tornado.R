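#!/usr/bin/env Rscript
# One-way sensitivity: tornado analysis over every cost (published min-max
# ranges) and every probability/utility with a sampling distribution
# (central 95% beta intervals).

suppressPackageStartupMessages(library(icdcea))
dir.create("results", showWarnings = FALSE)

cfg <- load_config(base_case_config_path())
tor <- tornado(cfg)
export_tornado(tor, "results/tornado.csv")
write_manifest("results", "tornado", cfg,
               config_path = base_case_config_path())

print(tor, row.names = FALSE, digits = 4)
cat("\nMost influential parameters (widest ICER span):\n")
cat(paste0("  ", head(tor$parameter, 3), collapse = "\n"), "\n")
cat("The all-cause mortality probabilities dominate every cost parameter;\n")
cat("the well-state utility ranks highest only because its published beta\n")
cat("distribution is very diffuse. Sweeping the sudden-cardiac-death\n")
cat("probabilities re-attributes deaths between causes without changing\n")
cat("totals, so their ICER span is exactly zero.\n")
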