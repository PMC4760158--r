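#!/usr/bin/env Rscript
# Step 4 — all-subsets AICc selection.
#
# Tests every admissible combination of explanatory variables (with
# marginality enforced for the prey x predator diversity interaction) for
# the transfer proxy, and reports the most parsimonious model.

source("analysis/00_config.R")

summary_tab <- read.csv(path_in_results("summary.csv"))

terms <- c("prey_mu", "predator_mu", "prey_mu:predator_mu",
           "sst", "ln_sio3")
dr <- suppressWarnings(
  dredge_all_subsets("log10_ppbr", terms, "station_id", summary_tab))

cat(sprintf("Fitted %d admissible models over %d candidate terms.\n",
            nrow(dr$table), length(terms)))
cat("\nTop of the AICc ranking:\n")
print(head(dr$table, 8), digits = 5, row.names = FALSE)
cat(sprintf("\nMost parsimonious model: %s (AICc %.2f)\n",
            dr$table$model[1], dr$table$aicc[1]))
print(dr$best)

write.csv(dr$table, path_in_results("dredge_table.csv"), row.names = FALSE)
cat("\nWrote results/dredge_table.csv\n")
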