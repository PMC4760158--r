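#!/usr/bin/env Rscript
# Step 3 — univariate mixed-model ranking.
#
# Ranks single explanatory variables for three responses — the transfer
# proxy log10(PPBR), predator size diversity and prey size diversity —
# using station random-intercept models compared by AICc, the first stage
# of the model-selection procedure.

source("analysis/00_config.R")

summary_tab <- read.csv(path_in_results("summary.csv"))

rankings <- list(
  log10_ppbr = c("predator_mu", "prey_mu", "sss", "sst",
                 "ln_no3", "ln_po4", "ln_sio3"),
  predator_mu = c("prey_mu", "sss", "sst", "ln_no3", "ln_po4", "ln_sio3"),
  prey_mu = c("predator_mu", "sss", "sst", "ln_no3", "ln_po4", "ln_sio3")
)

all_rows <- lapply(names(rankings), function(resp) {
  r <- suppressWarnings(
    rank_univariate(resp, rankings[[resp]], "station_id", summary_tab))
  cat(sprintf("\nResponse %s — univariate ranking by AICc:\n", resp))
  print(as.data.frame(r), digits = 3, row.names = FALSE)
  cat(sprintf("best single predictor: %s\n", r$term[1]))
  cbind(response = resp, as.data.frame(r))
})

out <- do.call(rbind, all_rows)
write.csv(out, path_in_results("univariate_ranking.csv"), row.names = FALSE)
cat("\nWrote results/univariate_ranking.csv\n")
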