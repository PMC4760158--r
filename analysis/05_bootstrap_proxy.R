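#!/usr/bin/env Rscript
# Step 5 — proxy validation and uncertainty propagation.
#
# Emulates the reduced validation subset on which growth rates are
# measured (artificial-cohort incubations for 29 samples), computes the
# production-rate ratio log10(PPPR), correlates it with the biomass-ratio
# proxy log10(PPBR), and propagates the proxy uncertainty by bootstrap —
# including a sign-stability check of the selected model's coefficients.

source("analysis/00_config.R")

summary_tab <- read.csv(path_in_results("summary.csv"))

cohorts <- simulate_cohorts(summary_tab, n_samples = 29, seed = SEED + 1L)
prod <- suppressWarnings(production_ratios(cohorts))
paired <- merge(summary_tab[, c("sample_id", "log10_ppbr")], prod,
                by = "sample_id")
cat(sprintf("Validation subset: %d samples with cohort incubations.\n",
            nrow(paired)))

best_terms <- c("prey_mu", "predator_mu", "prey_mu:predator_mu")
refit <- function(idx) {
  f <- suppressWarnings(fit_lmm("log10_ppbr", best_terms, "station_id",
                                summary_tab[idx, , drop = FALSE]))
  setNames(f$coefficients$estimate, f$coefficients$term)
}
n_all <- nrow(summary_tab)
boot <- suppressWarnings(bootstrap_proxy_uncertainty(
  paired$log10_ppbr, paired$log10_pppr,
  n_boot = 1000, seed = SEED + 2L,
  refit = function(idx) {
    if (identical(idx, seq_len(nrow(paired)))) refit(seq_len(n_all))
    else refit(sample.int(n_all, n_all, replace = TRUE))
  }
))

cat(sprintf("log10(PPBR) vs log10(PPPR): r = %.2f, 95%% CI [%.2f, %.2f] (n = %d)\n",
            boot$r, boot$ci[1], boot$ci[2], boot$n))
cat("Sign stability of the selected model's coefficients across resamples:\n")
print(round(boot$sign_stability, 3))

report <- data.frame(
  quantity = c("pearson_r", "ci_lower", "ci_upper", "n_pairs", "n_boot",
               paste0("sign_stability_", names(boot$sign_stability))),
  value = c(boot$r, boot$ci[1], boot$ci[2], boot$n, boot$n_boot,
            unname(boot$sign_stability))
)
write.csv(report, path_in_results("bootstrap_report.csv"), row.names = FALSE)
cat("Wrote results/bootstrap_report.csv\n")
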