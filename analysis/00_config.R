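# Shared configuration for the analysis drivers. Each numbered script
# sources this file, so one seed and one set of conversion factors govern
# the whole workflow. Outputs accumulate under results/.

library(sizetransfer)

SEED <- 1L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Survey design: 40 stations sampled 3 times each, with on average
# 3500 prey (nano-microplankton) and 2000 predator (mesozooplankton)
# individuals measured per sample.
survey_config <- community_sim_config(seed = SEED)

# Biovolume-to-carbon conversion. These factors are illustrative
# placeholders on a plausible scale (mg C per um^3-power); they set the
# absolute biomass level but cancel out of every relationship studied
# here except the intercept of log10(PPBR).
conversion <- biomass_conversion_table(
  prey = list(factor = 1e-7, exponent = 0.9),
  predator = list(factor = 4e-8, exponent = 0.95),
  shrinkage_factor = 1.33,
  quiet = TRUE
)

sd_options <- size_diversity_options()

path_in_results <- function(...) file.path(RESULTS_DIR, ...)
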