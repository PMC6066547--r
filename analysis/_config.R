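# Shared configuration for the numbered analysis scripts. Desk-scale run:
# 60 bank images (the emulated experiment used 180 natural images; 60 keeps
# every script under a couple of minutes while populating all scenarios).
library(rivalmix)

ANALYSIS_SEED <- 2026L
ANALYSIS_CFG <- default_config(seed = ANALYSIS_SEED, n_images = 60L,
                               subset_max = 6L)
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# Human-report scenario proportions emulated by the coded-report generator:
# one image 70.5%, both 6.0%, none 23.2% (single-winner share split evenly),
# renormalized to sum to 1.
HUMAN_PROBS <- c(none = 0.232, first = 0.3525, second = 0.3525, both = 0.060)
HUMAN_PROBS <- HUMAN_PROBS / sum(HUMAN_PROBS)

analysis_bank <- function(cfg = ANALYSIS_CFG) {
  make_image_bank(cfg$n_images, cfg$bank_ranges, side = cfg$image_side,
                  seed = cfg$seeds$bank)
}

analysis_perceiver <- function(cfg = ANALYSIS_CFG) {
  build_mock_perceiver(cfg$seeds$perceiver, cfg$perceiver_K,
                       cfg$perceiver_widths, input_side = cfg$image_side)
}
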