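#!/usr/bin/env Rscript
# Stage 3: which image parameters predict dominance? Using the trials where
# the perceiver chose exactly one image, fit the zero-intercept logistic on
# each parameter's log ratio (|beta| = predictability), bin the dominance
# curves with Clopper-Pearson intervals, and search all parameter subsets
# for the best cross-validated prediction agreement.

source("analysis/_config.R")
cfg <- ANALYSIS_CFG

cat("== 03_dominance: image parameters as predictors of the winner ==\n")

trials <- read.csv(file.path(RESULTS_DIR, "trials_5050.csv"),
                   stringsAsFactors = FALSE)
usable <- sum(!is.na(trials$y))
cat(sprintf("%d of %d trials had a single winner\n", usable, nrow(trials)))

single <- do.call(rbind, lapply(cfg$features, function(f) {
  fit <- fit_dominance_glm(trials, f, lambda_grid = 0, folds = cfg$folds,
                           seed = cfg$seeds$cv)
  sc <- predict_and_score(fit, trials)
  data.frame(feature = f, beta = unname(fit$coefficients),
             se = unname(fit$se), abs_beta = abs(unname(fit$coefficients)),
             agreement = sc$agreement, n_trials = fit$n_trials)
}))
single <- single[order(-single$abs_beta), ]
write.csv(single, file.path(RESULTS_DIR, "single_parameter_fits.csv"),
          row.names = FALSE)
cat("single-parameter predictability (|beta|, descending):\n")
for (i in seq_len(nrow(single))) {
  cat(sprintf("  %-16s |beta| = %.2f +/- %.2f  agreement %.1f%%\n",
              single$feature[i], single$abs_beta[i], single$se[i],
              100 * single$agreement[i]))
}

curves <- do.call(rbind, lapply(cfg$features, function(f) {
  cbind(feature = f,
        dominance_curve(trials, f, cfg$n_bins, cfg$ci_level))
}))
write.csv(curves, file.path(RESULTS_DIR, "dominance_curves.csv"),
          row.names = FALSE)

subsets <- best_subsets(trials, cfg$features, max_size = cfg$subset_max,
                        folds = cfg$folds, lambda_grid = cfg$lambda_grid,
                        seed = cfg$seeds$cv)
write.csv(subsets, file.path(RESULTS_DIR, "best_subsets.csv"),
          row.names = FALSE)
cat("best subset per size (cross-validated agreement):\n")
for (s in sort(unique(subsets$size))) {
  b <- subsets[subsets$size == s & subsets$best_in_size, ]
  cat(sprintf("  size %d: {%s} %.1f%% +/- %.1f\n", s, b$subset,
              100 * b$agreement, 100 * b$se))
}
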