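#!/usr/bin/env Rscript
# Stage 4: where is the competition resolved? Correlate the mixture's
# activation maps with each source's, layer by layer. For 50/50 mixtures,
# split by winner vs loser; for phase/magnitude hybrids, group by which
# source (if either) the perceiver chose, against both references.

source("analysis/_config.R")
cfg <- ANALYSIS_CFG

cat("== 04_layers: activation-map correlations through the hierarchy ==\n")

bank <- analysis_bank()
perceiver <- analysis_perceiver()
act_cache <- new.env(parent = emptyenv())
src_act <- function(id) {
  if (!exists(id, envir = act_cache)) {
    assign(id, perceiver$activations(bank[[id]]), envir = act_cache)
  }
  get(id, envir = act_cache)
}

# --- 50/50: winner vs loser -------------------------------------------------
trials <- read.csv(file.path(RESULTS_DIR, "trials_5050.csv"),
                   stringsAsFactors = FALSE)
won <- which(!is.na(trials$y))
won <- head(won, cfg$layer_max_trials)
stacks <- lapply(won, function(r) {
  img1 <- bank[[trials$source1_id[r]]]
  img2 <- bank[[trials$source2_id[r]]]
  mix <- mix_average(img1, img2)
  wid <- if (trials$y[r] == 1L) trials$source1_id[r] else trials$source2_id[r]
  lid <- if (trials$y[r] == 1L) trials$source2_id[r] else trials$source1_id[r]
  list(mix = perceiver$activations(mix), winner = src_act(wid),
       loser = src_act(lid))
})
prof <- winner_loser_profile(stacks)
out <- data.frame(layer = prof$winner$layer,
                  winner_mean = prof$winner$mean, winner_se = prof$winner$se,
                  loser_mean = prof$loser$mean, loser_se = prof$loser$se,
                  difference = prof$difference$difference,
                  n = prof$winner$n)
write.csv(out, file.path(RESULTS_DIR, "layer_profiles_5050.csv"),
          row.names = FALSE)
cat(sprintf("50/50 (%d trials): winner-loser correlation difference by layer:\n",
            length(stacks)))
for (i in seq_len(nrow(out))) {
  cat(sprintf("  %s: winner %.3f, loser %.3f, difference %.3f\n",
              out$layer[i], out$winner_mean[i], out$loser_mean[i],
              out$difference[i]))
}

# --- phase/magnitude: grouped by outcome ------------------------------------
phs_mixes <- build_mixture_set(bank, "phase_magnitude", "unique_pairing",
                               seed = cfg$seeds$pairing)
phs_trials <- run_competition(perceiver, phs_mixes, bank, n = cfg$top_n,
                              seed = cfg$seeds$noise)
# source1 supplies the phase; "both" outcomes (rare) are set aside so groups
# match the three-way split: phase won / magnitude won / neither
grouped <- lapply(which(phs_trials$scenario != "both"), function(r) {
  rec <- phs_mixes[[which(vapply(phs_mixes, `[[`, "", "id") ==
                            phs_trials$pair_id[r])]]
  list(mix = perceiver$activations(rec$mixed),
       phase = src_act(phs_trials$source1_id[r]),
       magnitude = src_act(phs_trials$source2_id[r]),
       outcome = switch(phs_trials$scenario[r], first = "phase_won",
                        second = "magnitude_won", none = "neither"))
})
res <- outcome_grouped_profile(grouped)
rows <- list()
for (g in setdiff(names(res), "warnings")) {
  rows[[g]] <- data.frame(group = g, layer = res[[g]]$vs_phase$layer,
                          vs_phase = res[[g]]$vs_phase$mean,
                          vs_magnitude = res[[g]]$vs_magnitude$mean,
                          difference = res[[g]]$difference$difference,
                          n = res[[g]]$vs_phase$n)
}
phs_out <- do.call(rbind, rows)
write.csv(phs_out, file.path(RESULTS_DIR, "layer_profiles_phsmag.csv"),
          row.names = FALSE)
counts <- table(vapply(grouped, `[[`, "", "outcome"))
cat(sprintf("phs/mag (%d unique pairs; outcomes: %s):\n", length(grouped),
            paste(names(counts), counts, sep = "=", collapse = ", ")))
if (length(res$warnings)) cat("  note:", res$warnings, "\n")
for (g in names(rows)) {
  last <- rows[[g]][nrow(rows[[g]]), ]
  cat(sprintf("  %s: final-layer corr vs phase %.3f, vs magnitude %.3f\n",
              g, last$vs_phase, last$vs_magnitude))
}
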