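#' Default pipeline configuration
#'
#' Every run-affecting constant lives in this config, and every stochastic
#' stage has its own explicit seed, so a config file fully reproduces a run.
#' Defaults mirror the emulated protocol: top-5 overlap rule, 90 mixtures
#' sampled per iteration, 100 iterations, noise levels 0-5.
#'
#' @param seed master seed from which the per-stage seeds are derived.
#' @param n_images number of synthetic bank images (180 emulates the full
#'   stimulus set; smaller values give fast desk-scale runs).
#' @param ... overrides for any config field.
#' @return named list of class `run_config`.
#' @export
default_config <- function(seed = 1L, n_images = 60L, ...) {
  cfg <- list(
    n_images = n_images,
    image_side = 64L,
    bank_ranges = list(luminance = c(60, 200), contrast = c(8, 45),
                       saturation = c(5, 150), alpha = c(0.5, 2.5)),
    mixture_mode = "average_5050",
    pairing = "all_pairwise",
    perceiver_K = 1000L,
    perceiver_widths = c(256L, 128L, 64L),
    top_n = 5L,
    sigma = 0,
    sample_size = 90L,
    sampling_iterations = 100L,
    features = c("gradient", "low_frequencies", "luminance",
                 "global_contrast", "colorfulness", "saturation"),
    folds = 10L,
    lambda_grid = 0,
    subset_max = 2L,
    n_bins = 9L,
    ci_level = 0.95,
    layer_max_trials = 200L,
    seeds = list(bank = child_seed(seed, 1), pairing = child_seed(seed, 2),
                 perceiver = child_seed(seed, 3), noise = child_seed(seed, 4),
                 sampling = child_seed(seed, 5), cv = child_seed(seed, 6))
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("run_config", "list"))
}

#' Validate a pipeline configuration
#'
#' Rejects, before any computation, configs missing a stage seed or with
#' out-of-range fields.
#'
#' @param config a `run_config` (or plain list with the same fields).
#' @return the config, invisibly; errors on invalid input.
#' @export
validate_config <- function(config) {
  needed <- c("n_images", "image_side", "mixture_mode", "pairing",
              "perceiver_K", "perceiver_widths", "top_n", "sigma",
              "sample_size", "sampling_iterations", "features", "folds",
              "lambda_grid", "subset_max", "n_bins", "ci_level", "seeds")
  miss <- setdiff(needed, names(config))
  if (length(miss)) {
    stop_invalid("config is missing fields: %s", paste(miss, collapse = ", "))
  }
  seed_names <- c("bank", "pairing", "perceiver", "noise", "sampling", "cv")
  miss_seed <- setdiff(seed_names, names(config$seeds))
  if (length(miss_seed) ||
      !all(vapply(config$seeds[seed_names], is.numeric, TRUE))) {
    stop_invalid("every stochastic stage needs an explicit numeric seed%s",
                 if (length(miss_seed)) {
                   sprintf(" (missing: %s)", paste(miss_seed, collapse = ", "))
                 } else "")
  }
  if (config$n_images < 2L) stop_invalid("n_images must be >= 2")
  if (config$subset_max > length(config$features)) {
    stop_invalid("subset_max exceeds the number of features")
  }
  invisible(config)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full mock-perceiver pipeline
#'
#' Executes the stages in order — synthetic image bank, mixture set, mock
#' perceiver competition, scenario probabilities, single-parameter dominance
#' fits and curves, best subsets, winner/loser layer profiles — writing flat
#' CSV/JSON outputs plus the config and a stage log into `out_dir`.
#' Re-running with the same config reproduces every analytic output.
#'
#' @param config a `run_config`, see [default_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results (`bank_features`,
#'   `trials`, `scenario_probs`, `single_fits`, `curves`, `subsets`,
#'   `layer_profiles`) and `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }

  say("stage bank: %d textures at %dx%d (seed %d)", config$n_images,
      config$image_side, config$image_side, config$seeds$bank)
  bank <- make_image_bank(config$n_images, config$bank_ranges,
                          side = config$image_side, seed = config$seeds$bank)
  bank_features <- feature_table(bank, extended = TRUE)
  utils::write.csv(bank_features, file.path(out_dir, "bank_features.csv"),
                   row.names = FALSE)

  say("stage mix: %s / %s (seed %d)", config$mixture_mode, config$pairing,
      config$seeds$pairing)
  mixtures <- build_mixture_set(bank, config$mixture_mode, config$pairing,
                                seed = config$seeds$pairing)
  utils::write.csv(mixture_manifest(mixtures),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)

  say("stage perceive: mock perceiver K=%d (seed %d), top-%d, sigma=%g",
      config$perceiver_K, config$seeds$perceiver, config$top_n, config$sigma)
  perceiver <- build_mock_perceiver(config$seeds$perceiver, config$perceiver_K,
                                    config$perceiver_widths,
                                    input_side = config$image_side)
  trials <- run_competition(perceiver, mixtures, bank, n = config$top_n,
                            sigma = config$sigma, seed = config$seeds$noise)
  utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)

  say("stage scenarios: sample %d x %d iterations (seed %d)",
      min(config$sample_size, nrow(trials)), config$sampling_iterations,
      config$seeds$sampling)
  probs <- scenario_probabilities(trials$scenario,
                                  min(config$sample_size, nrow(trials)),
                                  config$sampling_iterations,
                                  seed = config$seeds$sampling)
  write_json_out(probs, file.path(out_dir, "scenario_probabilities.json"))

  say("stage dominance: single-parameter fits and curves")
  usable <- sum(!is.na(trials$y))
  single_fits <- NULL
  curves <- NULL
  subsets <- NULL
  if (usable >= 20L) {
    single_fits <- do.call(rbind, lapply(config$features, function(f) {
      fit <- fit_dominance_glm(trials, f, lambda_grid = 0,
                               folds = config$folds, seed = config$seeds$cv)
      sc <- predict_and_score(fit, trials)
      data.frame(feature = f, beta = unname(fit$coefficients),
                 se = unname(fit$se), abs_beta = abs(unname(fit$coefficients)),
                 agreement = sc$agreement, n_trials = fit$n_trials,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(single_fits,
                     file.path(out_dir, "single_parameter_fits.csv"),
                     row.names = FALSE)
    curves <- do.call(rbind, lapply(config$features, function(f) {
      cv <- dominance_curve(trials, f, config$n_bins, config$ci_level)
      cbind(feature = f, cv)
    }))
    utils::write.csv(curves, file.path(out_dir, "dominance_curves.csv"),
                     row.names = FALSE)

    say("stage subsets: exhaustive up to size %d, %d-fold CV",
        config$subset_max, config$folds)
    subsets <- best_subsets(trials, config$features, config$subset_max,
                            config$folds, config$lambda_grid,
                            seed = config$seeds$cv)
    utils::write.csv(subsets, file.path(out_dir, "best_subsets.csv"),
                     row.names = FALSE)
  } else {
    say("stage dominance: skipped (%d single-winner trials < 20)", usable)
  }

  say("stage layers: winner/loser correlation profiles")
  layer_profiles <- NULL
  win_rows <- which(!is.na(trials$y) & trials$iteration == 1L)
  if (length(win_rows) > 0L) {
    win_rows <- utils::head(win_rows, config$layer_max_trials)
    act_cache <- new.env(parent = emptyenv())
    get_act <- function(id) {
      if (!exists(id, envir = act_cache)) {
        assign(id, perceiver$activations(bank[[id]]), envir = act_cache)
      }
      get(id, envir = act_cache)
    }
    mix_by_id <- stats::setNames(mixtures,
                                 vapply(mixtures, `[[`, "", "id"))
    stack_trials <- lapply(win_rows, function(r) {
      win_id <- if (trials$y[r] == 1L) trials$source1_id[r] else
        trials$source2_id[r]
      los_id <- if (trials$y[r] == 1L) trials$source2_id[r] else
        trials$source1_id[r]
      list(mix = perceiver$activations(mix_by_id[[trials$pair_id[r]]]$mixed),
           winner = get_act(win_id), loser = get_act(los_id))
    })
    layer_profiles <- winner_loser_profile(stack_trials)
    prof <- merge(merge(
      stats::setNames(layer_profiles$winner,
                      c("layer", "winner_mean", "winner_se", "n")),
      stats::setNames(layer_profiles$loser[, 1:3],
                      c("layer", "loser_mean", "loser_se")), by = "layer"),
      layer_profiles$difference, by = "layer")
    utils::write.csv(prof[order(prof$layer), ],
                     file.path(out_dir, "layer_profiles.csv"),
                     row.names = FALSE)
  }

  cfg_out <- config
  cfg_out$bank_ranges <- lapply(cfg_out$bank_ranges, as.numeric)
  write_json_out(unclass(cfg_out), file.path(out_dir, "config.json"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  say("done: outputs in %s", out_dir)
  invisible(list(bank_features = bank_features, trials = trials,
                 scenario_probs = probs, single_fits = single_fits,
                 curves = curves, subsets = subsets,
                 layer_profiles = layer_profiles, out_dir = out_dir))
}
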