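# RGB offsets per unit of IQ-plane chroma at a given hue, solved from the
# YIQ transform with the luma component fixed at 0 (so adding chroma never
# moves luminance).
yiq_matrix <- matrix(c(0.299, 0.587, 0.114,
                       0.596, -0.274, -0.322,
                       0.211, -0.523, 0.312), 3, byrow = TRUE,
                     dimnames = list(c("Y", "I", "Q"), c("R", "G", "B")))

chroma_direction <- function(hue) {
  drop(solve(yiq_matrix, c(0, cos(hue), sin(hue))))
}

#' Generate a seeded 1/f^alpha texture with controlled image parameters
#'
#' Builds a spectral (1/f^alpha) Gaussian noise field, affinely maps it to
#' the target luminance and global contrast (exact by construction), and adds
#' a constant zero-luminance chroma offset at the given hue whose scale is
#' solved numerically so the mean saturation hits its target. Textures are
#' the synthetic stand-in for a natural-image bank: unlike photographs, each
#' parameter is independently steerable.
#'
#' @param luminance target mean weighted intensity, in \[0, 255\].
#' @param contrast target population SD of weighted intensity, >= 0.
#' @param saturation target mean saturation, in \[0, 255\].
#' @param alpha spectral slope of the 1/f^alpha noise (0 = white).
#' @param hue chroma hue angle in the IQ plane, radians.
#' @param side image side in pixels.
#' @param seed integer seed; same spec + seed gives an identical image.
#' @return an `image_rgb`. Errors if the targets would clip more than 1% of
#'   channel values.
#' @export
make_texture_image <- function(luminance = 128, contrast = 30,
                               saturation = 0, alpha = 1, hue = 0,
                               side = 64L, seed = 1L) {
  if (luminance < 0 || luminance > 255 || contrast < 0 ||
      saturation < 0 || saturation > 255 || alpha < 0) {
    stop_invalid("invalid texture spec")
  }
  z <- with_seed(seed, matrix(stats::rnorm(side^2), side))
  if (alpha > 0) {
    f <- normalized_freqs(side)
    r <- sqrt(outer(f^2, f^2, `+`))
    filt <- ifelse(r == 0, 0, 1 / r^alpha)
    z <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / side^2
  }
  z <- z - mean(z)
  sdz <- sqrt(mean(z^2))
  if (sdz > 0) z <- z / sdz
  Y <- luminance + contrast * z

  d <- chroma_direction(hue)
  s <- 0
  if (saturation > 0) {
    mean_sat <- function(s) {
      mx <- pmax(Y + s * d[1], Y + s * d[2], Y + s * d[3])
      mn <- pmin(Y + s * d[1], Y + s * d[2], Y + s * d[3])
      mean(ifelse(mx <= 0, 0, 255 * (mx - mn) / mx))
    }
    upper <- 1000
    if (mean_sat(upper) < saturation) {
      stop_invalid("saturation target %g unachievable at this luminance",
                   saturation)
    }
    s <- stats::uniroot(function(s) mean_sat(s) - saturation,
                        c(0, upper), tol = 1e-8)$root
  }
  px <- array(0, dim = c(side, side, 3L))
  for (ch in 1:3) px[, , ch] <- Y + s * d[ch]
  clipped <- sum(px < 0 | px > 255)
  if (clipped > 0.01 * length(px)) {
    stop_invalid("spec clips %.1f%% of channel values (limit 1%%)",
                 100 * clipped / length(px))
  }
  image_rgb(quantize_pixels(px))
}

#' Generate a bank of synthetic texture images
#'
#' Texture parameters are sampled log-uniformly over the given ranges (hue
#' uniformly on the circle), giving wide feature-ratio coverage across random
#' pairs — the role played by a large set of natural images from distinct
#' categories in the emulated experiments.
#'
#' @param n number of images (>= 2); 180 matches the emulated stimulus set.
#' @param ranges named list of c(lo, hi) ranges for `luminance`, `contrast`,
#'   `saturation`, `alpha` (all lo > 0 for log-uniform sampling).
#' @param side image side in pixels.
#' @param seed integer seed.
#' @return named list of `image_rgb` (ids `img001`, ...).
#' @export
make_image_bank <- function(n = 180L,
                            ranges = list(luminance = c(60, 200),
                                          contrast = c(8, 45),
                                          saturation = c(5, 150),
                                          alpha = c(0.5, 2.5)),
                            side = 64L, seed = 1L) {
  if (n < 2L) stop_invalid("need n >= 2")
  runif_log <- function(k, rng) exp(stats::runif(k, log(rng[1]), log(rng[2])))
  pars <- with_seed(seed, {
    list(luminance = runif_log(n, ranges$luminance),
         contrast = runif_log(n, ranges$contrast),
         saturation = runif_log(n, ranges$saturation),
         alpha = runif_log(n, ranges$alpha),
         hue = stats::runif(n, 0, 2 * pi),
         seeds = sample.int(2^30, n))
  })
  imgs <- lapply(seq_len(n), function(i) {
    # keep the draw inside the generator's feasible region: the Gaussian
    # luma field needs ~3.5 SDs of headroom to the [0, 255] rails
    headroom <- min(pars$luminance[i], 255 - pars$luminance[i])
    contrast <- min(pars$contrast[i], headroom / 3.5)
    saturation <- pars$saturation[i]
    for (try in 1:6) {
      img <- tryCatch(
        make_texture_image(pars$luminance[i], contrast, saturation,
                           pars$alpha[i], pars$hue[i],
                           side = side, seed = pars$seeds[i]),
        error = function(e) NULL)
      if (!is.null(img)) return(img)
      # deterministically shrink an infeasible draw toward gray
      saturation <- saturation * 0.6
      contrast <- contrast * 0.85
    }
    make_texture_image(pars$luminance[i], contrast, 0, pars$alpha[i],
                       pars$hue[i], side = side, seed = pars$seeds[i])
  })
  names(imgs) <- sprintf("img%03d", seq_len(n))
  imgs
}

#' Simulate choice trials from a known dominance model
#'
#' Inverts the dominance logistic: per pair, feature log-ratios are drawn
#' zero-mean Gaussian, the win probability computed from the true
#' coefficients under the package's sign convention (positive beta favors
#' the larger parameter), and the winner drawn Bernoulli. Feature values are
#' reconstructed as exp(+/- x/2) around 1, so refitting the trials recovers
#' the generating coefficients.
#'
#' @param beta named numeric vector of true coefficients.
#' @param n_pairs number of trials.
#' @param spread SD of the Gaussian feature log-ratios.
#' @param seed integer seed.
#' @return trials data.frame compatible with [fit_dominance_glm()].
#' @export
make_choice_trials <- function(beta, n_pairs = 2000L, spread = 1, seed = 1L) {
  if (!length(beta) || is.null(names(beta)) || !all(is.finite(beta))) {
    stop_invalid("beta must be a named finite vector")
  }
  if (spread <= 0) stop_invalid("spread must be > 0")
  p <- length(beta)
  dat <- with_seed(seed, {
    x <- matrix(stats::rnorm(n_pairs * p, sd = spread), n_pairs, p)
    prob <- stats::plogis(drop(x %*% beta))
    y <- stats::rbinom(n_pairs, 1L, prob)
    list(x = x, y = y)
  })
  out <- data.frame(pair_id = sprintf("pair%05d", seq_len(n_pairs)),
                    scenario = ifelse(dat$y == 1L, "first", "second"),
                    winner = ifelse(dat$y == 1L, "source1", "source2"),
                    y = dat$y, stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    out[[paste0(names(beta)[j], "_1")]] <- exp(dat$x[, j] / 2)
    out[[paste0(names(beta)[j], "_2")]] <- exp(-dat$x[, j] / 2)
  }
  out
}

#' Analytic activation fixture with known mixture correlation
#'
#' Winner and loser stacks are independent standard-normal unit vectors per
#' layer; the mixture stack is alpha * winner + sqrt(1 - alpha^2) * noise, so
#' the expected mixture-winner correlation is alpha at every layer and the
#' mixture-loser correlation is 0. Ground truth for the layer-profile
#' machinery.
#'
#' @param alpha mixing weight in \[0, 1\].
#' @param widths named or unnamed vector of layer widths.
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @return list of trials, each with `mix`, `winner`, `loser` activation
#'   stacks (named lists of numeric vectors).
#' @export
make_activation_fixture <- function(alpha = 0.8, widths = c(1e4, 1e4, 1e4),
                                    n_trials = 50L, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop_invalid("alpha must be in [0, 1]")
  lnames <- if (is.null(names(widths))) {
    sprintf("layer%02d", seq_along(widths))
  } else {
    names(widths)
  }
  with_seed(seed, {
    lapply(seq_len(n_trials), function(t) {
      win <- lapply(widths, function(w) stats::rnorm(w))
      los <- lapply(widths, function(w) stats::rnorm(w))
      mix <- lapply(seq_along(widths), function(i) {
        alpha * win[[i]] + sqrt(1 - alpha^2) * stats::rnorm(widths[i])
      })
      list(mix = stats::setNames(mix, lnames),
           winner = stats::setNames(win, lnames),
           loser = stats::setNames(los, lnames))
    })
  })
}

#' Simulate a coded human-report table
#'
#' Emulates the already-coded outcome table of a brief-presentation
#' experiment: each participant sees `trials_per_participant` mixtures and
#' each report is one of the four scenario codes, drawn from the given
#' probabilities.
#'
#' @param probabilities named numeric vector over
#'   `c("none", "first", "second", "both")`, summing to 1.
#' @param n_participants number of participants.
#' @param trials_per_participant trials per participant.
#' @param condition condition label stored with every row.
#' @param seed integer seed.
#' @return data.frame: participant_id, pair_id, condition, scenario_code.
#' @export
make_report_table <- function(probabilities, n_participants = 100L,
                              trials_per_participant = 30L,
                              condition = "cond1", seed = 1L) {
  codes <- c("none", "first", "second", "both")
  if (!setequal(names(probabilities), codes)) {
    stop_invalid("probabilities must be named over %s",
                 paste(codes, collapse = "/"))
  }
  probabilities <- probabilities[codes]
  if (abs(sum(probabilities) - 1) > 1e-9) {
    stop_invalid("probabilities must sum to 1")
  }
  n <- n_participants * trials_per_participant
  draws <- with_seed(seed, sample(codes, n, replace = TRUE,
                                  prob = probabilities))
  data.frame(
    participant_id = rep(sprintf("p%04d", seq_len(n_participants)),
                         each = trials_per_participant),
    pair_id = rep(sprintf("pair%03d", seq_len(trials_per_participant)),
                  times = n_participants),
    condition = condition,
    scenario_code = draws,
    stringsAsFactors = FALSE)
}

#' Aggregate a coded report table into scenario proportions
#'
#' @param reports data.frame as produced by [make_report_table()] (or read
#'   from CSV with the same columns).
#' @return list with `p_none`, `p_one`, `p_both` (overall proportions) and
#'   `se_*` (standard errors across participants), plus `n_participants`,
#'   `n_trials`.
#' @export
aggregate_report_table <- function(reports) {
  if (!all(c("participant_id", "scenario_code") %in% names(reports))) {
    stop_invalid("reports must have participant_id and scenario_code columns")
  }
  cls <- scenario_class(reports$scenario_code)
  per <- do.call(rbind, lapply(split(cls, reports$participant_id), function(s) {
    c(none = mean(s == "none"), one = mean(s == "one"),
      both = mean(s == "both"))
  }))
  np <- nrow(per)
  se <- if (np > 1) apply(per, 2, stats::sd) / sqrt(np) else rep(NA_real_, 3)
  list(p_none = mean(cls == "none"), p_one = mean(cls == "one"),
       p_both = mean(cls == "both"),
       se_none = unname(se[1]), se_one = unname(se[2]),
       se_both = unname(se[3]),
       n_participants = np, n_trials = length(cls))
}
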