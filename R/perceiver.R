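#' Build a deterministic mock perceiver
#'
#' A layered stand-in for a pretrained recognition network, so every
#' downstream analysis is testable without trained weights: a fixed-seed
#' hierarchy of dense Gaussian linear filters with thresholded rectification
#' (activations more than `threshold` preactivation-SDs below saturation are
#' zeroed, which sparsifies and decorrelates the representations), ending in
#' a cosine-similarity classification head against K fixed seeded templates,
#' scaled to logits. Bit-reproducible for a given seed and architecture.
#' Without the sparsifying threshold all images share the input's DC
#' direction and mixtures trivially overlap both sources' top-N sets.
#'
#' Hidden layers are exposed as 8-channel activation matrices
#' (channels x units), the final layer as a flat unit vector, so both
#' correlation conventions of [layer_correlations()] are exercised.
#'
#' @param seed integer seed fixing all weights.
#' @param K number of output categories (>= 2); the default mirrors a
#'   1000-category classifier, keeping chance top-5 overlap low (~2.5%).
#' @param layer_widths widths of the hidden layers (each a multiple of 8).
#' @param input_side input image side in pixels; other sizes are
#'   standardized on the way in.
#' @param logit_scale multiplier mapping cosine similarities to logits.
#' @param threshold rectification threshold in units of the layer's
#'   preactivation SD (0 = plain ReLU; default 1 keeps ~16% of units active).
#' @return object of class `perceiver` with fields `K`, `layer_names`,
#'   `input_side`, and closures `classify(image)` -> list(logits,
#'   probabilities) and `activations(image)` -> named activation stack.
#' @export
build_mock_perceiver <- function(seed = 1L, K = 1000L,
                                 layer_widths = c(256L, 128L, 64L),
                                 input_side = 64L, logit_scale = 10,
                                 threshold = 1) {
  if (K < 2L) stop_invalid("K must be >= 2")
  if (length(layer_widths) < 1L || any(layer_widths < 8L) ||
      any(layer_widths %% 8L != 0L)) {
    stop_invalid("layer_widths must be multiples of 8, each >= 8")
  }
  in_dim <- input_side^2 * 3L
  dims <- c(in_dim, layer_widths)
  pieces <- with_seed(seed, {
    W <- lapply(seq_along(layer_widths), function(i) {
      matrix(stats::rnorm(dims[i + 1] * dims[i]), dims[i + 1], dims[i])
    })
    templates <- matrix(stats::rnorm(K * layer_widths[length(layer_widths)]),
                        K)
    list(W = W, templates = templates)
  })
  layer_names <- sprintf("layer%02d", seq_along(layer_widths))
  tnorm <- sqrt(rowSums(pieces$templates^2))

  forward <- function(image) {
    assert_image(image)
    if (dim(image)[1] != input_side || dim(image)[2] != input_side) {
      image <- standardize(image, input_side)
    }
    v <- as.numeric(unclass(image)) / 255 - 0.5
    acts <- vector("list", length(pieces$W))
    for (i in seq_along(pieces$W)) {
      pre <- drop(pieces$W[[i]] %*% v) / sqrt(length(v))
      v <- pmax(pre - threshold * stats::sd(pre), 0)
      acts[[i]] <- v
    }
    names(acts) <- layer_names
    acts
  }

  classify <- function(image) {
    h <- forward(image)[[length(layer_names)]]
    hn <- sqrt(sum(h^2))
    cosine <- if (hn == 0) rep(0, K) else
      drop(pieces$templates %*% h) / (tnorm * hn)
    logits <- logit_scale * cosine
    noisy_softmax(logits, sigma = 0)
  }

  activations <- function(image) {
    acts <- forward(image)
    nlay <- length(acts)
    out <- lapply(seq_len(nlay), function(i) {
      if (i < nlay) matrix(acts[[i]], nrow = 8L) else acts[[i]]
    })
    stats::setNames(out, layer_names)
  }

  structure(list(K = K, layer_names = layer_names, input_side = input_side,
                 seed = seed, layer_widths = layer_widths,
                 threshold = threshold,
                 classify = classify, activations = activations),
            class = "perceiver")
}

#' @export
print.perceiver <- function(x, ...) {
  cat(sprintf("<perceiver: K = %d, layers %s, input %dx%d, seed %d>\n",
              x$K, paste(x$layer_widths, collapse = "-"),
              x$input_side, x$input_side, x$seed))
  invisible(x)
}

#' Run the visual competition for a mixture set against a perceiver
#'
#' Classifies each mixture and both of its sources, applies the top-N overlap
#' rule, and attaches the six retained image parameters of each source,
#' yielding one trial record per mixture (per iteration when noise is
#' injected). Mixtures whose sources are missing from `sources` are skipped
#' with a warning.
#'
#' @param perceiver a `perceiver` (anything with `classify`).
#' @param mixtures output of [build_mixture_set()] (with images attached).
#' @param sources named list of source `image_rgb`s.
#' @param n top-N threshold (default 5).
#' @param sigma logit noise SD; 0 gives a single deterministic pass.
#' @param iterations noise re-draws when `sigma > 0`.
#' @param seed noise seed.
#' @param keep_distributions attach the per-trial probability vectors as an
#'   attribute `"distributions"`.
#' @return data.frame with pair_id, mode, source1_id, source2_id, phase_role,
#'   iteration, scenario, winner, y, and feature columns `<name>_1`,
#'   `<name>_2`; `y` is 1/0 when exactly one source was chosen, else NA.
#' @export
run_competition <- function(perceiver, mixtures, sources, n = 5L, sigma = 0,
                            iterations = 1L, seed = 1L,
                            keep_distributions = FALSE) {
  feats <- lapply(sources, extract_features)
  dist_cache <- new.env(parent = emptyenv())
  get_dist <- function(id) {
    if (!exists(id, envir = dist_cache)) {
      assign(id, perceiver$classify(sources[[id]]), envir = dist_cache)
    }
    get(id, envir = dist_cache)
  }
  rows <- list()
  dists <- list()
  with_seed(seed, {
    for (rec in mixtures) {
      if (!rec$source1_id %in% names(sources) ||
          !rec$source2_id %in% names(sources)) {
        warning(sprintf("skipping %s: missing source image", rec$id))
        next
      }
      mix_d <- perceiver$classify(rec$mixed)
      d1 <- get_dist(rec$source1_id)
      d2 <- get_dist(rec$source2_id)
      f1 <- feats[[rec$source1_id]]
      f2 <- feats[[rec$source2_id]]
      iters <- if (sigma > 0) seq_len(iterations) else 1L
      for (it in iters) {
        md <- if (sigma > 0) noisy_softmax(mix_d$logits, sigma) else mix_d
        o1 <- if (sigma > 0) noisy_softmax(d1$logits, sigma) else d1
        o2 <- if (sigma > 0) noisy_softmax(d2$logits, sigma) else d2
        sc <- classify_scenario(md, o1, o2, n)
        row <- data.frame(pair_id = rec$id, mode = rec$mode,
                          source1_id = rec$source1_id,
                          source2_id = rec$source2_id,
                          phase_role = rec$phase_role,
                          iteration = it, scenario = sc$value,
                          winner = if (is.na(sc$winner)) NA_character_ else
                            sc$winner,
                          y = switch(sc$value, first = 1L, second = 0L,
                                     NA_integer_),
                          stringsAsFactors = FALSE)
        for (nmf in names(f1)) {
          row[[paste0(nmf, "_1")]] <- unname(f1[nmf])
          row[[paste0(nmf, "_2")]] <- unname(f2[nmf])
        }
        rows[[length(rows) + 1L]] <- row
      }
      if (keep_distributions) {
        dists[[rec$id]] <- list(mix = mix_d$probabilities,
                                orig1 = d1$probabilities,
                                orig2 = d2$probabilities,
                                logits = list(mix = mix_d$logits,
                                              orig1 = d1$logits,
                                              orig2 = d2$logits))
      }
    }
  })
  out <- do.call(rbind, rows)
  if (keep_distributions) attr(out, "distributions") <- dists
  out
}
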