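#' Luminance and global contrast of an image
#'
#' Luminance is the pixel mean of the weighted intensity
#' 0.299 R + 0.587 G + 0.114 B; global contrast is the population standard
#' deviation of the same per-pixel quantity.
#'
#' @param image an `image_rgb`.
#' @return named vector `c(luminance =, global_contrast =)`.
#' @export
weighted_intensity_stats <- function(image) {
  y <- weighted_intensity(image)
  mu <- mean(y)
  c(luminance = mu, global_contrast = sqrt(mean((y - mu)^2)))
}

#' Gradient energy of the weighted-intensity image
#'
#' Sum over pixels of squared first-order forward differences of the
#' luminance plane along the requested axis; `"both"` is the sum of the
#' horizontal and vertical energies.
#'
#' @param image an `image_rgb`.
#' @param axis `"horizontal"` (differences along rows, i.e. between adjacent
#'   columns), `"vertical"`, or `"both"`.
#' @return scalar gradient energy (squared intensity units).
#' @export
gradient_energy <- function(image, axis = c("both", "horizontal", "vertical")) {
  axis <- match.arg(axis)
  y <- weighted_intensity(image)
  h <- sum((y[, -1, drop = FALSE] - y[, -ncol(y), drop = FALSE])^2)
  v <- sum((y[-1, , drop = FALSE] - y[-nrow(y), , drop = FALSE])^2)
  switch(axis, horizontal = h, vertical = v, both = h + v)
}

# signed per-axis DFT frequencies normalized so Nyquist = 1
normalized_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n / 2)
}

#' Spectral band energy of the weighted-intensity image
#'
#' Sum of 2-D DFT magnitudes over bins whose radial frequency (Euclidean norm
#' of the signed per-axis frequencies, each normalized to Nyquist = 1) is
#' <= 0.25 ("low", DC included) or >= 0.75 ("high"). Unnormalized forward
#' transform.
#'
#' @param image an `image_rgb`.
#' @param band `"low"` or `"high"`.
#' @return scalar band energy (intensity units).
#' @export
spectral_band_energy <- function(image, band = c("low", "high")) {
  band <- match.arg(band)
  y <- weighted_intensity(image)
  F <- stats::fft(y)
  fr <- normalized_freqs(nrow(y))
  fc <- normalized_freqs(ncol(y))
  r <- sqrt(outer(fr^2, fc^2, `+`))
  mask <- if (band == "low") r <= 0.25 else r >= 0.75
  sum(Mod(F)[mask])
}

#' Chromatic statistics of an image
#'
#' Colorfulness is the pixel sum of the IQ-plane chroma magnitude
#' sqrt(I^2 + Q^2) under the standard RGB -> YIQ transform
#' (I = 0.596 R - 0.274 G - 0.322 B, Q = 0.211 R - 0.523 G + 0.312 B).
#' Saturation is the pixel mean of 255 (max(R,G,B) - min(R,G,B)) / max(R,G,B),
#' defined as 0 at black pixels (removable singularity). Per-channel means are
#' also returned.
#'
#' @param image an `image_rgb`.
#' @return named vector with colorfulness, saturation, avg_red, avg_green,
#'   avg_blue.
#' @export
color_stats <- function(image) {
  assert_image(image)
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  I <- 0.596 * R - 0.274 * G - 0.322 * B
  Q <- 0.211 * R - 0.523 * G + 0.312 * B
  mx <- pmax(R, G, B)
  mn <- pmin(R, G, B)
  sat <- ifelse(mx == 0, 0, 255 * (mx - mn) / mx)
  c(colorfulness = sum(sqrt(I^2 + Q^2)),
    saturation = mean(sat),
    avg_red = mean(R), avg_green = mean(G), avg_blue = mean(B))
}

#' Local contrast of an image
#'
#' Mean over non-overlapping tile x tile blocks of the population standard
#' deviation of weighted intensity inside each block; edge remainders that do
#' not fill a block are dropped.
#'
#' @param image an `image_rgb`.
#' @param tile block side in pixels, >= 2 and <= min(H, W). Default 8.
#' @return scalar local contrast.
#' @export
local_contrast <- function(image, tile = 8L) {
  y <- weighted_intensity(image)
  h <- nrow(y); w <- ncol(y)
  if (tile < 2L || tile > min(h, w)) {
    stop_invalid("tile must be in [2, min(H, W)]")
  }
  nbr <- h %/% tile
  nbc <- w %/% tile
  sds <- numeric(nbr * nbc)
  k <- 0L
  for (bi in seq_len(nbr)) {
    for (bj in seq_len(nbc)) {
      blk <- y[(bi - 1L) * tile + seq_len(tile),
               (bj - 1L) * tile + seq_len(tile)]
      k <- k + 1L
      sds[k] <- sqrt(mean((blk - mean(blk))^2))
    }
  }
  mean(sds)
}

#' The six retained image parameters
#'
#' The parameters retained after de-correlating the initial feature set:
#' gradient energy, low-frequency spectral energy, luminance, global
#' contrast, colorfulness, and saturation.
#'
#' @param image an `image_rgb`.
#' @return named numeric vector of the six parameters.
#' @export
extract_features <- function(image) {
  ws <- weighted_intensity_stats(image)
  cs <- color_stats(image)
  c(gradient = gradient_energy(image, "both"),
    low_frequencies = spectral_band_energy(image, "low"),
    luminance = unname(ws["luminance"]),
    global_contrast = unname(ws["global_contrast"]),
    colorfulness = unname(cs["colorfulness"]),
    saturation = unname(cs["saturation"]))
}

#' The extended initial feature set
#'
#' The full initial feature list before de-correlation: the six retained
#' parameters plus per-channel means, local contrast, the separate horizontal
#' and vertical gradient energies, and high-frequency spectral energy.
#'
#' @param image an `image_rgb`.
#' @param tile tile side for local contrast (default 8).
#' @return named numeric vector of 13 features.
#' @export
extract_extended <- function(image, tile = 8L) {
  base <- extract_features(image)
  cs <- color_stats(image)
  c(base,
    avg_red = unname(cs["avg_red"]),
    avg_green = unname(cs["avg_green"]),
    avg_blue = unname(cs["avg_blue"]),
    local_contrast = local_contrast(image, tile),
    horizontal_gradient = gradient_energy(image, "horizontal"),
    vertical_gradient = gradient_energy(image, "vertical"),
    high_frequencies = spectral_band_energy(image, "high"))
}

#' Feature table for an image bank
#'
#' @param images named list of `image_rgb`.
#' @param extended include the full initial set (default) or only the six
#'   retained parameters.
#' @return data.frame, one row per image, first column `id`.
#' @export
feature_table <- function(images, extended = TRUE) {
  f <- if (extended) extract_extended else extract_features
  rows <- t(vapply(images, f, f(images[[1]])))
  data.frame(id = names(images), rows, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Greedy selection of mutually least-correlated features
#'
#' Starts from the pair of features with the lowest absolute Pearson
#' correlation across images, then repeatedly adds the feature minimizing the
#' maximum absolute correlation with the chosen set, until `k` features are
#' selected. Ties are broken lexicographically by feature name, so the
#' selection is deterministic. Constant columns have undefined correlation;
#' they are treated as correlation 1 with everything and flagged.
#'
#' @param feature_table data.frame as returned by [feature_table()] (an `id`
#'   column is ignored) or a numeric matrix, rows = images.
#' @param k number of features to retain.
#' @return list with `selected` (feature names in selection order) and
#'   `flagged_constant` (names of constant columns).
#' @export
select_least_correlated <- function(feature_table, k = 6L) {
  X <- feature_table
  if (is.data.frame(X)) {
    X <- as.matrix(X[vapply(X, is.numeric, TRUE)])
  }
  if (nrow(X) < 3L) stop_invalid("need >= 3 images to estimate correlations")
  p <- ncol(X)
  if (k < 1L || k > p) stop_invalid("k must be in [1, %d]", p)
  nm <- colnames(X)
  constant <- apply(X, 2, function(col) stats::sd(col) == 0)
  C <- suppressWarnings(abs(stats::cor(X)))
  C[constant, ] <- 1
  C[, constant] <- 1
  diag(C) <- 0
  # lexicographic order for deterministic tie-breaks
  ord <- order(nm)
  best <- c(NA_integer_, NA_integer_)
  best_val <- Inf
  for (a in seq_len(p - 1L)) for (b in (a + 1L):p) {
    i <- ord[a]; j <- ord[b]
    if (C[i, j] < best_val - 1e-15) {
      best_val <- C[i, j]
      best <- c(i, j)
    }
  }
  if (k == 1L) {
    return(list(selected = nm[best[1]], flagged_constant = nm[constant]))
  }
  chosen <- best
  while (length(chosen) < k) {
    remaining <- setdiff(ord, chosen)
    scores <- vapply(remaining, function(j) max(C[j, chosen]), 0)
    chosen <- c(chosen, remaining[which.min(scores)])
  }
  list(selected = nm[chosen], flagged_constant = nm[constant])
}
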