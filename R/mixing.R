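#' Pixel-average ("50/50") mixture of two images
#'
#' Each output channel value is the arithmetic mean of the two inputs at that
#' pixel and channel. Symmetric in its arguments.
#'
#' @param image1,image2 `image_rgb` objects of equal dimensions.
#' @param quantize round half up to integer levels (default TRUE). With
#'   `quantize = FALSE` the exact means are returned.
#' @return an `image_rgb`.
#' @export
mix_average <- function(image1, image2, quantize = TRUE) {
  assert_image(image1, "image1"); assert_image(image2, "image2")
  if (!identical(dim(image1), dim(image2))) {
    stop_invalid("dimension mismatch: %s vs %s",
                 paste(dim(image1), collapse = "x"),
                 paste(dim(image2), collapse = "x"))
  }
  m <- (unclass(image1) + unclass(image2)) / 2
  if (quantize) m <- quantize_pixels(m)
  image_rgb(m)
}

#' Fourier phase/magnitude hybrid of two images
#'
#' Per RGB channel independently: take the 2-D DFT of both sources, combine
#' the magnitude spectrum of `magnitude_source` with the phase spectrum of
#' `phase_source`, invert, keep the real part, then clamp to \[0, 255\] and
#' quantize. The pre-quantization result's magnitude spectrum equals
#' `magnitude_source`'s exactly (up to floating-point error).
#'
#' DFT convention: unnormalized forward transform, 1/(H·W) on the inverse.
#'
#' @param phase_source image supplying the phase spectrum.
#' @param magnitude_source image supplying the magnitude spectrum.
#' @param quantize clamp + round to integer levels (default TRUE). With
#'   `FALSE` the raw pre-quantization real part is returned as a plain array
#'   (it can leave \[0, 255\]); this is the object whose magnitude spectrum
#'   conserves the source's.
#' @return an `image_rgb`, or a plain H x W x 3 array when
#'   `quantize = FALSE`.
#' @export
mix_phase_magnitude <- function(phase_source, magnitude_source,
                                quantize = TRUE) {
  assert_image(phase_source, "phase_source")
  assert_image(magnitude_source, "magnitude_source")
  if (!identical(dim(phase_source), dim(magnitude_source))) {
    stop_invalid("dimension mismatch between phase and magnitude sources")
  }
  d <- dim(phase_source)
  npix <- d[1] * d[2]
  out <- array(0, dim = d)
  for (ch in 1:3) {
    fp <- stats::fft(phase_source[, , ch])
    fm <- stats::fft(magnitude_source[, , ch])
    hybrid <- Mod(fm) * exp(1i * Arg(fp))
    out[, , ch] <- Re(stats::fft(hybrid, inverse = TRUE)) / npix
  }
  if (!quantize) return(out)
  image_rgb(quantize_pixels(out))
}

#' Build a set of mixtures from an image bank
#'
#' `all_pairwise` enumerates every unordered pair for 50/50 averages
#' (n(n-1)/2 records) and every ordered pair for phase/magnitude hybrids
#' (n(n-1) records, the two role assignments being distinct stimuli).
#' `unique_pairing` draws a seeded random perfect matching, each image
#' appearing exactly once (n/2 records), as used for human testing where
#' repeated images could cause memory biases.
#'
#' @param images named list of `image_rgb` objects (names are the ids).
#' @param mode `"average_5050"` or `"phase_magnitude"`.
#' @param pairing `"all_pairwise"` or `"unique_pairing"`.
#' @param seed integer seed (required for `unique_pairing`).
#' @param keep_images attach the mixed image to each record (default TRUE).
#' @return list of mixture records; each has `id`, `mode`, `source1_id`,
#'   `source2_id`, `phase_role` (for hybrids, `source1_id` supplies the
#'   phase) and, unless disabled, `mixed`.
#' @export
build_mixture_set <- function(images,
                              mode = c("average_5050", "phase_magnitude"),
                              pairing = c("all_pairwise", "unique_pairing"),
                              seed = 1L, keep_images = TRUE) {
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  n <- length(images)
  if (n < 2L) stop_invalid("need at least 2 images")
  ids <- names(images)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_invalid("images must be a uniquely named list")
  }
  pairs <- switch(pairing,
    all_pairwise = {
      idx <- utils::combn(n, 2L)
      p <- data.frame(i = idx[1, ], j = idx[2, ])
      if (mode == "phase_magnitude") rbind(p, data.frame(i = p$j, j = p$i)) else p
    },
    unique_pairing = {
      if (n %% 2L != 0L) {
        stop_invalid("unique_pairing requires an even number of images")
      }
      perm <- with_seed(seed, sample.int(n))
      data.frame(i = perm[seq(1L, n, by = 2L)], j = perm[seq(2L, n, by = 2L)])
    }
  )
  lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    rec <- list(
      id = sprintf("%s__%s__%s",
                   if (mode == "average_5050") "avg" else "phsmag",
                   ids[i], ids[j]),
      mode = mode,
      source1_id = ids[i],
      source2_id = ids[j],
      phase_role = if (mode == "phase_magnitude") ids[i] else NA_character_
    )
    if (keep_images) {
      rec$mixed <- if (mode == "average_5050") {
        mix_average(images[[i]], images[[j]])
      } else {
        mix_phase_magnitude(images[[i]], images[[j]])
      }
    }
    rec
  })
}

#' Manifest table for a mixture set
#'
#' @param mixtures output of [build_mixture_set()].
#' @return data.frame with columns id, mode, source1_id, source2_id,
#'   phase_role.
#' @export
mixture_manifest <- function(mixtures) {
  data.frame(
    id = vapply(mixtures, `[[`, "", "id"),
    mode = vapply(mixtures, `[[`, "", "mode"),
    source1_id = vapply(mixtures, `[[`, "", "source1_id"),
    source2_id = vapply(mixtures, `[[`, "", "source2_id"),
    phase_role = vapply(mixtures, `[[`, "", "phase_role"),
    stringsAsFactors = FALSE
  )
}
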