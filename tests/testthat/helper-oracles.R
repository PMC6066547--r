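# Definition-level oracles, kept deliberately naive and independent of the
# package's implementation paths.

rand_image <- function(h, w, seed) {
  set.seed(seed)
  image_rgb(array(runif(h * w * 3, 0, 255), c(h, w, 3)))
}

rand_gray_image <- function(h, w, seed) {
  set.seed(seed)
  image_rgb(matrix(runif(h * w, 0, 255), h, w))
}

luma_oracle <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# O(n^4) 2-D DFT straight from the definition sum
dft2_brute <- function(x) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0 + 0i, H, W)
  for (u in 0:(H - 1)) for (v in 0:(W - 1)) {
    s <- 0 + 0i
    for (a in 0:(H - 1)) for (b in 0:(W - 1)) {
      s <- s + x[a + 1, b + 1] *
        exp(-2i * pi * (u * a / H + v * b / W))
    }
    out[u + 1, v + 1] <- s
  }
  out
}

# band energy oracle with the same radial mask definition, via brute DFT
band_energy_brute <- function(y, band) {
  F <- dft2_brute(y)
  sf <- function(n) {
    k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n; k / (n / 2)
  }
  fr <- sf(nrow(y)); fc <- sf(ncol(y))
  total <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
    r <- sqrt(fr[i]^2 + fc[j]^2)
    keep <- if (band == "low") r <= 0.25 else r >= 0.75
    if (keep) total <- total + Mod(F[i, j])
  }
  total
}

gradient_brute <- function(y, axis) {
  h <- 0; v <- 0
  for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y) - 1)) {
    h <- h + (y[i, j + 1] - y[i, j])^2
  }
  for (i in seq_len(nrow(y) - 1)) for (j in seq_len(ncol(y))) {
    v <- v + (y[i + 1, j] - y[i, j])^2
  }
  switch(axis, horizontal = h, vertical = v, both = h + v)
}

local_contrast_brute <- function(y, tile) {
  vals <- c()
  for (bi in seq_len(nrow(y) %/% tile)) {
    for (bj in seq_len(ncol(y) %/% tile)) {
      blk <- y[(bi - 1) * tile + 1:tile, (bj - 1) * tile + 1:tile]
      vals <- c(vals, sqrt(mean((blk - mean(blk))^2)))
    }
  }
  mean(vals)
}

chroma_brute <- function(r, g, b) {
  M <- matrix(c(0.299, 0.587, 0.114,
                0.596, -0.274, -0.322,
                0.211, -0.523, 0.312), 3, byrow = TRUE)
  yiq <- M %*% c(r, g, b)
  sqrt(yiq[2]^2 + yiq[3]^2)
}

# Clopper-Pearson by bisection on the exact binomial tail conditions
cp_brute <- function(k, n, level = 0.95, tol = 1e-10) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else
    bisect(function(p) sum(dbinom(k:n, n, p)) - alpha / 2, 0, 1)
  upper <- if (k == n) 1 else
    bisect(function(p) {
      -(sum(dbinom(0:k, n, p)) - alpha / 2)
    }, 0, 1)
  c(lower = lower, upper = upper)
}

pearson_brute <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# exhaustive scenario oracle: plain set intersections of explicit top-n sets
scenario_brute <- function(top_mix, top1, top2) {
  c1 <- length(intersect(top_mix, top1)) > 0
  c2 <- length(intersect(top_mix, top2)) > 0
  if (c1 && c2) "both" else if (c1) "first" else if (c2) "second" else "none"
}

softmax_closed <- function(z) exp(z) / sum(exp(z))
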