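#' Softmax with optional Gaussian noise injected into the logits
#'
#' Computes probabilities = softmax(logits + eps) with eps i.i.d. Gaussian of
#' standard deviation `sigma`, emulating stochastic choice in an otherwise
#' deterministic classifier. `sigma = 0` reduces to the deterministic
#' softmax. Numerically stabilized by max-subtraction.
#'
#' @param logits numeric vector of K >= 2 finite pre-softmax activations.
#' @param sigma noise standard deviation, >= 0.
#' @return list with `logits` (the perturbed logits actually used) and
#'   `probabilities` (length K, summing to 1).
#' @export
noisy_softmax <- function(logits, sigma = 0) {
  if (length(logits) < 2L) stop_invalid("need at least 2 categories")
  if (!all(is.finite(logits))) stop_invalid("logits must be finite")
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  z <- logits
  if (sigma > 0) z <- z + stats::rnorm(length(z), sd = sigma)
  e <- exp(z - max(z))
  list(logits = z, probabilities = e / sum(e))
}

#' Top-N categories of a probability distribution
#'
#' @param probabilities numeric vector (or the list returned by
#'   [noisy_softmax()]).
#' @param n number of categories, 1 <= n <= K.
#' @return integer vector of the n highest-probability category indices in
#'   descending probability order; ties broken by ascending index.
#' @export
top_n <- function(probabilities, n) {
  if (is.list(probabilities)) probabilities <- probabilities$probabilities
  K <- length(probabilities)
  if (n < 1L || n > K) stop_invalid("n must be in [1, K]")
  order(-probabilities, seq_len(K))[seq_len(n)]
}

#' Classify a mixture trial into one of the four competition scenarios
#'
#' A source image is "chosen" iff the top-N categories of the mixture's
#' output distribution intersect the top-N categories of that source's
#' distribution. The trial outcome is `none`, `first`, `second`, or `both`
#' accordingly; `winner` carries the single chosen source when exactly one is
#' chosen.
#'
#' @param mix_dist,orig1_dist,orig2_dist probability vectors over the same K
#'   categories (or [noisy_softmax()] results).
#' @param n top-N threshold (default 5).
#' @return list with `value` in `c("none","first","second","both")` and
#'   `winner` (`"source1"`, `"source2"`, or NA).
#' @export
classify_scenario <- function(mix_dist, orig1_dist, orig2_dist, n = 5L) {
  p <- lapply(list(mix_dist, orig1_dist, orig2_dist),
              function(d) if (is.list(d)) d$probabilities else d)
  K <- length(p[[1]])
  if (length(p[[2]]) != K || length(p[[3]]) != K) {
    stop_invalid("all three distributions must share the same K")
  }
  tm <- top_n(p[[1]], n)
  chose1 <- length(intersect(tm, top_n(p[[2]], n))) > 0L
  chose2 <- length(intersect(tm, top_n(p[[3]], n))) > 0L
  value <- if (chose1 && chose2) "both"
           else if (chose1) "first"
           else if (chose2) "second"
           else "none"
  list(value = value,
       winner = switch(value, first = "source1", second = "source2",
                       NA_character_))
}

scenario_class <- function(values) {
  ifelse(values == "none", "none",
         ifelse(values == "both", "both", "one"))
}

#' Scenario probabilities by repeated subsampling
#'
#' Per iteration, draws `sample_size` trials without replacement from the
#' scenario pool and computes the proportions of the three aggregate outcomes
#' (none / one image chosen / both); reports the across-iteration mean and
#' standard error. Defaults mirror the reference protocol: 90 mixtures
#' sampled per iteration, 100 iterations.
#'
#' @param scenarios character vector of scenario values
#'   (`none`/`first`/`second`/`both`) or a list of [classify_scenario()]
#'   results.
#' @param sample_size mixtures drawn per iteration (<= length of pool).
#' @param iterations number of subsampling iterations.
#' @param seed integer seed.
#' @return list with `p_none`, `p_one`, `p_both`, matching `se_*` standard
#'   errors, `n_iterations`, `sample_size`.
#' @export
scenario_probabilities <- function(scenarios, sample_size = 90L,
                                   iterations = 100L, seed = 1L) {
  if (is.list(scenarios)) {
    scenarios <- vapply(scenarios, `[[`, "", "value")
  }
  if (length(scenarios) == 0L) stop_invalid("empty scenario list")
  if (sample_size > length(scenarios)) {
    stop_invalid("sample_size exceeds the number of scenarios")
  }
  cls <- scenario_class(scenarios)
  props <- with_seed(seed, {
    t(vapply(seq_len(iterations), function(it) {
      s <- cls[sample.int(length(cls), sample_size)]
      c(none = mean(s == "none"), one = mean(s == "one"),
        both = mean(s == "both"))
    }, c(none = 0, one = 0, both = 0)))
  })
  m <- colMeans(props)
  se <- apply(props, 2, stats::sd) / sqrt(iterations)
  list(p_none = unname(m["none"]), p_one = unname(m["one"]),
       p_both = unname(m["both"]),
       se_none = unname(se["none"]), se_one = unname(se["one"]),
       se_both = unname(se["both"]),
       n_iterations = iterations, sample_size = sample_size)
}

#' Sweep the injected-noise level and find the best match to a reference
#'
#' For each sigma in the grid, re-draws noisy output distributions per trial
#' per iteration, classifies the scenarios, and aggregates the three-scenario
#' proportions. `best_sigma` minimizes the total-variation distance to the
#' reference proportions (e.g. human report proportions); ties break toward
#' smaller sigma.
#'
#' @param trial_logits list of trials, each a list with elements `mix`,
#'   `orig1`, `orig2` holding logit vectors over the same K categories.
#' @param n top-N threshold.
#' @param sigma_grid non-empty numeric vector of noise SDs, all >= 0.
#' @param reference list with `p_none`, `p_one`, `p_both` (any object with
#'   those names, e.g. a [scenario_probabilities()] result).
#' @param iterations noise re-draws per sigma (default 100).
#' @param sample_size mixtures drawn per iteration; `NULL` (default) uses the
#'   whole trial set each iteration.
#' @param noise_all if TRUE (default) noise is injected into the mixture's
#'   and both originals' logits; if FALSE only the mixture's.
#' @param seed integer seed.
#' @return list with `sweep` (data.frame: sigma, p_none, p_one, p_both and
#'   SEs, tv_distance) and `best_sigma`.
#' @export
sigma_sweep <- function(trial_logits, n = 5L, sigma_grid = seq(0, 5, by = 0.5),
                        reference, iterations = 100L, sample_size = NULL,
                        noise_all = TRUE, seed = 1L) {
  if (length(sigma_grid) == 0L || any(sigma_grid < 0)) {
    stop_invalid("sigma_grid must be non-empty and non-negative")
  }
  ref <- c(reference$p_none, reference$p_one, reference$p_both)
  rows <- lapply(seq_along(sigma_grid), function(si) {
    sigma <- sigma_grid[si]
    props <- with_seed(child_seed(seed, si), {
      t(vapply(seq_len(iterations), function(it) {
        vals <- vapply(trial_logits, function(tr) {
          mix <- noisy_softmax(tr$mix, sigma)
          o1 <- noisy_softmax(tr$orig1, if (noise_all) sigma else 0)
          o2 <- noisy_softmax(tr$orig2, if (noise_all) sigma else 0)
          classify_scenario(mix, o1, o2, n)$value
        }, "")
        cls <- scenario_class(vals)
        if (!is.null(sample_size)) {
          cls <- cls[sample.int(length(cls), sample_size)]
        }
        c(mean(cls == "none"), mean(cls == "one"), mean(cls == "both"))
      }, numeric(3)))
    })
    m <- colMeans(props)
    se <- apply(props, 2, stats::sd) / sqrt(iterations)
    data.frame(sigma = sigma, p_none = m[1], p_one = m[2], p_both = m[3],
               se_none = se[1], se_one = se[2], se_both = se[3],
               tv_distance = 0.5 * sum(abs(m - ref)))
  })
  sweep <- do.call(rbind, rows)
  best_sigma <- sweep$sigma[which.min(sweep$tv_distance)]  # first min: small sigma
  list(sweep = sweep, best_sigma = best_sigma)
}
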