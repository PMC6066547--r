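#' Per-layer correlations between two activation stacks
#'
#' An activation stack is a named, ordered list of per-layer activations:
#' a matrix (channels x units) for convolutional-style layers or a numeric
#' vector for fully connected layers. For matrix layers the Pearson
#' correlation is computed per channel map (row) and averaged over channels
#' ("per_channel", the default) or over the whole flattened layer
#' ("flatten"); constant maps contribute correlation 0 and are counted, so
#' layer averages stay comparable across images.
#'
#' @param stack_a,stack_b activation stacks with identical layer structure.
#' @param method `"per_channel"` or `"flatten"`.
#' @return named numeric vector, one correlation per layer.
#' @export
layer_correlations <- function(stack_a, stack_b,
                               method = c("per_channel", "flatten")) {
  method <- match.arg(method)
  if (!identical(names(stack_a), names(stack_b))) {
    stop_invalid("layer names differ between stacks")
  }
  vapply(seq_along(stack_a), function(i) {
    a <- stack_a[[i]]; b <- stack_b[[i]]
    if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
      stop_invalid("shape mismatch at layer %s", names(stack_a)[i])
    }
    if (is.matrix(a) && method == "per_channel") {
      mean(vapply(seq_len(nrow(a)), function(ch) {
        safe_pearson(a[ch, ], b[ch, ])
      }, 0))
    } else {
      safe_pearson(as.numeric(a), as.numeric(b))
    }
  }, 0, USE.NAMES = FALSE) -> r
  stats::setNames(r, names(stack_a))
}

# Pearson correlation with constant vectors mapped to 0 (stated convention)
safe_pearson <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

profile_from_cors <- function(cor_rows) {
  m <- do.call(rbind, cor_rows)
  n <- nrow(m)
  data.frame(layer = colnames(m),
             mean = colMeans(m),
             se = if (n > 1) apply(m, 2, stats::sd) / sqrt(n)
                  else rep(NA_real_, ncol(m)),
             n = n, row.names = NULL, stringsAsFactors = FALSE)
}

#' Winner/loser layer-correlation profiles
#'
#' For trials where one source image won, correlates the mixture's activation
#' stack with the winning and losing sources' stacks per layer, and averages
#' across trials. The per-layer difference (winner minus loser) localizes
#' where in the hierarchy the competition is resolved.
#'
#' @param trials list of trials, each a list with `mix`, `winner`, `loser`
#'   activation stacks.
#' @param method correlation method, see [layer_correlations()].
#' @return list with `winner`, `loser` (data.frames: layer, mean, se, n) and
#'   `difference` (data.frame: layer, difference).
#' @export
winner_loser_profile <- function(trials, method = "per_channel") {
  if (length(trials) == 0L) stop_invalid("empty trial list")
  wc <- lapply(trials, function(tr) {
    layer_correlations(tr$mix, tr$winner, method)
  })
  lc <- lapply(trials, function(tr) {
    layer_correlations(tr$mix, tr$loser, method)
  })
  wp <- profile_from_cors(wc)
  lp <- profile_from_cors(lc)
  list(winner = wp, loser = lp,
       difference = data.frame(layer = wp$layer,
                               difference = wp$mean - lp$mean,
                               stringsAsFactors = FALSE))
}

#' Outcome-grouped layer-correlation profiles for phase/magnitude mixtures
#'
#' Groups trials by outcome (`phase_won`, `magnitude_won`, `neither`) and
#' reports, per group, the mean layer-correlation profile of the mixture's
#' stack against the phase source's stack and against the magnitude source's
#' stack, plus their per-layer difference. Empty groups are omitted with a
#' warning record.
#'
#' @param trials list of trials, each a list with `mix`, `phase`, `magnitude`
#'   activation stacks and `outcome` in
#'   `c("phase_won", "magnitude_won", "neither")`.
#' @param method correlation method.
#' @return list keyed by group, each with `vs_phase`, `vs_magnitude`
#'   profiles and `difference`; plus `warnings` (character vector naming
#'   empty groups).
#' @export
outcome_grouped_profile <- function(trials, method = "per_channel") {
  groups <- c("phase_won", "magnitude_won", "neither")
  outcomes <- vapply(trials, `[[`, "", "outcome")
  if (!all(outcomes %in% groups)) stop_invalid("unknown outcome label")
  out <- list(warnings = character())
  for (g in groups) {
    sub <- trials[outcomes == g]
    if (length(sub) == 0L) {
      out$warnings <- c(out$warnings, sprintf("group '%s' is empty", g))
      next
    }
    pc <- lapply(sub, function(tr) layer_correlations(tr$mix, tr$phase, method))
    mc <- lapply(sub, function(tr) {
      layer_correlations(tr$mix, tr$magnitude, method)
    })
    pp <- profile_from_cors(pc)
    mp <- profile_from_cors(mc)
    out[[g]] <- list(vs_phase = pp, vs_magnitude = mp,
                     difference = data.frame(layer = pp$layer,
                                             difference = pp$mean - mp$mean,
                                             stringsAsFactors = FALSE))
  }
  out
}
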