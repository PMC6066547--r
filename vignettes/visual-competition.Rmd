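---
title: "Methods: perceptual dominance in superimposed image mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perceptual dominance in superimposed image mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two images are superimposed and shown briefly, a perceiver — a human
observer or a feed-forward recognition network — usually reports seeing only
one of them. This package implements the full non-dynamic visual-competition
analysis around that phenomenon:

1. **Stimulus construction** (`mix_average()`, `mix_phase_magnitude()`,
   `build_mixture_set()`): 50/50 pixel averages and Fourier phase/magnitude
   hybrids of image pairs.
2. **Choice classification** (`classify_scenario()`, `noisy_softmax()`,
   `scenario_probabilities()`, `sigma_sweep()`): the top-N category-overlap
   rule turning classifier outputs into one of four trial outcomes, with
   optional Gaussian noise injected into the logits to emulate stochastic
   choice.
3. **Dominance modelling** (`fit_dominance_glm()`, `dominance_curve()`,
   `best_subsets()`, `clopper_pearson()`): which image parameters predict
   the winner.
4. **Localization** (`layer_correlations()`, `winner_loser_profile()`,
   `outcome_grouped_profile()`): where, along a layered perceiver's
   hierarchy, the competition is resolved.

Every stage is testable offline: a deterministic mock perceiver
(`build_mock_perceiver()`) and synthetic-data generators (`make_*()`) stand
in for pretrained networks and natural images.

## Stimuli

The 50/50 mixture averages the two sources' RGB values pixel-wise and
rounds half-up; it is exactly symmetric in its arguments, and a self-mix
reproduces the image bit-for-bit. The phase/magnitude hybrid combines, per
RGB channel, the 2-D DFT magnitude spectrum of one source with the phase
spectrum of the other and inverts the transform (unnormalized forward,
1/(HW) inverse). The real part can leave [0, 255]; we clamp rather than
rescale, because rescaling would change the stimulus' luminance and contrast
in a pair-dependent way. Magnitude-spectrum conservation therefore holds for
the *pre-clamp* result (`quantize = FALSE`), which the tests verify to
1e-9 relative error.

Channel handling for the hybrid is not dictated by the source material (the
published hybrids are color images with unstated channel treatment); we
operate on each RGB channel independently to treat both sources
symmetrically. Pairing conventions: unordered pairs for averages (the
operation is symmetric), ordered pairs for hybrids (phase-donor vs
magnitude-donor are distinct stimuli), and a seeded random perfect matching
("unique pairing") where repeated exposure to an image would be a confound.

Inputs of unequal size are center-cropped to the largest square and
resampled bicubically (Catmull–Rom kernel, centre-aligned, edge-clamped) —
a recorded package choice, not a claim about how the original stimuli were
prepared. The kernel interpolates exactly, so standardization is idempotent
at the target size.

## Image parameters

Six parameters are attached to every source image:

| parameter | definition |
|---|---|
| gradient | sum of squared forward differences of the luminance plane, both axes |
| low frequencies | sum of DFT magnitudes at radial frequency ≤ 0.25 × Nyquist (DC included) |
| luminance | mean of 0.299 R + 0.587 G + 0.114 B |
| global contrast | population SD of the same plane |
| colorfulness | pixel sum of √(I² + Q²) in YIQ |
| saturation | mean of 255 (max − min)/max over RGB, 0 at black pixels |

plus, in the extended set, per-channel means, local contrast (mean
within-block SD over non-overlapping 8-px tiles), the separate horizontal
and vertical gradient energies, and the high-frequency band (radius ≥ 0.75).
Choices the printed formulas leave open, fixed here once: all
intensity-domain features are computed on the luminance plane; the gradient
operator is first-order forward differences (closest to a bare ∇ symbol;
Sobel rejected); the one-dimensional band notation is read radially on the
2-D spectrum; saturation's 0/0 at black is defined as 0; colorfulness stays
a sum while luminance/saturation are means — for same-size images the
pair *ratios* the models consume are unaffected by the sum-vs-mean
convention. Features are computed on floating-point intensities, before any
quantization of derived images. `select_least_correlated()` reduces the
extended set by greedy forward selection on absolute Pearson correlation,
with lexicographic tie-breaking so the selection is reproducible; constant
columns are treated as correlated-with-everything and flagged.

The extended list has 13 entries, not 12: the enumeration it follows
(three channel means, colorfulness, luminance, saturation, two contrasts,
three gradients, two bands) counts 13 distinct quantities, and we implement
them all.

## Choice rule and noise model

A source is *chosen* if its top-N categories intersect the mixture's top-N;
the trial outcome is none / first / second / both. N defaults to 5 (the
standard metric for 1000-category classifiers, whose labels are
over-specific), with N = 2 exposed. Ties in the top-N ranking break by
ascending category index — real probability ties are measure-zero, but
synthetic fixtures hit them and the rule must be deterministic. Because
top-N sets are nested in N, outcomes can only move along
none → one → both as N grows; the tests assert this exhaustively.

Stochastic choice is modelled by adding i.i.d. Gaussian noise (SD σ) to the
logits before the softmax; σ = 0 recovers the deterministic classifier
exactly. In `sigma_sweep()` all three distributions (mixture and both
originals) are re-noised per trial per iteration, since the noise enters the
output layer itself; a mixture-only switch is exposed. The "best" σ
minimizes total-variation distance between the three-scenario proportions
and a reference (e.g. aggregated human reports); TV is our choice — the
source material says only "best resembled" — and ties break toward
smaller σ. Scenario probabilities are estimated by drawing 90 mixtures
without replacement per iteration and averaging proportions over 100
iterations (both config values).

## Dominance models

For trials with exactly one winner, the model is a zero-intercept logistic
on log parameter ratios:

P(pick I₁) = 1 / (1 + exp(−Σᵢ βᵢ log(fᵢ(I₁)/fᵢ(I₂))))

Two printed-formula corrections are deliberate. First, written without the
minus sign the formula would make a *larger* parameter value *reduce* the
probability of being picked, contradicting both the rising empirical curves
and the use of |β| as "predictability"; we implement the standard logistic,
so positive β means the image with the larger parameter tends to win.
Second, the printed "accuracy" formula is the mismatch fraction; we report
agreement = 1 − mismatch and call it that. The intercept is omitted because
the two classes are balanced by construction: relabelling a pair flips both
x and y, and the no-intercept likelihood is invariant to that relabelling
(a property the tests assert).

Fitting is Newton/IRLS on the objective −(1/n)·loglik + (λ/2)‖β‖², authored
in-package (this model *is* the analysis; `stats::glm` serves as an
independent cross-check at λ = 0 in the tests). Ridge rather than a
sparsity penalty, because subsets are enumerated explicitly anyway; λ is
chosen by k-fold cross-validated log-loss (k = 10 default) over a grid that
may include 0. Complete separation at λ = 0 is detected (non-convergence or
|β| > 25) and the fit falls back, flagged, to the smallest positive λ.
Standard errors come from the sandwich A⁻¹ I A⁻¹ with A the penalized and I
the unpenalized Fisher information; at λ = 0 this reduces to the usual
inverse information. Feature values are floored at 1e-8 before the log
ratio. Model choice thresholds fitted P at 0.5, with P = 0.5 resolved to
the first image (measure-zero in data, deterministic in tests).

Dominance curves bin the log ratio into 9 equal-width bins (the typical
resolution of the published curves; a config value) spanning the observed
range, with exact Clopper–Pearson 95% intervals per bin via the
beta-quantile characterization; empty bins are omitted. `best_subsets()`
enumerates all subsets up to a size cap, scores each by per-fold held-out
agreement at its CV-selected λ, and shares one fold assignment across
subsets so scores are comparable.

## Layer profiles

Activation stacks are named, ordered lists of per-layer arrays. For
convolutional-style layers (matrices, channels × units) the Pearson
correlation is computed per channel map and averaged over channels — the
default reading of "correlations between activity maps, averaged per
layer" — with whole-layer flattening implemented as an alternative and the
choice recorded in the output. Constant (zero-variance) maps contribute
correlation 0 and are *counted*, so layer averages remain comparable across
images. Winner and loser profiles are computed from identical trial sets,
and the per-layer difference localizes where the representation commits to
the winner. Correlations are invariant to per-layer affine rescaling, per
the Pearson definition.

## The synthetic world

- **Textures** (`make_texture_image()`): seeded 1/f^α Gaussian fields,
  affinely mapped to exact target luminance and contrast, colorized by a
  constant zero-luminance chroma offset in the YIQ plane at a requested hue,
  with the offset scale solved by `uniroot` so mean saturation hits its
  target. Unlike photographs, each parameter is independently steerable.
  The generator refuses specs that would clip more than 1% of channel
  values. `make_image_bank()` samples parameters log-uniformly (hue
  uniformly); because extreme corner draws (bright + high-contrast +
  saturated) are infeasible, the bank caps contrast at luminance-headroom
  / 3.5 and deterministically shrinks rejected draws (0.6× saturation,
  0.85× contrast) — the bank remains a pure function of ranges + seed.
- **Choice trials** (`make_choice_trials()`): the dominance logistic run
  generatively — Gaussian log ratios (zero mean, so curves are populated
  symmetrically around ratio 1), Bernoulli winners, features reconstructed
  as exp(±x/2). Round-trip recovery of β is the generator's defining test.
- **Activation fixtures** (`make_activation_fixture()`): mix =
  α·winner + √(1−α²)·noise per layer, so the expected mixture–winner
  correlation is exactly α.
- **Coded reports** (`make_report_table()`): multinomial scenario codes per
  participant per trial, aggregating back to the generating proportions
  within binomial error.
- **Mock perceiver**: dense seeded Gaussian layers with *thresholded*
  rectification (preactivations more than one SD below their mean are
  zeroed) and a cosine-template head over K = 1000 categories. The
  threshold matters: with plain ReLU on zero-centred inputs, every image's
  representation shares the input DC direction and mixtures trivially
  overlap both sources' top-5 sets; at one preactivation-SD the
  representations sparsify and all four scenarios are populated. K = 1000
  keeps chance top-5 overlap near 2.5%, as for the classifiers this mock
  stands in for.

What a green test does **not** establish: the mock perceiver is untrained,
so *which* parameters predict its choices (its β profile) carries no
information about trained networks or humans — only the machinery that
measures such profiles is validated. The textures lack the object structure,
spatial inhomogeneity, and cross-parameter correlations of natural images,
so headline proportions from the synthetic pipeline are not comparable to
published values.

## Numerical choices and limitations

- DFT convention: unnormalized forward, 1/(HW) inverse, everywhere.
- Rounding of derived images: round half-up; deviation from the exact mean
  is at most 0.5 level.
- Seeds: every stochastic stage has its own config seed; generators
  save and restore the caller's RNG state, and `run_pipeline()` refuses a
  config with a missing stage seed before any computation.
- Pretrained-network adapters (anything satisfying the `perceiver` contract:
  `K`, `layer_names`, `classify`, `activations`) plug in without code
  changes, but no adapter ships here — that keeps the test suite free of
  weight downloads, at the cost that claims about specific architectures are
  out of reach.
- Human free-text reports are ingested only in pre-coded form
  (`aggregate_report_table()`); the encoding step itself is out of scope.
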