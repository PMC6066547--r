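# rivalmix

Analysis pipeline for **non-dynamic visual competition**: when two images are
superimposed and presented briefly, a perceiver — a human observer or a
feed-forward recognition network — usually "sees" only one of them. This
package builds the competing stimuli, classifies which source image a
classifier chooses, models which image parameters predict that dominance,
and localizes where in a layered perceiver the competition is resolved. It
is aimed at vision scientists comparing biological and artificial perception
with identical stimuli.

## What it computes

**Stimuli.** Two mixture types of an image pair (I₁, I₂): the *50/50*
mixture (pixel-wise RGB average) and the *phase/magnitude hybrid* (2-D DFT
magnitude of one image combined with the phase of the other, inverse
transformed, per channel). Pair sets are all-pairwise or a seeded unique
matching.

**Choice rule.** A source is *chosen* when its top-N output categories
intersect the mixture's top-N (N = 5 default), giving four trial scenarios:
none / first / second / both. Stochastic choice is emulated by logit noise:

    P(class_i) = exp(x_i + ε_i) / Σ_j exp(x_j + ε_j),   ε ~ N(0, σ²)

and a σ sweep finds the noise level whose scenario proportions best match a
reference (total-variation distance).

**Dominance model.** For single-winner trials, a zero-intercept logistic on
log parameter ratios,

    P(pick I₁ | I₁, I₂) = 1 / (1 + exp(−Σ_i β_i log(f_i(I₁)/f_i(I₂))))

where the f_i are six image parameters (gradient energy, low-frequency
spectral energy, luminance, global contrast, YIQ colorfulness, saturation);
|β_i| measures predictability. Ridge-regularized fits with CV-selected λ,
exhaustive best-subset search scored by cross-validated agreement, binned
dominance curves with exact Clopper–Pearson 95% intervals.

**Layer localization.** Pearson correlations between the mixture's
activation maps and each source's, per channel, averaged per layer; winner
vs loser profiles and outcome-grouped phase/magnitude profiles.

Everything runs offline: a deterministic mock perceiver and synthetic-data
generators (1/f^α textures with steerable parameters, model-generated choice
trials, analytic activation fixtures, coded report tables) stand in for
pretrained weights, natural images, and human subjects. See
`vignettes/visual-competition.Rmd` for the methods account.

## Worked example

```r
library(rivalmix)

# a synthetic bank, all pairwise 50/50 mixtures, a mock perceiver
bank  <- make_image_bank(30, side = 64, seed = 5)
mixes <- build_mixture_set(bank, "average_5050", "all_pairwise")
net   <- build_mock_perceiver(seed = 3, K = 1000)
trials <- run_competition(net, mixes, bank, n = 5)
table(trials$scenario)
#>   both  first   none second
#>    104     66    163    102

# which parameter predicts the winner?
fit <- fit_dominance_glm(trials, "low_frequencies", lambda_grid = 0)
fit
#> Zero-intercept logistic dominance fit (n = 168, lambda = 0)
#>      low_frequencies
#> beta          0.7455
#> se            0.4837
predict_and_score(fit, trials)$agreement
#> [1] 0.5892857
```

Here 168 of 435 mixtures were resolved to a single winner; the positive β
(0.75 ± 0.48) leans toward the image with more low-frequency energy winning
for this perceiver (a small bank — the `analysis/` scripts run the same fit
on ~750 trials, where the effect is clear), and the fitted model agrees with
the observed winner in 59% of single-winner trials.

The full workflow is scripted as thin drivers over the package:

```sh
Rscript analysis/01_simulate.R     # synthetic bank + coded human reports
Rscript analysis/02_competition.R  # mixtures, scenarios, noise sweep
Rscript analysis/03_dominance.R    # beta table, curves, best subsets
Rscript analysis/04_layers.R       # layer-correlation profiles
```

each writing its tables under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch — synthetic bank →
mixture set → mock-perceiver competition → scenario probabilities →
dominance fits → layer profiles — against the installed package, writes the
run's tables next to the output path, and emits the acceptance JSON.
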