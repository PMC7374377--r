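---
title: "Noise-robust feature-saliency fuzzy clustering segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-robust feature-saliency fuzzy clustering segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saliseg)
```

## The problem

Unsupervised segmentation of a greyscale image assigns each pixel to one of
`C` classes using only the pixel values.  Plain clustering (k-means, fuzzy
C-means) treats pixels independently, so impulse noise (salt-and-pepper) and
strong additive noise shatter the segmentation: each corrupted pixel is
classified by its own corrupted value.  `saliseg` implements a clustering
model that pulls every pixel's class posterior towards the evidence of its
spatial neighbourhood, which lets the segmentation survive noise levels at
which pixelwise methods fail.

## The model

Pixel `i` carries a feature vector `x_i` of dimension `D` (by default `D = 1`,
the raw grey level).  Each class `j` models feature `l` with a Gaussian
`N(mu_jl, sigma_jl^2)`; a single *background* Gaussian `N(eps_l, nu_l^2)`
shared by all classes models the non-informative part of each feature.  A
feature-saliency prior `rho_l` gives the probability that feature `l` is
informative for class structure at all, and the per-pixel, per-class
posterior of that event is the saliency membership `s_ijl`.

The solver minimises

```
J = sum_ij z_ij d_ij
  + lambda * sum_ij ( z_ij log(z_ij / pi_ij) + G_ij log(G_ij / pi_ij) )
  + gamma  * sum_ij z_ij KL(s_ij. || rho)
```

where

* `z_ij` are fuzzy class memberships (rows sum to 1),
* `d_ij = sum_l [ -s_ijl log Phi(x_il | mu_jl, sigma_jl^2)
  - (1 - s_ijl) log Phi(x_il | eps_l, nu_l^2) ]` is the saliency-weighted
  negative log likelihood,
* `pi_ij` is a spatial prior (below), and the `lambda` term is the KL
  divergence tying memberships to that prior — the fuzziness mechanism,
  replacing the classical fuzzifier exponent,
* the `gamma` term is the Bernoulli KL divergence of the saliency
  memberships from their prior `rho_l`.

### Spatial machinery

Three windowed fields over a `w x w` sliding window (replicate padding, the
centre pixel included, `n_i = w^2`):

1. **Neighbourhood likelihood weights**
   `h_ijl = ( sum_{t in N_i} Phi(x_tl | mu_jl, sigma_jl^2) )^alpha`:
   the windowed sum of class likelihoods, sharpened by the exponent `alpha`.
2. **Markov prior** `pi_ij = sum_l h_ijl / sum_k sum_l h_ikl`, the
   class-normalised form of `h`, expressing the assumption that neighbouring
   pixels follow the same distribution as the centre pixel.
3. **Noise smoothing factor**
   `G_ij = exp( beta/(2 n_i) * sum_{t in N_i} (z_tj + h_tj) )`, with `h` the
   class-normalised weight from step 2.  `G` grows with the local vote
   (memberships plus likelihood weights) for class `j` and is bounded in
   `[1, exp(beta)]`.

The prior used by the membership update is the *combined* prior
`pi_ij = (z_ij + G_ij) / sum_k (z_ik + G_ik)`: the pixel's own membership
inflated by the neighbourhood vote.  An isolated noise pixel has a small
`z` for the locally dominant class but a large `G`, so the prior — and with
it the posterior — is pulled to the class of its surroundings.

### Block-coordinate updates

All updates are exact minimisers of `J` in their own block (the package's
tests verify each one against grid-search or brute-force oracles):

* `s_ijl = rho_l Phi_jl^(1/gamma) / (rho_l Phi_jl^(1/gamma) +
  (1 - rho_l) Phi_l^(1/gamma))` — both densities tempered symmetrically by
  `1/gamma`,
* `z_ij ∝ pi_ij exp(-(d_ij + gamma K_ij)/lambda)`, normalised per pixel via
  a log-sum-exp shift (`G` is frozen during this update, an ICM-style
  treatment; letting the `G log G/pi` term back-propagate into `z` through
  the neighbours would destroy the closed form for no observed benefit),
* class and background parameters are the corresponding weighted moments
  with weights `z_ij s_ijl` and `z_ij (1 - s_ijl)`,
* `rho_l = (1/N) sum_ij z_ij s_ijl`.

Each outer sweep refreshes `h`, `G` and `pi`, then `s`, `z` and the
parameters, and records `J`.  Iteration stops when `|J(t+1) - J(t)| <
delta` (absolute difference, default `1e-4`) or after `t_max = 400`
sweeps.  With `pi` and `G` frozen a sweep never increases `J`; the prior
refresh itself is a fixed-point step, so the trace may move non-monotonically
early on but settles in practice.

## Parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `C` | — | 2–4 typical | number of classes; chosen by the user |
| `window` | 5 | pixels | neighbourhood side; 3 for low noise, 5 for heavy noise |
| `lam` | 150 | — | weight of the KL membership regulariser |
| `gamma` | 15 | — | saliency tempering; larger = flatter saliency evidence |
| `beta` | 12 | — | smoothing-factor weight; bounds `G` in `[1, e^beta]` |
| `alpha` | 2 | — | exponent sharpening the windowed likelihood sum |
| `delta` | 1e-4 | objective units | absolute convergence threshold |
| `t_max` | 400 | sweeps | iteration cap |
| `variance_floor` | 1e-4 | grey-level² | lower bound for all fitted variances |
| `rho_floor` | 1e-3 | — | clipping bound for saliency priors |

### Why `beta = 12`

`beta` is the one genuinely consequential open choice.  With `lambda = 150`
and `d` on the negative-log-likelihood scale, the likelihood factor
`exp(-d/lambda)` in the membership update is weak (typical likelihood
ratios contribute factors below 2), so the memberships are driven almost
entirely by the combined prior.  If `beta` is small (say `1/2`), `G` is
confined to `[1, 1.65]`, the combined prior can never become sharp, and the
membership fixed point is soft: we measured both class means of a two-region
phantom (true levels 60/180, noise std 10) collapsing to ~83 because every
class mean then averages over all pixels.  With `beta = 12` the smoothing
factor spans `[1, e^12]` and the prior concentrates exponentially on the
locally dominant class; memberships sharpen, the class means are recovered
to within about one grey level, and the noise robustness the model is built
for actually materialises.  The exponent never exceeds `beta`, so there is
no overflow risk.  `beta` remains a configuration knob for users who want
weaker smoothing (at the cost of soft parameter estimates).

### `alpha`

`alpha` sharpens the neighbourhood likelihood vote before normalisation.
The default is the square (`alpha = 2`).  Values much larger mainly saturate
`h_norm` towards one-hot, which `beta` already accomplishes through `G`;
we keep the smallest exponent that worked and expose the knob.

## Numerical choices

* **Log-space densities.**  Every Gaussian density is computed as a log
  density; linear-scale values appear only inside the windowed likelihood
  sums, floored at `1e-300`.
* **Log-sum-exp shift** in the membership update: the largest exponent per
  pixel is shifted to 0, so a pixel whose every class weight underflows
  still gets a valid membership row — never a zeroed one.
* **Floors and clips.**  Variances are floored at `1e-4` (squared grey
  levels — a noise-free region otherwise collapses to a zero-variance
  Gaussian and infinite log densities); saliency memberships are clipped to
  `[1e-10, 1 - 1e-10]`; saliency priors to `[1e-3, 1 - 1e-3]`;
  `0 log 0 = 0` in the objective, log arguments clipped at `1e-300`.
* **Borders** use replicate padding, so every pixel has a full `w x w`
  window and results are bit-reproducible.
* **Ties** in the final argmax labelling go to the lowest class index.
* **Randomness.**  A single integer seed drives the fuzzy C-means centre
  initialisation and the noise simulators; no other stochastic step exists,
  so identical seeds give byte-identical outputs end to end.
* **Degenerate inputs.**  A constant image (or any constant feature) is
  rejected by the initialiser with an error naming the feature; asking for
  more clusters than distinct grey levels is an error; an emptied cluster
  or background keeps its previous parameters with a warning rather than
  producing NaNs.

## The synthetic test material

The generators emulate the study conditions the method is meant for:
piecewise-constant phantoms of 2–4 regions (`two_region` disk,
`four_region` quadrants with inset rectangles, `stripes`) corrupted by

* additive Gaussian noise (std on the 0–255 scale; up to ~140),
* salt-and-pepper noise (a seeded fraction of pixels forced to 0 or 255,
  up to 45%),
* multiplicative (speckle) noise `I + I·n`, `n ~ N(0, (std/255)^2)` —
  quoted levels are stds on the 0–255 scale mapped onto the conventional
  unit-scale multiplicative model,
* Gaussian followed by salt-and-pepper ("mixed").

What the phantoms deliberately lack: texture, smooth shading, blur and
partial-volume boundaries, spatially correlated noise.  Passing the test
suite therefore demonstrates noise robustness on piecewise-constant scenes,
not performance on natural images; on textured scenes the piecewise-constant
assumption behind the spatial prior is itself violated.

## Problem sizes used by the tests

The suite checks the block updates against brute-force and grid-search
oracles on instances of up to 20 pixels, the windowed operators against
nested loops on images up to 16×16, parameter recovery on a 96×96 two-region
phantom (Gaussian noise std 10, five seeds — class means within ±5 grey
levels, misclassification below 2%), and the headline robustness ordering on
a 128×128 four-region phantom (Gaussian std 58 and 35% salt-and-pepper,
five seeds — the spatial model must beat plain fuzzy C-means on both MCR
and PSNR on every seed).  These sizes keep a full run of the default suite
in the tens of minutes on one core while still exercising the
400-iteration regime of the solver.

## Evaluation conventions

* **MCR** (misclassification rate): cluster labels are arbitrary, so the
  predicted labels are first aligned to the ground truth by the
  permutation maximising the confusion-matrix trace (exhaustive over `C!`,
  `C <= 6`); the rate is the percentage of pixels left unmatched.
* **PSNR** is computed between class-mean reconstructions: each pixel
  replaced by its class's fitted mean intensity, compared against the
  ideal reconstruction (true labels at the true levels).  This makes PSNR
  well defined on label maps; `mse = 0` is reported as infinite PSNR.

## Known limitations

* Greyscale only; colour images are out of scope.
* `C` must be supplied; there is no automatic model-order selection.
* `lambda`, `gamma` and `beta` interact: `lambda` large enough to smooth
  implies the data term is weak, so the burden of sharpness falls on
  `beta` (see above).  Tuning for other imaging domains may be needed.
* The neighbourhood vote smooths boundaries as well as noise: with a 5×5
  window, sharp convex corners can lose a few pixels to the surrounding
  class even on noise-free input (use the 3×3 window when noise is low).
* The objective is non-convex; the fuzzy C-means initialisation is what
  makes runs reproducible, and a bad draw of initial centres can still
  yield a poor local optimum on hard images (mitigate by trying seeds).
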