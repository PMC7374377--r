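# saliseg

Noise-robust unsupervised segmentation of 8-bit greyscale images by
feature-saliency fuzzy Gaussian-mixture clustering with embedded
neighbourhood information constraints.

## Who this is for

Anyone who needs to partition a noisy greyscale image — phantoms,
micrographs, CT/MR slices, remote-sensing scenes — into `C` intensity
classes when impulse (salt-and-pepper), Gaussian, speckle or mixed noise
makes pixelwise clustering useless.  The package also ships the synthetic
machinery (phantom generators, noise simulators, PSNR/MCR metrics) to
benchmark the method end to end without any external data.

## The model

Each class `j` models feature `l` of pixel `i` with a Gaussian
`Φ(x_il | μ_jl, σ_jl²)`; a shared background Gaussian `Φ(x_il | ε_l, ν_l²)`
absorbs non-informative features, with saliency memberships `s_ijl` and
priors `ρ_l` arbitrating between the two.  Fuzzy class memberships `z_ij`
minimise

    J = Σ_ij z_ij d_ij
      + λ Σ_ij ( z_ij log(z_ij/π_ij) + G_ij log(G_ij/π_ij) )
      + γ Σ_ij z_ij KL(s_ij· ‖ ρ)

where `d_ij` is the saliency-weighted negative log likelihood, `π_ij` the
combined spatial prior `(z_ij + G_ij)/Σ_k (z_ik + G_ik)`, and
`G_ij = exp(β/(2Nᵢ) Σ_{t∈Nᵢ} [z_tj + h_tj])` a noise smoothing factor built
from the window's memberships and its class-normalised likelihood weights
`h_ijl = (Σ_{t∈Nᵢ} Φ(x_tl|μ_jl,σ_jl²))^α`.  Block-coordinate updates
(all closed forms) alternate with a fuzzy C-means initialisation; see the
methods vignette (`vignettes/noise-robust-segmentation.Rmd`) for the full
derivation-level account and the reasoning behind every default.

## Worked example

```r
library(saliseg)

ph  <- make_phantom("four_region", 128, 128, levels = c(30, 100, 170, 240))
img <- corrupt(ph$clean, noise_spec("salt_pepper", sp_fraction = 0.35, seed = 1))

res <- run_segmentation(img, seg_config(C = 4, seed = 1))
res
#> saliseg segmentation: 128 x 128 image, C = 4, 400 iteration(s), stopped at t_max
#> class means (feature 1): 240.37, 30.74, 100.59, 170.26

fcm <- fcm_segment(img, C = 4, seed = 1)
ref <- reconstruct(ph$truth, ph$levels)

mcr(res$labels, ph$truth)$mcr_percent   # 4.03  — spatial model
mcr(fcm$labels, ph$truth)$mcr_percent   # 26.50 — plain FCM baseline
psnr(reconstruct(res), ref)$psnr_db                            # 17.77 dB
psnr(reconstruct(fcm$labels, fcm$centers[, 1]), ref)$psnr_db   #  9.63 dB
```

With 35% of pixels destroyed, the neighbourhood-constrained model recovers
the four class means to within a grey level and misclassifies ~4% of pixels
(mostly at region boundaries), while plain FCM — which sees each pixel in
isolation — misclassifies ~27% and its reconstruction PSNR drops by 8 dB.

## Command line

```sh
Rscript inst/cli/saliseg simulate --kind four_region --levels 30,100,170,240 \
    --noise salt_pepper --sp-fraction 0.35 --seed 1 --out runs/sim
Rscript inst/cli/saliseg segment --image runs/sim/noisy.png --clusters 4 \
    --seed 1 --out runs/seg
Rscript inst/cli/saliseg evaluate --pred runs/seg/labels.png \
    --truth runs/sim/truth.png --out runs/report.json
```

`segment` accepts every model knob as a flag (`--window`, `--lam`,
`--gamma`, `--beta`, `--alpha`, `--delta`, `--max-iter`) or a YAML file via
`--config`; flags override the file.  Identical invocations with identical
seeds are byte-identical.

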