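# spdecon

Sparse-deconvolution decoding for combinatorial FISH image stacks.

Multiplexed in situ hybridization experiments read out hundreds of genes by
imaging rolling-circle-amplified spots (rolonies) over `n` rounds of
3-channel hybridization. Each gene carries a *compact barcode* — an
`n`-digit string over `{0,1,2,3}` that names the fluorescent channel of each
of its `k` "on" rounds (`0` = off), e.g. `132000` for `n = 6, k = 3`. At
20x magnification several rolonies can overlap a single ~0.3 μm pixel, so
per-pixel nearest-barcode matching breaks down as gene panels and detection
efficiency grow. This package decodes such stacks at the pixel level by
sparse deconvolution, and is aimed at people building or evaluating decoding
pipelines for barcoded FISH data.

## The model

Flattening rounds and channels (plane `3*(round-1) + channel`), the codebook
is a binary matrix `X` (`3n x N`, column sums `k`) and every pixel a vector
`y` in `[0,1]^{3n}`, modeled as a non-negative mixture with per-plane gains
`c`:

    y = c ⊙ X w,   w ≥ 0  (sparse)

Foreground pixels (`||y/c||₂ > 0.25`) are decoded by a non-negative elastic
net,

    ŵ = argmin_{w≥0} 1/(2·3n) ||y/c − Xw||² + α ||w||₁ + (α′/2) ||w||₂²,
    α′ = α/100,

followed by an elbow filter (keep the top weight if the second is < 50% of
it, else the top two if the third is < 30%) and an OLS refit of the
surviving support. Under this scaling a pure-barcode pixel is undetectable
exactly below `w_max = (3n/k)·α` — for `n=6, k=3, α=0.05`, `w_max = 0.3` —
which anchors the choice of `α`. The penalty adapts to pixel brightness
through a norm-indexed lookup table, and `c` is estimated from the data by
alternating decoding with per-plane scalar least squares.

Around the decoder the package provides: combinatorial codebook design
(randomized maximal-independent-set search over the Hamming-distance-1
conflict graph), a rolony-image simulator with known ground truth, spot
calling by marker-seeded watershed on the weight maps, empty-barcode
false-positive filtering with a random forest, spot-to-cell assignment
against a segmentation mask, and benchmarking (sensitivity / specificity /
empty rate) including a naive nearest-barcode baseline. A thin CLI
(`exec/dartfish`) wraps the same functions.

## Worked example

Design a brain-scale codebook (121 genes + 10 empty controls), simulate one
field of view, decode it, and score against the simulator's truth:

```r
library(spdecon)

cb <- design_codebook(6, 3, sprintf("gene%03d", 1:121), n_empty = 10,
                      n_runs = 20000, rng_seed = 0)
cb
#> codebook: 131 barcodes (121 genes + 10 empty), n = 6 rounds, k = 3 on

sim <- simulate_fov(cb, n_spots = 2000, shape = c(512, 512), rng_seed = 1)
cfg <- spd_config(rng_seed = 1)
cf  <- estimate_channel_coefficients(sim$stack, cb, cfg)
median(abs(cf - sim$coefficients) / sim$coefficients)
#> 0.0173   # per-plane gains recovered to ~2%

lk    <- build_alpha_lookup(sim$stack, cb, cf, cfg)
maps  <- decode_fov(sim$stack, cb, cf, lk, cfg)
spots <- call_spots(maps)
m     <- match_spots(sim$truth, spots)
compute_metrics(sim$truth, spots, m, cb)
#>   n_truth n_decoded n_matched sensitivity specificity empty_rate
#> 1    2000      2019      1979      0.9895   0.9801882          0
```

98.9% of the 2000 simulated rolonies are recovered with an identical
barcode within 6 px (sensitivity), 98.0% of decoded spots correspond to a
true rolony (specificity), and none of the decoded spots carry an empty
barcode — the empty rate is the observable error proxy available on real
tissue, where specificity cannot be measured.

`train_empty_classifier()` / `filter_spots()` then remove spots that look
like empty-barcode hits (small, dim) at an emptiness-probability threshold
of 0.325, and `assign_spots_to_cells()` attaches the survivors to a
segmentation mask with per-gene distance rules.

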