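---
title: "Sparse-deconvolution decoding of combinatorial FISH: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-deconvolution decoding of combinatorial FISH: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdecon)
```

## The decoding problem

Combinatorial FISH experiments encode each gene as a *compact barcode*: an
`n`-digit string over `{0,1,2,3}` whose digit for round `r` names the
fluorescent channel (1–3) in which the gene's rolonies light up in that
round, with `0` marking an off round. Every barcode is on in exactly `k`
rounds, so `choose(n,k) * 3^k` barcodes exist; restricting to *multicolor*
barcodes (on-rounds not all in one channel, `choose(n,k) * (3^k - 3)`)
avoids codes that are indistinguishable from single-channel artifacts.

Concatenating rounds and channels, a barcode becomes a one-hot vector of
length `3n` (plane index `3*(round-1) + channel`), the codebook a binary
matrix `X` of shape `3n x N`, and each pixel of the registered image stack a
vector `y` in `[0,1]^{3n}`. Rolonies are sub-resolution, so a pixel can
receive light from a small number of overlapping rolonies; its intensity is
modeled as a non-negative mixture

    y = c * X w,    w >= 0,

where `c` is a per-plane gain vector (some round/channel combinations are
systematically brighter) and `w` holds per-barcode contributions, almost all
zero. The decoder solves, for every foreground pixel,

    min_{w >= 0}  1/(2*3n) ||y/c - X w||^2 + alpha ||w||_1 + (alpha2/2) ||w||_2^2

with `alpha2 = alpha/100` a small ridge term for numerical stability. The
`1/(2*3n)` least-squares scaling is pinned by a useful identity: at
`alpha2 = 0` a pixel made purely of one barcode with weight `w` yields an
all-zero solution exactly when `w < (3n/k) * alpha`
(`max_undetected_weight()`), which the suite verifies empirically. With
`n = 6, k = 3, alpha = 0.05` the detection threshold is 0.3.

Solutions are post-processed per pixel by an *elbow filter* — keep the top
weight if the runner-up is below half of it, else the top two if the third
is below 30% of the top, else reject — and the surviving one or two weights
are re-estimated by ordinary least squares to undo shrinkage. Negative OLS
refits are physically meaningless; the support is reduced instead (a choice
the upstream description leaves open).

## Codebook design

Conflicting barcodes at Hamming distance 1 (same on-rounds, one channel
changed) must not share a codebook. `design_codebook()` follows a
three-stage search: a greedy-with-restarts *seed set* of barcodes at
pairwise distance > 2; a randomized maximal-independent-set (MIS) search on
the distance-1 conflict graph, 20,000 seeded runs; then random assignment of
genes and empty controls.

One structural fact does real work here: distance-1 edges require identical
on-round supports, so the conflict graph is a disjoint union of one
subgraph per support. Runs therefore decompose over components, and
`select_mis()` unions, per component, the best sub-set seen in *any* of the
20,000 runs. The result is still a maximal independent set containing the
seed (verified by property tests) and dominates keeping the single best
whole run — in our measurements the brain-scale (6,3) search returns
165–168 barcodes where whole-run selection plateaus at 156–158. Ties and
randomization are driven entirely by the user seed; identical seeds replay
identically.

`find_seed_set()` keeps 200 random greedy orders by default; experiments
with more restarts produced marginally larger seed sets that did not improve
(and sometimes hurt) the downstream MIS, so the default stays modest.

## Channel gains and adaptive regularization

`estimate_channel_coefficients()` alternates decoding and gain estimation
for 2 iterations on one fixed random sample of up to 50,000 foreground
pixels (`||y||_2 > 0.25`): pixels are normalized by the current `c`,
decoded, reduced to those with a single dominant unsaturated OLS weight in
`[0.1, 0.5]`, and each plane's gain is re-fit by scalar least squares of
observed on model intensities. Planes never touched by a qualifying pixel
keep their previous value, with a warning.

A single `alpha` cannot serve both dim rolonies (which need a small penalty
to be detected at all) and bright crowded pixels (which need a large one to
stay sparse). `build_alpha_lookup()` therefore tabulates, on a grid of 50
pixel norms spanning 0–2.8, the `alpha` from `{0.01, 0.015, ..., 0.1}` that
maximizes a Gaussian-weighted (bandwidth 0.1, about two norm-grid steps —
the upstream description does not state this bandwidth) sum of the
elbow-filtered OLS L1 norms over a training sample, ties resolved toward the
larger (sparser) `alpha`; per-alpha solutions reuse the full elbow + refit
path. Decoding then looks each pixel's `alpha` up by nearest norm, clamped
at the grid ends. Foreground is judged on gain-normalized norms so that a
decode is exactly invariant to jointly rescaling the stack and its
coefficient vector.

The per-pixel solver (compiled) is a hybrid: coordinate descent with a
non-negativity-aware screening rule identifies the support, and an
active-set finisher — exact minimization over the working set via an
incrementally extended Cholesky factor, dropping negatives and admitting
dual violators — lands on the exact KKT point, which property tests verify
against independent FISTA and glmnet solvers. Crowded pixels whose
ridge-degenerate remainder stalls the objective (a sweep improving it by
less than `1e-8` of the first sweep's decrease, on supports past 48
barcodes) are accepted as converged, since that remainder redistributes
weight among a crowd the elbow filter rejects either way; truly
non-convergent pixels (2,000-sweep cap) are counted, reported, and decoded
as zero. Two further exact reductions keep crowded fields tractable:
byte-identical (pixel, alpha) problems — ubiquitous once clipping saturates
a neighborhood — are solved once and fanned back out, and training samples
exclude pixels more than five kernel bandwidths above the top of the norm
grid, which carry negligible kernel weight at every grid norm (and can
never be single unsaturated rolonies for gain estimation).

## From weight maps to spots

Per barcode, the OLS weight map is Gaussian-smoothed (`sigma = 1` px),
local maxima at least 2 px apart become markers, and marker-seeded
propagation partitions the positive region (both parameters are unstated
upstream and exposed). Each region yields a spot with its area,
weight-weighted centroid (0-based, pixel-centered), and max/mean weight.
Smoothing runs on the padded bounding box of each barcode's support, with
values below `1e-6` floored to keep FFT ripple from minting spurious
markers.

Empty barcodes — codebook entries with no probes — can only be hit by
decoding errors, so spots decoded to them are labeled false positives.
`train_empty_classifier()` fits a seeded 100-tree random forest on (area,
max weight, mean weight); `filter_spots()` drops spots with emptiness
probability at or above 0.325, the midpoint of the 0.3–0.35 working range,
and reports the *empty rate* (fraction of kept spots still carrying empty
barcodes) both before and after filtering, since either convention is
defensible.

Spot-to-cell assignment uses the segmentation mask's 8-connectivity
boundaries: interior spots take their cell at distance 0; exterior spots
take the nearest boundary pixel's cell if the Euclidean distance (in μm,
via the pixel size) is within the global radius, with per-gene overrides
winning — this expresses rules like a 0 μm radius for myelin transcripts
that legitimately live outside somata. Equidistant ties go to the smaller
label.

## The simulator and what it does (not) show

`simulate_fov()` reproduces the benchmarking conditions used to compare
decoders: spots uniform in space, genes uniform over non-empty barcodes,
isotropic Gaussian rolonies with peak intensity in `[0.25, 0.7]` and sigma
in `[2, 2.5]` px, per-plane gains drawn from `U(0.75, 1.25)`, intensities
clipped at 1. Gaussians are peak-parameterized and truncated at 4 sigma
without renormalization. Background is zero by default with an optional
additive-noise flag, since the upstream description states none; rendering
is 2D only, matching decoding of maximum-projected images.

Passing benchmarks on these simulations demonstrates the decoder's
arithmetic and its crowding behavior, not robustness to what the simulator
omits: autofluorescence and structured background, registration error,
optical aberrations, empty-barcode hits caused by real chemistry rather
than decoding, and non-uniform gene abundance.

## Benchmarking

`match_spots()` pairs truth and decoded spots greedily nearest-first,
one-to-one, same barcode, strictly within 6 px. Sensitivity is matched
truth over all truth; specificity is matched decoded over all decoded;
empty rate is the empty fraction of decoded spots, the observable proxy for
specificity. Zero denominators report NA rather than 0. Optimal
(assignment-problem) matching is not provided: at a 6 px radius on these
densities greedy and optimal matchings differ negligibly, and no
linear-assignment backend is a package dependency. The naive baseline
(`naive_decode()`) labels each foreground pixel with its nearest
unit-normalized barcode within Euclidean distance 0.7 and groups labeled
pixels into 8-connected components; its spot aggregation is our choice, as
the baseline's original description leaves it open.

## Problem sizes used by the checks

The test suite and acceptance script run entirely on synthetic data built
at run time: codebook capacities by exhaustive enumeration; design searches
at full scale (480- and 840-node graphs, 20,000 runs); solver equivalence
on 1,000 random pixels against a block FISTA oracle; channel-gain recovery
on twenty 1024x1024 simulations of 10^4 spots; and an end-to-end density
sweep at 512x512 over 5x10^3 to 2x10^5 spots — chosen as the package's
standard desk-scale reference conditions, with densities spanning the same
per-area range as the published sweep. Larger FOVs change runtimes, not
conclusions.

## Known limitations

- Pixels are decoded independently; no information is shared between
  neighbors, which is the main avenue for improving crowded decodes.
- The elbow filter caps recoverable mixtures at two barcodes per pixel.
- The empty-spot classifier needs at least one decoded empty spot; very
  clean decodes fall back to an unfiltered pass-through.
- Channel-gain estimation assumes enough isolated, unsaturated rolonies per
  plane; planes without them keep unit gain.
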