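---
title: "Methods: areal boundary mapping on flat maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: areal boundary mapping on flat maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealmap)
```

## The model

Cortical areas participate in distinct large-scale resting-state networks,
so the low-frequency BOLD time course of a pixel reflects the network
membership of the area it belongs to. Within an area, pixel time courses
share a common latent component; across an areal border, that component
changes abruptly. Boundary mapping turns this into an image-processing
problem: build, for every seed pixel, a map of how similar each location's
connectivity is to the seed's, and detect where that similarity changes
fastest.

`arealmap` operates on a `ts_grid`: an H × W flat-map grid with one time
series per masked pixel, a TR in seconds, and a pixel pitch in mm. The
default pitch of 2 mm reflects a 50 mm × 50 mm flat map sampled at 2 mm.

Two similarity front ends share one edge-detection back end.

**Local method.** Each masked pixel in turn is the seed; its series is
correlated with every other masked pixel's series and Fisher
z-transformed. Self- and duplicate correlations are capped at
`|r| = 0.999` before `atanh` (z ≈ 3.80), keeping maps finite without
excluding the seed pixel. The map is symmetric in seed and target, and
only data inside the region of interest are used.

**Standard method.** Each seed is correlated with an external target set —
whole-brain voxels, cortical gray matter, or the contralateral homologue
of the ROI. On a flat map the contralateral "sphere" of the volumetric
formulation becomes an in-plane disc (boundary included, distance ≤
radius, default 2 mm) around the left–right mirrored seed, unioned over
seeds and deduplicated. Seed profiles are compared between pixels with

$$\eta^2 = 1 - \frac{\sum_i (a_i - m_i)^2 + (b_i - m_i)^2}
                    {\sum_i (a_i - M)^2 + (b_i - M)^2},
\qquad m_i = \tfrac{a_i + b_i}{2},$$

with $M$ the grand mean of both profiles; $\eta^2 \in [0,1]$ always, since
the per-position mean minimizes the within-pair sum of squares. Two
constant, equal profiles make the denominator zero; that degenerate case
is defined as 1 with a warning.

**Back end.** Each seed's similarity map passes through the Canny chain:

1. Gaussian smoothing at FWHM 6 mm (σ = FWHM/(2√(2 ln 2))/pixel ≈ 1.27 px
   at 2 mm pixels), *mask-renormalized*: kernel weight falling off-mask is
   redistributed so constants are preserved up to the mask border.
2. Spatial gradient by central differences, one-sided at mask borders.
3. Non-maximum suppression with the gradient direction quantized to four
   sectors.
4. Hysteresis: pixels at or above the 0.9 quantile of the nonzero gradient
   magnitudes seed edges; pixels at or above the 0.5 quantile extend them
   through 8-connected chains. Quantile (rather than absolute) thresholds
   make the same settings work on Fisher-z and η² maps, which live on
   different scales.

Averaging the resulting binary edge maps over all seeds gives the
probabilistic boundary map (PBM): the per-pixel fraction of seeds that saw
an edge there.

## Evaluation

**Boundary/Background classification.** For each pixel, a direction is
chosen among horizontal, vertical and the two diagonals by the greatest
3-pixel linear sum (the pixel plus its two neighbors along the
direction); ties resolve by the fixed precedence horizontal > vertical >
diagonal-down > diagonal-up. A pixel is a ridge candidate when its value
is *strictly* greater than both neighbors orthogonal to its direction —
strictness prevents flat plateaus from being classified wholesale, and the
comparison requires the full orthogonal triple on the mask, since a
one-sided comparison would let every mask-border pixel win by default.
Candidates forming 8-connected runs of three or more are Boundary pixels;
pixels with no Boundary pixel among their eight neighbors are Background;
everything else (and isolated pixels) is Neither. The boundary SNR is the
mean PBM value over Boundary pixels divided by the mean over Background
pixels — scale-invariant by construction.

**Map similarity.** Two PBMs are compared by Pearson correlation over the
shared mask. Smoothed maps carry far fewer independent samples than
pixels, so the test uses effective degrees of freedom $n/\mathrm{BCF} - 2$
with the isotropic lag-product correction
$\mathrm{BCF} = 1 + 2\sum_k \rho_a(k)\,\rho_b(k)$, where $\rho(k)$ is a
map's spatial autocorrelation at integer pixel lag $k$ (value pairs pooled
over row and column offsets), accumulated from lag 1 while either
autocorrelation is ≥ 0.1. The exact correction formula is an
implementation choice isolated in one function; BCF is clamped at ≥ 1 so
the effective dof never exceed the classical $n-2$, and forcing
`force_bcf = 1` recovers the classical test exactly. Monte-Carlo
calibration on white-noise map pairs (500 replicates in the test suite)
keeps the type-I error at the nominal 5% level.

**Cross-boundary profiles.** For a line of ≥ 8 pixels crossing a putative
border, each line pixel's correlation profile against the whole line peaks
at itself; on a genuine boundary the profiles split into two groups,
similar within each area and dissimilar across.

## The synthetic-data generator

`simulate_flatmap()` is the package's test bed. It plants a parcellation
(vertical split at column ⌊width/2⌋ with the border column in the second
area, an L-shaped variant, or seeded Voronoi cells), draws K mutually
orthogonal, unit-variance latent network signals — white Gaussian noise
band-limited to 0.009–0.08 Hz by an ideal FFT mask, then
QR-orthogonalized and standardized — and builds each pixel as
$\sqrt{w}\,\mathrm{net}(\mathrm{label}) + \sqrt{1-w}\,\varepsilon$ with
independent band-limited pixel noise, standardized. The expected
within-area correlation is then exactly $w$ and the between-area
correlation 0. Noise is band-limited like the signal so that boundaries
arise from network membership, not spectral artifacts.

Reference study conditions, used throughout the tests and the acceptance
script: 25 × 25 grid, 2-mm pixels, TR 3 s, T = 512 frames, vertical
two-area split, w = 0.5. Target sets for the standard method contain 16
series per network, built exactly like pixels at the same mixing weight —
a stand-in for the many remote nodes of each network that a whole-brain
target set would contain; 16 per network keeps the η² profiles
realistically noisy while averaging over targets, which is the standard
method's actual advantage. The optional contralateral grid mirrors the
labels, shares the networks and draws fresh noise, modeling the premise
that a region's strongest remote connectivity is with its contralateral
homologue. Everything is deterministic given the master seed (sub-seeds
are derived by fixed offsets), and generation does not disturb the
caller's RNG stream.

What the generator does *not* emulate: hemodynamic response shapes, head
motion and scanner drift, spatially correlated noise within areas, pixels
mixing several networks, or irregular ROI masks. Passing tests on these
grids therefore demonstrate the pipeline's correctness and its behavior
under idealized network structure, not performance on real fMRI data.

## Preprocessing

Band-pass filtering (default 0.009–0.08 Hz) is zero-phase: a 4th-order
Butterworth run forward and backward by default (no phase lag to distort
correlations), with an ideal FFT-mask filter as an option. Each series is
demeaned first, and the small DC residue that forward–backward filtering
leaves at the edges is removed exactly afterwards, so output series are
mean-zero. Nuisance regression residualizes every pixel against an
intercept plus user-supplied regressor columns (motion parameters and
mean whole-brain/ventricle/white-matter signals in the usual workflow;
this package has no volumetric atlas to derive them, so they arrive as a
matrix) and errors informatively on collinear designs. Regressors are
used as given by default, with a flag to band-pass them identically;
since filtering and projection are both linear, the two orders agree
whenever the regressors are band-limited, which the test suite checks
with the FFT filter where the identity is exact.

## Numerical choices

- Gaussian kernels are truncated at 5σ, keeping the semigroup property
  (two passes at σ match one pass at σ√2) to ~1e-7 on interior pixels.
- A flat map's numerical gradient residue (~1e-16 of the value scale)
  must not seed edges: gradient magnitudes below 1e-10 of the smoothed
  value scale mean "no edges".
- Non-maximum suppression keeps a pixel iff its magnitude is ≥ the
  neighbor at the negative offset along the quantized gradient direction
  and strictly > the neighbor at the positive offset, with comparisons at
  a relative tolerance of 1e-9 so that exact ties resolve identically in
  every row. An ideal step between two pixel columns produces *equal*
  gradients on both; the asymmetric rule thins that to a single line (the
  higher-index column) instead of a double line, and plateau ridges
  survive as their last pixel. The cost is that mirror equivariance of
  the pipeline is exact only on tie-free maps — on a perfectly symmetric
  step, the mirrored edge sits on the other member of the tied pair.
- Direction ties in the ridge classifier use a fixed precedence
  (horizontal first) for reproducibility.
- Effective dof in the similarity test are clamped to ≥ 1.

## Known limitations

The Boundary/Background rules contain no magnitude threshold: any strict
local ridge of the PBM, however faint, is a Boundary candidate. On
synthetic grids the local method's PBM has a flat but nonzero background
(~0.01) generated by each seed's own capped correlation spike — after
smoothing, the spike's gradient is comparable to the border's, so each
seed's edge map carries a few near-seed pixels besides the border line.
Count-level ripple in that background (±1–2 seeds out of 625) forms
strict local maxima that the classifier labels Boundary far from the
planted border; the border itself is still recovered as the dominant
ridge (probabilities 0.2–0.8 against the 0.01 background), and the
boundary SNR remains well-defined and high. The standard method on the
same grids yields an exactly zero background — every edge map is just the
border line — so its SNR degenerates to a ratio with a zero denominator;
`snr()` reports this as an error rather than inventing a value, and the
comparison of the two methods is then made on the boundary and background
means directly. Both behaviors are properties of the idealized synthetic
background, not of the classifier: real resting-state maps have
structured, nonzero background everywhere, which is also why published
boundary-SNR values for such pipelines are small single-digit numbers
rather than the large ratios seen on clean simulations.

The package consumes already-flattened grids; surface reconstruction,
inflation and flattening cuts, volumetric (3D) boundary mapping, and
parcellation *from* the boundary map (watershed, graph cuts) are out of
scope.
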