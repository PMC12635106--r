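---
title: "Dry-mass quantification from quantitative phase images: models and methods"
author: "holomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dry-mass quantification from quantitative phase images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holomass)
```

## The measurement model

A transparent cell of height $h$ delays transmitted light by a phase
$\varphi(x,y) = \frac{2\pi}{\lambda}\int_0^h (n_c(z) - n_m)\,dz$, which we
express as a length, the optical path difference
$\mathrm{OPD}(x,y) = \frac{\lambda}{2\pi}\varphi(x,y)$. The refractive
index excess of cytoplasm is proportional to the local concentration of
non-aqueous material with a remarkably universal proportionality constant
— the refractive index increment $\alpha \approx 1.9\times10^{-4}$
m$^3$/kg — so the OPD field is a dry-mass surface density map and the mass
of cell $i$ is

$$M_i = \frac{1}{\alpha}\iint_{S_i} \mathrm{OPD}\,dx\,dy
      = \frac{S_i}{\alpha}\,\overline{\mathrm{OPD}_i}.$$

Internally all OPD values are nanometers and $\alpha$ is carried as
$1.9\times10^{-4}\ \mu m^3/\mathrm{fg}$ (numerically identical to the SI
value), so `mass(fg) = integrated OPD(um*um^2) / alpha` with no unit
juggling. Images are row-major matrices with the origin at the top-left;
physical coordinates appear only in feature tables.

## Background leveling

Reconstructed phase images carry smooth aberrations (tilt, curvature,
uneven illumination). `levelBackground()` fits a bivariate polynomial of
total degree $N$ (default 16) to the *whole* image by least squares and
subtracts it; cells are not excluded because they cover of order 1% of the
field of view.

Rather than raw monomials — whose normal equations are numerically
hopeless beyond degree $\sim$15 — the fit uses 1-D polynomial bases
orthonormalized on the actual pixel grid (QR of the Vandermonde in a
coordinate scaled to $[-1,1]$). On a tensor grid the least-squares
solution is then an exact orthogonal projection: coefficients are inner
products, any order up to the grid size is numerically stable, the bases
are nested (so the residual standard deviation is monotone in $N$,
cf. `stdReductionCurve()`), and an input surface of total degree
$\le N$ is recovered to machine precision.

One consequence the user should understand: a genuine degree-$N$
projection has an effective resolution kernel of width $\sim \pi L/N$
pixels (narrower near the image border). At $N = 16$ on a 802-px frame
that kernel is two orders of magnitude wider than a coccus and the fit
absorbs only a few percent of a cell's OPD; at $N = 64$–$128$ the kernel
width approaches the (smoothed) cell size and the fit eats most of the
cell signal. Frozen-mask sweeps over leveling orders 2–128
(`frozenMaskSweep()`) therefore show large discrepancies at the extreme
orders on synthetic scenes — a property of honest high-order least
squares itself, not of the implementation; commercial black-box routines
that fit raw monomials in double precision are effectively
rank-truncated near degree 20 and cannot exhibit it. Within orders 8–32
the default pipeline's reference values are stable at the few-percent
level.

## Gaussian filtering

`gaussianSmooth()` convolves with a separable normalized Gaussian with
$\sigma$ = `radius` (default 4 px), truncated at $3\sigma$, with
reflective boundaries. Each output pixel's weights sum to 1, so constants
pass unchanged and the integrated OPD of interior structure is preserved
to well under 1%. The default follows the spatial-frequency trade-off:
radius 2 leaves visible high-frequency noise, radius 6 distorts cell
shapes; `spectrumDb()` (max-normalized 2-D DFT magnitude in dB, axes in
$\mu m^{-1}$ from the pixel size) is provided to reproduce that analysis.
Note that smoothing spreads a small fraction of a cell's OPD beyond the
segmentation mask; on synthetic scenes this contributes a systematic
$\sim$10% mass deficit, comfortably inside the propagated uncertainty but
visible in recovery studies.

## Adaptive masking and features

`adaptiveMask()` marks pixels exceeding a Gaussian-weighted local mean
(window `blockSize` = 127 px, $\sigma = (\mathrm{blockSize}-1)/6$ so the
window carries essentially all kernel mass) plus
`offsetMultiplier` $\times$ the image's global standard deviation. The
local mean absorbs residual gradients; the global-std offset sets the
detection level. The mask is invariant to positive rescaling of the
image. The default multiplier 2 is the midpoint of the 1–3 range swept in
robustness studies (`runSweeps()`, which also sweeps morphological radii
1–3 px and block sizes 33/65/127 px — the odd sizes nearest 32/64/128).

`refineAndLabel()` applies a disk opening (radius 2), labels
8-connected components, drops components below 0.2 $\mu m^2$ (a quarter
of a single coccus), and dilates each label by a disk (radius 2);
contested pixels join the nearest label (Voronoi propagation), ties
resolved deterministically, so labeling is reproducible bit-for-bit.
Border-touching regions are flagged and excluded from population
statistics by default.

On a *pure-noise* image this thresholding does produce spurious
detections: smoothed noise is spatially correlated, and 2$\sigma$
excursion blobs survive a radius-2 opening. Every such region fails the
low-confidence floor $M < 3\,\delta_{\mathrm{OPD}} S/\alpha$ and is
flagged in the mass table; filtering on `low_confidence` is the
recommended rejection rule. In images that contain cells the global
standard deviation is dominated by the cells and the effect disappears.

`extractFeatures()` reports area, perimeter, circularity
$C = 4\pi A/P^2$, eccentricity $\varepsilon = \sqrt{1-(b/a)^2}$ from the
second-moment ellipse, axis lengths, centroid, and mean/integrated OPD.
The perimeter uses a 4-direction Crofton (line-intercept) estimator,
$P = \frac{\pi}{8}(n_h + n_v + (n_{d1}+n_{d2})/\sqrt2)$ in pixels:
unbiased for isotropic shapes, it keeps $C$ of digitized disks within a
few percent of 1 (border-pixel counting would bias $C$ by tens of
percent). $C$ is deliberately not clamped at 1 — digitized values
fluctuate slightly above it.

## Mass uncertainty

`massUncertainty()` propagates three independent error sources per cell:

$$\delta M_i = \sqrt{\Big(\tfrac{S_i\,\delta_{\mathrm{OPD}}}{\alpha}\Big)^2
 + \Big(\tfrac{\overline{\mathrm{OPD}_i}\,S_i\,\delta_\alpha}{\alpha^2}\Big)^2
 + \Big(\tfrac{\overline{\mathrm{OPD}_i}}{\alpha}\,\delta_{S_i}\Big)^2}$$

with $\delta_{\mathrm{OPD}}$ the per-image standard deviation of the
cell-free background (`backgroundNoise()` over the complement of the
guard-dilated labels), $\delta_\alpha = 0.03\times10^{-4}\ \mu m^3$/fg
from the literature spread of the refractive increment, and
$\delta_{S_i} \approx P_i\,p$ the one-pixel boundary band of the mask.
The area term dominates for bacteria-sized objects, giving relative
errors of a few tens of percent — the known resolution limit of the
technique at the single-cell level. Population summaries report the mean
relative error with a Student-t 95% interval.

## Morphological classification

Cocci arrive on the substrate singly or in small clusters; clusters
depress circularity. `fitMixture()` is a 1-D EM implementation
(k-means++-style seeding, 10 restarts, tolerance $10^{-6}$ on the
log-likelihood, 500 iterations max) with AIC/BIC using $3K-1$ free
parameters; `selectComponents()` scans $K = 1..5$ and takes the BIC
minimum, which lands on $K = 2$ for circularity data. Components are
ordered by descending mean so component 1 is always the high-circularity
"singles" mode — identification by mean, not weight, because singles are
defined by shape, not abundance. `ambiguousFraction()` reports the share
of observations whose maximum posterior membership falls below a
confidence threshold (0.70 and 0.90 conventionally); it evaluates the
fitted model on the supplied data, so with a large model-generated sample
it estimates the model's intrinsic overlap, while on an observed dataset
it reproduces the empirical ambiguous fraction. `singleFilter()` keeps
regions with $C \in [\mu_1 - 2\sigma_1,\ \mu_1 + 2\sigma_1]$.
`fitLengthMass()` is ordinary least squares of bacillus length on mass
with standard errors, $r$, $R^2$ and RSS.

## The Koch–Schaechter population model

For an asynchronously growing, binary-dividing population in steady
state, the probability of observing a cell at mass $m$ is proportional to
$m^{-2} P(\text{division mass} \in (m, 2m))$. With a normal division-mass
density $g$ this has the erf closed form used by `ksPdf()`. The
normalization $A$ is computed by adaptive quadrature on the log-mass
scale over $(\sim 10^{-9}\mu_{div},\ \mu_{div}+6\sigma_{div}]$: the erf
form retains a small $1/m$ tail toward zero mass (a normal $g$ assigns
residual probability to near-zero division masses), so the integrand is
only log-integrable and the quadrature variable matters. In the
deterministic limit $\sigma_{div}\to 0$ the closed forms
$A \to \mu_{div}$ and $\langle m\rangle \to \mu_{div}\ln 2$ hold to
$10^{-3}$ and are tested.

`ksSample()` inverts the trapezoidal CDF on a dense grid, log-spaced
below $\mu_{div}/4$ for the same reason. `fitKS()` estimates
$(\mu_{div}, \sigma_{div})$ by maximum likelihood (Nelder–Mead on log
parameters with per-iterate renormalization) rather than by fitting a
binned histogram, avoiding bin-choice sensitivity; a histogram $R^2$
against Freedman–Diaconis bins is reported purely as a diagnostic. The
sampler's sub-resolution tail is physically meaningless for scene
generation, so `samplePopulation()` rejects cocci below 0.25 $\mu m$
radius — half the instrument's 0.53 $\mu m$ lateral resolution.

`emd()` computes the 1-D Earth Mover's Distance as the integral of the
absolute empirical-CDF difference (equal to the optimal-transport cost,
verified against brute-force assignment in the tests), and
`bootstrapEmd()` summarizes $B$ paired redraws with a mean and central
95% interval; bootstrap sample sizes default to the original $n$ of each
input.

## Synthetic scenes and what they do (not) show

`makeScene()` renders cells with analytic volumes — spheres
($V = \tfrac43\pi R^3$), spherocylinders ($V = \pi R^2 l + \tfrac43\pi
R^3$) and clusters of 2–4 touching spheres — as projected-thickness OPD
patches with $4\times$ sub-pixel antialiasing, so the grid-summed OPD
matches $\Delta n\,V$ within 1%. Truth masks use pixel-center
rasterization. Defaults emulate the instrument: 802$\times$764 px frames
at 90.6 nm/px, a random smooth polynomial background (total degree 6,
coefficients decaying geometrically with degree, $\sim$30 nm
peak-to-valley) and 2.0 nm Gaussian noise (the stated vertical
resolution). Populations draw masses from Koch–Schaechter models
(defaults $\mu_{div}$ = 272 fg/$\sigma_{div}$ = 77 fg for cocci, 751/213
fg for bacilli), cocci with refractive contrast $\Delta n \sim
U(0.03, 0.08)$ (the paper-scale protoplasm contrast; never directly
published, chosen once), bacilli with fixed 1.19 $\mu m$ width, total
length $1.193 + 0.006\,M$ and $\Delta n$ solved from mass and volume,
and a 0.49 cluster fraction among cocci.

The generator reproduces the geometry, backgrounds and noise floor of the
instrument but not coherent-imaging physics (speckle, diffraction halos,
PSF sidelobes) or intracellular refractive-index structure; recovery
results on synthetic scenes therefore validate the *pipeline algebra*
(segmentation, integration, uncertainty coverage), not the optics.
End-to-end, $\ge 95\%$ of cells on default 20-cell scenes are recovered
within $2\,\delta M$ of their true mass; the residual systematic deficit
($\sim$10–15%, from filter spread beyond the mask and polynomial
absorption of cell signal) is well inside the propagated uncertainty.

## Problem sizes and numerical choices

Tests and the acceptance script run at: $10^5$ Monte-Carlo draws for
posterior-ambiguity estimates; 50 replicates of $n = 179$ for BIC model
selection; $10^4$ samples for division-model recovery (2%/5% parameter
tolerance); three full-size 20-cell scenes for end-to-end coverage;
full-size single scenes for the frozen-mask order sweep. Quadrature
tolerances are $10^{-8}$ (normalization) and $10^{-9}$ (test oracles); EM
and the KS optimizer stop at $10^{-6}$ and $10^{-10}$ relative
improvement. Ties in BIC go to the smaller $K$; EM component order is
descending mean; label numbering is raster order of first pixel.

## Known limitations

* Touching cells are deliberately *not* watershed-split; clusters are
  separated statistically via circularity, mirroring the intended
  workflow.
* The frozen-mask robustness bound (mass stable to 5% across leveling
  orders 2–128) is *not* met by a genuine total-degree least-squares fit
  at orders $\ge 64$ on bacteria-scale objects (see "Background
  leveling"); the package reports the sweep honestly instead of
  emulating a rank-deficient fit.
* TIFF output stores samples in $[0,1]$ with a `<path>.range` sidecar
  recording the affine value range; third-party raw-float TIFFs are read
  directly as nm.
* No validation against manually annotated real images is possible from
  generated data alone; acceptance rests on analytic ground truth.
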