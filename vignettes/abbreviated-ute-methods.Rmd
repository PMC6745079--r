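---
title: "Methods: abbreviated bicomponent T2* estimation and its bias correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abbreviated bicomponent T2* estimation and its bias correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uteq)
```

## The signal model and its assumptions

Magnitude UTE signal from collagenous tissue is modeled as a two-pool
bi-exponential decay,

$$S(TE) = S_0\left[f_{bw}\,e^{-TE/T_{2s}^*} + (1-f_{bw})\,e^{-TE/T_{2l}^*}\right],$$

with a fast pool (collagen-bound water, $T_{2s}^*$ of roughly 0.5–2 ms
in graft tissue) and a slow pool (free water, $T_{2l}^*$ of tens of
ms). The model deliberately ignores T1 saturation, flip-angle and
excitation-profile effects, fat chemical shift and field inhomogeneity:
it describes the ROI-averaged magnitude decay only, which is the
quantity the estimators consume. All times are in milliseconds; signals
are in arbitrary units with phantom $S_0$ defaulting to 1.

The abbreviated estimator exploits the time-scale separation between
the pools. Over the sub-millisecond TE1 echoes (0.1, 0.27, 0.5 ms) the
slow pool decays by only $1-e^{-0.5/20}\approx 2.5\%$, so its
contribution is approximated as a constant *baseline*, measured as the
mean signal at the TE2 echoes (4, 5, 6 ms) where the fast pool has
essentially vanished. The TE1 decay is then fit with

$$S(TE) = \frac{b}{1-f_{bw,app}}\,e^{-TE/T_{2s,app}^*} + b,$$

where $b$ is the fixed baseline. Two conventions are possible for
mapping the fitted amplitude $A$ to an apparent fraction: $f = A/(A+b)$
(fraction of the extrapolated TE=0 signal) or $A = b/(1-f)$,
equivalently $f = 1 - b/A$. The package adopts the second. The choice
is consequential because the measured baseline is *not* the slow pool's
TE=0 signal: it is attenuated by slow-pool decay out to 4–6 ms and
inflated by residual fast-pool signal when $T_{2s}^*$ is long. Under
the adopted convention these contaminations produce the characteristic
bias structure that the calibrated correction then removes — in
particular the pronounced *under*-estimation of $f_{bw,app}$ at long
$T_{2s}^*$, which the $A/(A+b)$ convention largely hides and which
simulation shows to be a real feature of the abbreviated protocol.

## Estimators and numerical choices

All fits are bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), deterministic by construction: fixed
multi-start lattices, no randomness.

* **`fit_abbreviated`** — baseline fixed first (mean TE2 signal; this
  keeps the TE1 fit two-parameter and matches the acquisition logic),
  then $(f_{bw,app}, T_{2s,app}^*)$ fit on the TE1 echoes. Starts: a
  data-driven point (two-point log-slope of the baseline-subtracted
  first/last TE1 signals, clamped to [0.1, 5] ms) plus a 3×3 lattice
  over $f \in \{0.1, 0.5, 0.9\}$, $T_{2s}^* \in \{0.3, 1, 3\}$ ms.
  Bounds: $f \in [10^{-4}, 0.999]$, $T_{2s}^* \in [0.05, 10]$ ms.
  Baseline-subtracted signals may be negative under noise and are used
  as-is (clipping would bias low-SNR fits). A solution pinned at a
  bound is returned *flagged*, never silently dropped.
* **`fit_biexp`** — four free parameters with bounds
  $T_{2s}^* \in [0.05, 5]$, $T_{2l}^* \in [5, 100]$ ms,
  $f_{bw} \in [0,1]$, $S_0 \in (0, 10\max S]$; 12 starts
  ($\{0.3,1,3\} \times \{10,30\} \times \{0.3,0.8\}$) because the
  objective is multi-modal; lowest RSS wins. All ten echoes of the full
  schedule are used by default; `drop_longest_te` discards the 20 ms
  echo for SNR-starved in vivo data.
* **`fit_t2l_monoexp`** — mono-exponential fit for variable-TE ladders,
  excluding TEs < 3 ms by default so that a fast pool with
  $T_{2s}^* \le 2$ ms has decayed by ≥ 88% before the first included
  echo.

## Bias simulation and polynomial correction

`simulate_bias_grid` evaluates the abbreviated estimator on noiseless
bi-exponential curves over a ground-truth grid. The default density,
61 × 41 nodes over $T_{2s}^* \in [0.5, 2]$ ms and the chosen $f_{bw}$
range, makes the grid-average bias summaries insensitive to further
refinement at the < 0.1 percentage-point level. Two $f_{bw}$ presets
matter: the *clinical* range 0.75–0.95 typical of ACL grafts, where the
estimator is well behaved (mean absolute relative biases of a few
percent), and the *low* range 0.25–0.75, where the fast-pool amplitude
falls below the baseline and the apparent fraction collapses against
its lower bound. Headline "±X%" summaries are means of **absolute**
relative biases; signed means are reported alongside. Bound-pinned fits
are flagged but *included* in summaries — they are what the estimator
actually returns — while outright optimizer failures (which do not
occur on the default grids) would be excluded with a warning.

`fit_correction` fits two full bivariate polynomials of total degree 4
(15 monomials) in the *apparent* coordinates — the only quantities
available at inference time — predicting the error
$(\text{true} - \text{apparent})$ of each parameter by ordinary least
squares on the unpinned grid nodes; pinned nodes carry no invertible
information and would corrupt the surfaces. `apply_correction` adds the
predicted error and clamps corrected $f_{bw}$ to $(0, 1]$ with a
warning; use outside the calibration rectangle triggers an
extrapolation warning. A lookup-table inversion mode (nearest
calibration node in normalized coordinates) is available for users who
want near-exact correction on-grid at the price of a staircase
response off-grid.

The correction is calibrated at a fixed assumed $T_{2l}^*$ (20 ms
default). `t2l_mismatch_study` quantifies the residual error when the
truth deviates (15 or 25 ms): on the clinical $f_{bw}$ range the
corrected estimates degrade gracefully (on the order of 1–2% mean
absolute relative error, as computed in the acceptance tests), whereas
on the low range the mismatch is substantial — a separate gradient-echo
measurement of $T_{2l}^*$ is then warranted.

## Monte-Carlo SNR study

`run_snr_study` compares the corrected abbreviated estimator against
full bi-exponential fitting under additive zero-mean Gaussian noise of
standard deviation $S_0/\mathrm{SNR}$ per echo, applied to the
ROI-averaged curve (a per-voxel Rician option exists behind the
`noise = "rician"` flag; at the studied SNR ≥ 200 after averaging
thousands of ROI voxels the Gaussian approximation is appropriate).
Defaults: a 7 × 6 node grid over $T_{2s}^* \in [0.5, 2]$ ms,
$f_{bw} \in [0.70, 0.95]$, 500 replicates per node, SNR levels 1000 to
200. The error metric is the mean over nodes and replicates of
$|\hat\theta - \theta|/\theta \times 100$, with its standard deviation
over the same population; divergent or bound-pinned fits are counted
and excluded. Every run is reproducible from its integer seed. These
problem sizes were chosen so the default study completes in a few
minutes on a single core while leaving Monte-Carlo error well inside
the tolerances asserted by the tests.

## Synthetic phantom

`build_phantom`/`render_echoes` generate piecewise-constant 3D
parameter maps on a 1 mm isotropic grid and render noisy multi-echo
magnitude volumes from them. The default object mimics an ACL
reconstruction: three cylindrical graft segments at ≈ 47°, 32° and 25°
to B0 with $T_{2s}^*$ 1.4–1.8 ms, $f_{bw}$ 0.82–0.90, $T_{2l}^*$
20 ms. Design choices worth noting:

* Cylinders are cut by planes perpendicular to **B0**, not to their own
  axis. With axis-perpendicular caps the partial end-slices drag
  per-slice centroids inward and `angle_to_b0` underestimates the
  nominal orientation by several degrees; B0-perpendicular caps make
  every slice a full cross-section, so the measured angle matches the
  specification to well under the 3° voxelization contract.
* Noise is added per voxel with $\sigma = S_0(\text{voxel})/\mathrm{SNR}$,
  so empty background stays noise-free and segment SNR is interpretable
  per segment.
* The phantom emulates geometry, piecewise-constant parameters and
  additive noise. It does **not** emulate partial-volume mixing at
  boundaries, B0/B1 inhomogeneity, susceptibility effects, the
  orientation dependence of $T_{2s}^*$ itself (magic-angle effect), or
  k-space acquisition artifacts. Passing phantom tests therefore
  demonstrates the correctness of the estimation and geometry code, not
  the clinical accuracy of the protocol on real tissue.

## ROI geometry

ROI analysis follows the conventions of graft assessment: signals are
averaged over the ROI before fitting (voxel-wise mapping is not a
supported product); the graft/bone interface is a Euclidean-ball
dilation of the intra-bone ROI by 2 mm (2 voxels at 1 mm isotropic)
minus the ROI itself, 3D by default with an in-plane option;
orientation to B0 is the angle between the total-least-squares line
through per-slice centroids and the B0 direction, folded into [0°, 90°].
The B0 axis is explicit metadata — it is never inferred from image
headers, because reconstruction orientation does not pin the field
direction. Intra-rater reliability uses the Dice coefficient
$2|A\cap B|/(|A|+|B|)$ and a *symmetric* relative error
$|x_1-x_2|/\bar{x} \times 100$; the symmetric denominator avoids
privileging either rating session.

## Known limitations

* The abbreviated estimator is unreliable for $f_{bw} < 0.5$ (fast-pool
  amplitude below baseline); its bias summaries there are dominated by
  the optimizer's boundary behavior, and the polynomial correction is
  not calibrated for that regime. The package reports these values
  honestly rather than masking them.
* The correction assumes a single fixed $T_{2l}^*$; no joint
  three-parameter correction is attempted.
* No Rician-bias correction of magnitudes, no registration between
  timepoints, no automated segmentation: masks are inputs and are
  assumed co-registered.
* Group statistics (normality tests, paired comparisons) are out of
  scope; standard R functions apply directly to the per-ROI outputs.
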