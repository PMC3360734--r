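---
title: "Quantifying ensemble angiogenic sprouting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ensemble angiogenic sprouting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioquant)
```

# The assay and the problem

Microfluidic gel-cage devices grow dozens of independent 3D angiogenesis
instances under one set of extracellular conditions: a collagen strip
(1.3 mm across in the reference device) is caged between two rows of
trapezoidal PDMS posts, an endothelial monolayer forms along one
gel-channel interface, and sprouts invade the gel toward a chemoattractant
gradient imposed by the two flanking media channels. Each device holds 37
growth regions (post spacing 100 µm, post base angle 60°, supplementary
to the ~120° contact angle of liquid collagen on treated PDMS so the gel
interface pins flush with the posts). Four confocal channels are acquired
per region and timepoint: a cytosolic stain, a nuclear stain, reflected
light (gel/PDMS contrast) and transmitted light.

`angioquant` implements the full quantification chain — image
standardization, gel-boundary detection, monolayer fitting, invasion
metrics, device transport simulation and ensemble statistics — and a
synthetic phantom generator with analytic ground truth that stands in for
raw image data (none are publicly deposited), so every stage is testable
against exact expected values.

# Phantom model

A phantom region is rendered on the package's voxel grid (arrays indexed
(y, x, z); pixel centers at $(i-\tfrac12)\,\Delta$; all lengths in µm):

* **Reflectance**: gel 0.2, PDMS posts 0.8, medium-filled channel 0.7
  (normalized units). A pure two-level gel/PDMS rendering would make the
  posts invisible, so the channel level is kept distinct; the histogram
  remains strongly bimodal (gel mode vs bright non-gel modes).
* **Cytosolic channel**: a monolayer band of intensity 1.0 and total
  width 12 µm centered on the monolayer spline, plus sprouts rendered as
  capped cylinders (uniform intensity, default 0.8) anchored on the
  monolayer, tilted by a chosen angle from the local normal.
* **Nuclear channel**: spheres spaced evenly along each sprout axis.
* **Transmitted channel**: an attenuation image (posts and cells dark).

Cylinders and spheres are rasterized with 3×3×3 per-voxel supersampling so
partial volumes are captured, then blurred per z-slice with a
volume-normalized Gaussian (default σ = 1 pixel, no axial blur: the axial
point-spread is already far coarser than the 4–9 µm section spacing, and
per-slice blur keeps plateau intensities at their nominal values so
grayscale normalization is near-identity on phantoms). Background is a
seeded Gaussian field composited as `max(structure, background)`: the
background pedestal does not add to structure amplitudes, which keeps the
analytic ground truth valid under the thresholding convention below. The
same seed always reproduces the same stack.

Ground-truth metrics are computed from the continuous geometry,
independent of rasterization. For a cylinder of radius $\rho$, length
$L$, intensity $s$ at angle $\theta$ from the normal of a straight
monolayer, with integration offset $d$:

$$M = s\,\pi\rho^2\,(L - d/\cos\theta), \qquad
  J = s\,\pi\rho^2\,\cos\theta\,\tfrac{1}{2}\!\left(L^2 - (d/\cos\theta)^2\right),$$

reducing to $s\pi\rho^2(L-d)$ and $s\pi\rho^2(L^2-d^2)/2$ for
perpendicular sprouts. Nuclei cut by the offset plane contribute exact
spherical-cap volumes and moments. Aspect ratios are evaluated by
deterministic quadrature over the same continuous geometry. M and J are
exactly additive over sprouts.

A degenerate case worth knowing: a *constant* nonzero background
(`background_sd = 0`, `background_mean > 0`) makes the background
indistinguishable from a pedestal, and min–max normalization then shifts
all structure amplitudes. "Noiseless" phantom checks therefore use a zero
background mean.

# Image standardization

Each stack is standardized by (1) a per-slice 2D median filter (default
3 px window), (2) per-channel min–max normalization to [0, 1] (channels
have unrelated dynamic ranges, so joint normalization would be
meaningless), and (3) Gaussian background elimination on the fluorescence
channels: a robust fit (median/MAD, then mean/SD of the ±4σ core) of the
dominant low-intensity histogram mode gives (µ, σ), and voxels at or
below µ + kσ (default k = 3, i.e. 99.87% one-sided suppression) are set
to zero while voxels above it are kept unchanged — elimination rather
than subtraction, which makes the operation idempotent and leaves
structure amplitudes unbiased under the max-composited phantom model.
Normalization precedes elimination (declared order).

# Gel-boundary detection and registration

The reflectance stack is mean-projected over z (posts span the full
depth). The two gel/PDMS boundary lines are found by maximizing the
histogram-separation score — the absolute difference between mean
reflectance on the two sides of a candidate line — with multi-start
Nelder–Mead over (intercept, angle) per line, initialized from an
Otsu-classified row profile. Two numerical details matter:

* the optimizer scores a *soft* partition (pixels the line crosses are
  weighted fractionally), because the hard-partition score is piecewise
  constant in the line parameters and stalls a derivative-free search at
  pixel resolution;
* the scoring window is frozen at the initialization rather than moving
  with the candidate, so the optimizer cannot trade window content
  against partition means.

The two lines are optimized independently, each against its own windowed
band (whether the original analysis optimized them jointly is unstated;
independent optimization is simpler and performed identically well on
phantoms). Ties are broken toward the smaller |angle|.

Post polygons are then placed by locating the opening between the two
flanking posts: the intensity-weighted centroid of the reflectance dip
sampled in a band just outside each boundary, which is interior to the
field of view and therefore an unbiased sub-pixel estimator (template
cross-correlation was evaluated and rejected: view-edge truncation biases
the peak toward zero shift). Sampled rows are kept clear of the blurred
boundary ramp and dip weights are capped at the post/gap contrast so
stray dark pixels cannot dominate.

Timepoints are registered by a least-squares rigid (Kabsch) fit mapping
the 48-hr gap-center anchors (one per boundary line) onto the 0-hr ones.
The anchors' sub-pixel x positions carry the rotation signal across the
full gel-width baseline; the boundary-line angles themselves have a small
systematic bias on phantoms (~0.2–0.4°, from the inhomogeneous PDMS-side
content of the separation objective) and are deliberately not used for
rotation. A fitted rotation is kept only when the displacement it implies
at the anchors exceeds the anchor localization uncertainty (default
1.5 µm); smaller rotations are indistinguishable from noise and collapse
to pure translation. On the reference device the 1.3 mm baseline makes
this threshold ≈ 0.13°.

# Monolayer fitting

The monolayer is modeled as a natural cubic spline through 4 control
points at fixed, evenly spaced positions along the region, moving only in
the normal direction — the curve is single-valued (fold-free) by
construction, and the search space is 4 scalars. The objective is the
mean of the combined signal over the band of pixels within a half-width
of the candidate curve, restricted to the gel strip (bright out-of-gel
structure such as post attenuation must not attract the curve), maximized
by multi-start Nelder–Mead. The combined signal is a weighted sum
(defaults 0.7/0.3) of the cytosolic projection and *inverted* transmitted
light: cells attenuate transmitted light, so the literal sum would
penalize the band objective; inversion makes both components peak on the
monolayer.

The band half-width default is 6 µm, matching the monolayer
half-thickness: a band wider than the monolayer makes the objective flat
over a several-µm plateau and the fitted curve position correspondingly
arbitrary, while a matched band peaks sharply at the true center. The
normalization of the integral by band area removes any long-curve bias.
Band distances use the first-order slope correction
$|y - f(x)|\cos\alpha$, exact for straight curves and accurate for the
gentle curvature the fold-free parameterization allows; the exact
nearest-point distance (dense 0.25 µm spline sampling) is used for the
metric distance fields, where accuracy matters over the whole region.

# Invasion metrics

The integration region V is the gel strip between the detected
boundaries, bounded laterally by the flanking post faces, excluding
everything within 10 µm of the monolayer on the gel side (the offset
avoids bias from the bright cellular aggregation around the monolayer
itself). For each channel signal $s(\mathbf{x})$:

* $M = \sum_V s\,\Delta V$ — aggregate invading signal;
* $J = \sum_V s\,r\,\Delta V$ — penetration-weighted signal, with
  $r(\mathbf{x})$ the normal distance to the monolayer;
* $AR = \dfrac{\sum_V s\,r / M'}{\sum_V s\,|u-\bar u| / M'}$ — mean
  signal-weighted normal penetration over mean signal-weighted lateral
  spread ($u$ the along-monolayer coordinate, $\bar u$ its
  signal-weighted mean, $M'$ the mask signal total). The source analysis
  does not print its aspect-ratio formula; this definition was chosen
  because it is dimensionless, unit-consistent, invariant under mirror
  symmetry, and strictly increasing with directional elongation. It is
  the declared definition, not a reproduction.

Integrals run over the full 3D stack (maximum-intensity projections are
display-only), with anisotropic voxels handled by the per-axis voxel
volume. Differentials are growth-positive: $\Delta M = M_{48h} - M_{0h}$
(the source text's subtraction order and its figures' sign-reversed
plotting disagree; growth-positive is this package's convention). The
48-hr metrics are computed in the registered frame, with the 0-hr
monolayer — the reference vessel wall — transported through the rigid
registration (refitting at 48 hr is config-selectable).

# Transport model

Steady chemoattractant transport is solved on a 2D plan view: two media
channels flanking the gel strip, trapezoidal posts partially occluding
the interfaces (grid cells whose centers fall inside a post are blocked).
Channel flow is plug advection along the channel axis (first-order
upwind); the gel carries pure diffusion with
$D = 5\times10^{-11}\,\mathrm{m^2/s}$ for a 40 kDa growth factor in both
collagen and medium; growth-factor binding is neglected. Boundary
conditions: Dirichlet source/sink at the channel inlets (the monolayer
side is the sink channel), convective outflow at the channel outlets,
optional Dirichlet sink at the gel strip's axial ends (the gel filling
ports), no-flux elsewhere. `flow_rate_ul_min = Inf` idealizes the
channels as fixed-concentration boundaries. The recesses between posts
are treated as stagnant — advection stops one post depth short of the
interface, with the stagnation boundary aligned to a grid face so it sits
at the same physical position at every resolution (plug flow straight
through the recess band would otherwise create broken advective segments
that dump mass into the posts).

The sparse linear system (harmonic-mean face diffusivities, upwind
advection) is solved directly; the relative residual must be below
1e-8. Upwinding makes the system an M-matrix, so the discrete maximum
principle holds: all concentrations lie within [sink, source]. Grid
convergence of the mid-gel gradient under halving is below 2% on the
smooth (post-free) domain; the staircase rasterization of the post
trapezoids converges only first-order, which is the standard behavior for
blocked-cell geometry and is documented rather than hidden. Two Peclet
conventions circulate for this device — the simple axial $uL/D$ and the
lateral-corrected $u(h/L)h/D$ — and both calculators are provided; they
differ by orders of magnitude and the source's quoted value (~50) cannot
be reconstructed without the unstated channel velocity, so neither is
asserted numerically.

The Young–Laplace calculator gives the filling containment pressure
$\Delta P = \gamma(1/R_x + 1/R_z)$ with flat directions contributing
zero, and `supplement_angle()` encodes the post-angle design rule
(180° − contact angle).

# Ensemble statistics

The device is the independent replication unit: condition means are means
of device means, condition standard errors the SD of device means over
$\sqrt{m}$. Condition definitions (VEGF and S1P levels at the monolayer
and opposite channels, nominal averages and gradients) are built in.
Tests against the matched basal control use Welch's two-sample t-test by
default (the classical pooled variant is selectable), with significance
markers at p < 0.1, 0.05, 0.005.

The generative ensemble model treats each region's response as a sum of
independent exponential cell-level events, hence gamma-distributed. In
the constant-CV regime the event count is fixed at
$N = \mathrm{round}(1/\mathrm{cv}^2)$ and the event scale tracks the
device mean, giving SD proportional to the mean (multiplicative noise) —
with cv = 0.4, N = 6 and the realized CV is $1/\sqrt6 \approx 0.408$. A
constant-Fano regime (fixed event scale, count tracking the mean, so
variance rather than SD is proportional to the mean) is also provided
because the two scaling descriptions are both used in the angiogenesis
literature and are mutually exclusive; the mean–SD regression diagnostic
distinguishes them.

`variance_ratio()` estimates $\sigma_d^2/\sigma_m^2$ (within-device over
between-device variance) by the standard method-of-moments one-way
decomposition: the raw variance of device means overstates $\sigma_m^2$
by $\sigma_d^2/n$, so that sampling term is subtracted before forming the
ratio.

Optimal allocation of a region budget $k$ over $m$ devices with $n$
regions each minimizes $SE^2 = \sigma_m^2/m + \sigma_d^2/(mn)$ subject to
$m(n + c) \le k$. The per-device overhead $c$ (default 5
region-equivalents) is essential: without it the model is minimized
trivially at $n = 1$, contradicting the point of ensemble devices. The
continuous optimum is $n^\* = \sqrt{c\,\sigma_d^2/\sigma_m^2}$ — at the
typical observed ratio of 7 and $c = 5$, about 6 regions per device — and
the integer optimizer is verified exactly against a brute-force
enumeration oracle. Ties (e.g. $\sigma_m = 0$) break toward more devices
and are flagged.

# Problem sizes, accuracy and limitations

The test and demonstration phantoms use a scaled region (200 µm gel
width, 80 µm post opening, 8–16 z-sections of 2–4 µm at 2 µm xy pixels)
so a full render-detect-fit-measure cycle takes a few seconds; the
geometry defaults themselves are the reference device. On 20 seeded noisy
phantoms (background SD 0.05 against a monolayer at 1.0) the gel
boundaries are recovered well within 2 px, the monolayer within 2 px
median deviation, the sprout-channel M and J within 5% of the analytic
truth, and the growth differential of an added sprout within 5%.

Known accuracy limits, all visible in the tests rather than hidden:

* The elimination threshold removes the dim blurred fringe of small
  structures; the 5% recovery holds for sprouts at least 3 voxels in
  radius along every axis. Nuclei near the z-sampling limit (a 6–7 µm
  sphere in 4 µm sections) lose 10–15% of their integral to fringe
  elimination; at nucleus-resolving sampling (2 µm sections) the nuclear
  metrics recover within 5%.
* The rendered aspect ratio differs from the analytic one by the lateral
  widening of the optics blur (≈10% at a 2 µm blur on 8–12 µm radii), so
  AR checks are ordinal (elongation increases AR; mirror symmetry leaves
  it fixed) rather than 5%-quantitative.
* Phantoms emulate geometry, staining contrast and Gaussian background —
  not photon shot noise, illumination gradients, spectral bleed-through,
  deformable tissue motion, or branching/anastomosing sprout topology.
  Passing phantom tests therefore validates the measurement chain, not
  robustness to every artifact of real confocal data.

The suite's acceptance script regenerates the mean–SD scaling analysis
(14 devices × 37 regions, constant-CV model, 10 replicate seeds) and
reports the median r² of the SD-on-mean regression:

```{r, eval = FALSE}
tab <- simulate_ensemble(n_devices = 14, n_regions = 37,
                         device_mean_range = c(1, 10), cv = 0.4, seed = 1)
fit <- mean_sd_regression(aggregate_ensemble(tab, "M_cyto")$devices)
fit$r_squared
```
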