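---
title: "Morphodynamic timelines: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphodynamic timelines: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphaline)
```

## The model

Development is reproducible in its *sequence* but variable in its *rate*:
two embryos traverse the same morphological states at individually fluctuating
speeds. `morphaline` treats each recording e as a reparameterized view of a
common process, `frame_e(τ) = master(g_e⁻¹(τ))`, with gₑ monotone increasing.
Alignment therefore reduces to estimating monotone maps between time axes,
which the package does from data in three ways:

- **Rigid** (shift only): a landmark event is located in each recording and
  clocks are shifted so the landmarks coincide. Two landmark detectors are
  provided: the sharp transition in the flow autocorrelation matrix,
  `t₀ = argmax_x Σ_y ∂ₓM(x,y)` (the posterior vorticity pattern flips sign at
  the onset of axis extension, so M anti-correlates across the transition),
  and the maximum acceleration of the r.m.s. speed curve, which defines t = 0.
  Rigid alignment distorts the data least and is required before ensemble
  averaging of flow.
- **Warped**: the correspondence curve is the minimum-cost monotone path
  through the frame-similarity matrix (below). This accommodates genuinely
  variable rates.
- **Static**: a single snapshot is placed on an existing timeline by χ²
  minimization with a curvature-based uncertainty.

### Monotone shortest path

The continuous formulation — a shortest path under the metric
(1/similarity)·ds, solvable by a fast-marching eikonal solver — reduces on a
frame lattice to single-source shortest path with moves {down, right,
down-right}, which is exactly the order-preservation constraint. We use exact
dynamic programming on that DAG; a brute-force enumeration oracle over all
monotone paths pins the semantics in the test suite for every matrix up to
6×6. Because correlations can be ≤ 0, the "inverse similarity" weight is
regularized as `w = 1/(ρ − ρ_min + ε)` with `ε = 0.05·(ρ_max − ρ_min)`; a
constant matrix degenerates to unit weights and the recovered path is the
discrete straight line. Cost ties are broken toward the start–end chord (and
then toward the diagonal), which biases toward a unit rate ratio without
affecting cost optimality. Missing matrix entries are interpolated by
iterative neighbour means *inside the search only*; reported matrices keep
their NAs.

Endpoints sit on the matrix edges at the maximal edge similarity (start on
the top/left, end on the bottom/right edge); ties resolve toward the corners.
The original workflow's interactive endpoint confirmation becomes the
`--override-endpoints` CLI flag.

### Consensus

Designating one recording as reference would import its idiosyncrasies. We
instead pick the *medoid* (highest mean pairwise similarity along its curves)
to seed the consensus axis, map every member onto it, then run **exactly one**
averaging pass that redefines each consensus time as the mean raw member time
at that stage: h(t) = meanᵢ mapᵢ⁻¹(t). One pass suffices to cancel the
medoid's own warp (if members are warps gᵢ of a master, the refined maps
compose as gᵢ ∘ gⱼ⁻¹ exactly); further iterations would only re-average an
already-averaged axis. Maps are re-fitted monotonically
(pool-adjacent-violators) after refinement. The construction is documented as
this package's choice — other fusion schemes (e.g. joint optimization) are
possible.

### Timestamp uncertainty

σ_t is defined by the curvature of chi-squared at its minimum,
`σ_t² = 2·(∂²χ²/∂t²)⁻¹`, with the curvature read from a fitted parabola.
Two numerical choices matter:

- **Core-region fit.** χ²(t) is quadratic only near the minimum; far from it
  the mismatch saturates as patterns decorrelate. Fitting the default ±5
  frame window through the saturated tail biases both the vertex and the
  curvature, so the fit is restricted to the Δχ² ≤ 9 core (the 3-σ region),
  falling back to the three frames nearest the minimum when the core is
  sub-frame. On an exactly parabolic χ² this is inert: χ² = (t−5)² yields
  t₀ = 5, σ_t = 1, and χ² = 4(t−3)² yields σ_t = √(2/8) = 0.5.
- **Residual scale.** χ² = RSS(t)/σ̂² with σ̂² estimated as RSS_min/n when no
  noise level is supplied (the reduced-χ²=1 convention), so σ_t is in time
  units regardless of feature scaling.

The returned t₀ is the parabola vertex (clamped to the fitted window), i.e.
continuous rather than grid-quantized; a minimum on the timeline boundary
raises a warning, a non-convex fit is an error rather than a fabricated
uncertainty. Timestamping demands at least three live members behind the
timeline, and is meaningful only while the morphological clock is running:
during a developmental pause χ² is flat and no timestamp exists — the
calibration experiment samples the active phase.

The ±1σ coverage criterion holds in the noise-dominated regime (sample noise
a few × pattern amplitude, σ_t of order 1 min — the regime real fixed
samples occupy, with their ~2 min uncertainties). With nearly noiseless
samples the residual interpolation/model error dominates σ_t and coverage
degrades; this is a property of the curvature formula itself, not of the
implementation.

## Kinematics

- **PIV** is a deliberately minimal normalized-cross-correlation block
  matcher with 3-point parabolic subpixel refinement (window ≥ 8 grid units,
  ~2–3 % of the chart range; x₂ windows wrap on the periodic chart; flat
  windows are masked; exact integer matches skip subpixel refinement, which
  would only import correlation-falloff asymmetry). It exists so the pipeline
  runs end-to-end from images; production analyses should substitute a
  dedicated PIV tool.
- **Pathlines** use classical RK4 with bilinear spatial and linear temporal
  interpolation, dt = 0.2 min (several substeps per 1-min frame; the value
  is conventional, and halving it changes rotation-field displacements by
  < 1e−4 relative). Seeds leaving the x₁ domain — the truncated pole region
  where PIV is unreliable — are frozen and flagged rather than extrapolated.
  Stored positions stay unwrapped in periodic x₂ so displacements are well
  defined; wrapping happens only when sampling the field.
- **Grid conventions**: `ceiling(0.08·n1)` columns are cut at each x₁ end
  (conservative reading of "~8 %"); x₂ periodicity is handled everywhere by
  index wrapping, never by storing tiled copies.
- **Module segmentation** formalizes the visual identification of stationary
  flow episodes: dynamic programming partitions the diagonal of the
  autocorrelation matrix into blocks maximizing Σ(mean block correlation −
  threshold)·length², length ≥ 3 frames, gaps allowed. The default threshold
  0.6 sits at the e^{−1/2} ≈ 0.61 decorrelation level, keeping "same module"
  and "decorrelated pattern" mutually consistent. Frames whose
  self-correlation is undefined (zero-flow gaps under the vorticity measure)
  are excluded from blocks. Reported boundaries should always be quoted with
  the threshold used.

## Temperature rescaling and decorrelation

Speed curves collapse under v → v/max(v), t → t·max(v) (rescaled speed
dimensionless, rescaled time in distance units). The family that is *exactly*
invariant under this transformation is v_s(t) = s·v₁(s·t) — temperature
multiplies amplitude and clock rate together — and on it the collapse
residual is zero to machine precision. Displacement comparisons across
conditions use the rescaled endpoint t₁(T) = t₁(ref)·v_max,ref/v_max,T
(integrate longer when cold), then a per-seed Welch t-test with
Benjamini–Hochberg correction; the summary statistic is the fraction of
seeds significant at FDR α, which under the null stays at α.

For stripe decorrelation, t_obs is the smaller s.d. of a two-term
shared-centre Gaussian fit (port-constrained `nls`; the fit falls back to a
single Gaussian, with a warning, when it fails, when the two s.d.s are
within 1.2×, or when one amplitude carries < 5 % of the mass — a single
Gaussian in disguise). The kinematic estimate is t_est = c·w/v with stripe
width w = 2 × intensity-weighted s.d. On the cos² stripe heuristic the shift
fraction has closed forms — Pearson gives c = arccos(thr)/2π ≈ 0.146 at
thr = e^{−1/2}, the uncentered overlap gives ≈ 0.279 — neither of which
reproduces the conventional c ≈ 0.34, whose exact construction is not fully
specified; c therefore remains a user input (default 0.34) and both
candidate forms are documented in `shift_fraction_c`.

Mitotic-clock ratios support the two reference conventions in use: onset
times relative to a landmark, and pairwise lags between domains (invariant
to any common shift within a condition).

## Deforming surfaces

ICP alternates brute-force nearest neighbours with the closed-form
Kabsch/SVD rigid fit. Initialization aligns centroids and principal axes,
trying the four proper-rotation axis-sign combinations and keeping the best —
this keeps elongated organs out of the head-to-tail local minimum, but
convergence is still only guaranteed within the initialization basin
(rotations ≲ 30° in the tests). Note that shapes with discrete rotational
symmetry (e.g. an axisymmetric tube meshed with n_θ vertices per ring) have
multiple exact registrations; recovering *the* ground-truth transform is only
well posed for asymmetric shapes.

Shape similarity is `exp(−residual/σ_ref)` with σ_ref the median post-ICP
residual — a monotone similarity in [0,1] that plugs into the same
shortest-path and timestamping machinery as image correlations.

Out-of-plane deformation uses the cotangent Laplace–Beltrami operator with
Meyer mixed Voronoi vertex areas (obtuse triangles fall back to T/2, T/4
splits), signed so a sphere with outward normals has H = 1/R (exact on
icosahedron subdivision levels 0–1 by symmetry; error shrinks ~8× per
further subdivision level). Normal velocity is the forward difference of
matched vertices projected on the area-weighted vertex normal, and
d = 2Hv_n — an inflating sphere gives 2Ṙ/R, an inflating cylinder Ṙ/R, and
a deepening constriction is most negative at its centre. Correlations of d
across material vertices are Lagrangian (tissue-frame) by construction; we
correlate per-vertex fields rather than 2D pullback images, which weights
vertices, not chart area — a difference to keep in mind against
chart-based analyses. Boundary vertices of open meshes are flagged and
excluded.

## The synthetic world

The generators state a world and stay there:

- Flows are sums of fixed smooth patterns (circumferential convergence with
  an x₁ modulation so it carries a vorticity fingerprint; a four-vortex
  extension quadrupole; a localized rotation) under per-module time
  envelopes, zero between windows — piecewise-stationary by construction.
- Stripe images are cos² patterns advected semi-Lagrangianly (RK4
  backtracking, bilinear sampling); default grid 48×64 in tests (scaled down
  from the production-scale 64×128 default purely for minutes-scale
  runtimes, stated here once), dt = 1 min.
- Warps g(t) = shift + rate·t + amp·sin(2πt/period) with monotonicity
  enforced at construction; the temperature proxy s compresses the clock and
  multiplies speeds together (v_s(t) = s·v(s·t)), and velocity resampling
  applies the chain-rule factor 1/g′.
- Image noise defaults to 5 % of pattern s.d. for live recordings; fixed
  samples in the calibration experiment carry 4× pattern s.d. (see above).
  Tube fixtures use Gaussian constrictions deepening linearly over scheduled
  windows, with recorded rigid motions.

What a green test does **not** establish: robustness to real microscopy
artifacts (bleaching, segmentation drift, projection distortion), to
non-shared morphology between genotypes, or to PIV failure modes on real
texture; the generators emulate none of these. The headline numbers of
real-data analyses (e.g. mean flow correlations near 0.94, ±2 min timestamp
uncertainties) depend on recordings this package does not ship and are
covered only qualitatively by the recovery properties.

## Known limitations

- The angle measure is an unweighted mean cosine with a 0.1 μm/min speed
  floor, and the vorticity measure is plain Pearson on ω — the simplest
  forms consistent with their names and the required magnitude invariance;
  weighted variants are possible.
- The consensus construction assumes every member overlaps the medoid's
  span; disconnected overlap graphs are an error, not a partial fuse.
- PIV near non-periodic image edges cannot bracket shifts and returns
  boundary-biased or masked vectors; downstream truncation absorbs this on
  the chart but synthetic non-periodic fixtures must account for it.
- Scalar field I/O is long-format CSV + JSON sidecar rather than a binary
  image container, keeping the package free of image-format dependencies.
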