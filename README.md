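# morphaline

Morphodynamic timeline registration and tissue-flow analysis for developing
embryos.

## The problem

Every embryo develops at its own pace, so two recordings — or a live video and
a fixed, immunostained snapshot — cannot be compared by clock time. What *can*
be compared is morphology: the shape of a gene-expression stripe, the pattern
of tissue flow, the shape of an organ. `morphaline` turns any of these into a
**morphological timeline**:

1. **Similarity.** For two recordings A and B, compute a matrix
   `M(t_A, t_B) = ρ(frame_A(t_A), frame_B(t_B))` under a correlation measure —
   Pearson on images, Pearson on vorticity fields ω = ∂₁v₂ − ∂₂v₁ (a
   magnitude-invariant flow fingerprint), mean vector-angle cosine, or
   post-ICP shape residuals for 3D surfaces.
2. **Monotone warping.** The correspondence curve s: t_A ↦ t_B is the
   minimum-cost monotone lattice path through M, with step cost = Euclidean
   step length × 1/(ρ − ρ_min + ε). Order preservation is built into the
   move set {down, right, down-right}.
3. **Consensus.** All pairwise curves are fused into one consensus timeline
   (medoid member initialization + one averaging pass over member clocks).
4. **Timestamping.** A static sample is placed at t₀ = argmin χ²(t), with
   1-σ uncertainty from the curvature of chi-squared,
   σ_t² = 2·(∂²χ²/∂t² |_{t₀})⁻¹, read from a parabola fitted to the
   quadratic core of χ².

On top of the timeline sit kinematic analyses: minimal PIV, RK4 pathline
integration (dt = 0.2 min) and displacement fields Δ(t₁) = √((x₁−x₀)²+(y₁−y₀)²),
autocorrelation matrices and stationary flow-**module** segmentation,
temperature rescaling v → v/max(v), t → t·max(v) with the rescaled endpoint
t₁(T) = t₁(ref)·v_max,ref/v_max,T, mitotic-clock ratios, stripe decorrelation
timescales t_est = c·w/v, and — for deforming surfaces — the covariant
out-of-plane deformation rate 2Hv_n (mean curvature × normal velocity).

A fully ground-truthed synthetic-data module (modular flows, advected stripe
patterns, monotone time warps, temperature-scaled ensembles, constricting
tubes) makes every stage testable without any external data.

## Worked example

```r
library(morphaline)

## three synthetic "embryos": one master morphogenesis program recorded
## under different clocks (shift/rate warps) with 5% image noise
ens <- synth_ensemble(3, n_frames = 30, noise_sd = 0.05,
                      warps = list(warp_spec(),
                                   warp_spec(shift = 3, rate = 0.8),
                                   warp_spec(shift = -2, rate = 1.25)),
                      seed = 42)
seqs <- lapply(ens$members, `[[`, "images"); names(seqs) <- c("e1","e2","e3")

## all-to-all alignment, then consensus
ct <- consensus_timeline(pairwise_align(seqs, "pearson"))
ct
#> <consensus_timeline> 3 members (medoid e1), dt = 0.718 min

## timestamp a noisy fixed sample of hidden age 17.3 min
feats <- do.call(rbind, lapply(ens$master$images$frames,
                               function(f) as.numeric(f$values)))
fx <- synth_fixed_samples(ens$master$images, times = 17.3,
                          noise_sd = 2 * sd(feats[10, ]), seed = 7)
timestamp_fixed(fx$frames[[1]], feats, times = ens$master$images$times,
                n_members = 3)
#> <timestamp> t0 = 17.5 +/- 0.187 min (1-sigma)

## stationary flow modules from the vorticity autocorrelation matrix
segment_modules(autocorr_matrix(ens$master$flow, "vorticity"),
                threshold = 0.6)
#> <module_segmentation> 3 modules (threshold 0.60)
#>  frame_start frame_end t_start t_end mean_corr    label
#>            1         9       0     8         1 module_1
#>           12        22      11    21         1 module_2
#>           25        30      24    29         1 module_3

## kinematic stripe-decorrelation estimate from width 19 um, speed
## 3.13 um/min and shift fraction 0.34
decorrelation_timescale_est(0.34, 19.0, 3.13)   # -> 2.064 (prints as 2.1 min)
decorrelation_threshold()                        # -> 0.6065 (~0.61)
```

The consensus recovered the three programmed clocks (its maps reproduce the
pairwise compositions g_i ∘ g_j⁻¹ to within one frame); the fixed sample was
placed 0.2 min from its hidden age with an honest 1-σ interval; the module
segmentation found exactly the three programmed stationary-flow windows with
their gap frames left unassigned.

## Command line

```sh
Rscript inst/cli/morphaline.R simgen  --type embryo --seed 1 --out gen/
Rscript inst/cli/morphaline.R simmat  --measure pearson -a gen/member1.csv \
                                      -b gen/member2.csv -o M.csv
Rscript inst/cli/morphaline.R align   -m M.csv -o curve.csv
Rscript inst/cli/morphaline.R modules -m M.csv --threshold 0.6 -o seg.json
```

All interchange formats are plain text (long-format CSV + JSON sidecars,
ASCII PLY for meshes); see `?write_field_sequence`, `?write_ply`.
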