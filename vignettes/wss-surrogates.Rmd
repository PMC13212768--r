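---
title: "Synthetic stenotic coronary geometry and WSS surrogate modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic stenotic coronary geometry and WSS surrogate modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

Wall shear stress (WSS) — the tangential frictional force per unit area that
flowing blood exerts on the vessel wall — is a central hemodynamic marker in
coronary artery disease: values below roughly 1 Pa are considered
pathologically low and atherogenic, while strongly elevated WSS at stenotic
throats is associated with plaque destabilization. Full computational fluid
dynamics (CFD) resolves WSS accurately but takes hours per vessel, which has
motivated surrogate regressors that map vessel geometry directly to the WSS
field in seconds.

`stenowss` implements such a surrogate-modelling study end to end at desk
scale:

1. **Geometry synthesis.** Parametric coronary centerlines (arc-length
   parameterized, 80 mm, standardized to 640 samples) are generated by
   descriptor-constrained smooth random deformation of template paths, and
   focal stenoses of four morphology classes (concentric/eccentric x
   round/oval) are sculpted onto the 3 mm nominal lumen.
2. **Reduced-order oracle.** A quasi-one-dimensional hemodynamic model with
   circumferential and wake corrections generates physically plausible
   ground-truth WSS fields in milliseconds.
3. **Encoding.** The wall becomes a structured axial x circumferential
   lattice, an 8-channel feature tensor, and a hybrid grid/spatial graph.
4. **Surrogates.** Three regressors, implemented from first principles with
   manual backpropagation: a dual-autoencoder MLP, a U-Net, and a
   physics-informed graph neural network (PI-GNN) whose loss couples data
   misfit with gradient-consistency, continuity and inlet-boundary terms.
5. **Evaluation.** Error metrics, node-wise Bland–Altman agreement, axial
   mean WSS profiles and unwrapped-surface reports.

## Geometry: centerlines, descriptors, lesions

A centerline is a 3D path `r(s)` with local lumen radius `R(s)`,
parameterized by arc length. Its shape descriptors are the path length
`l = s_max - s_min`, the chord `c = ||r(s_end) - r(s_start)||`, the
sinuosity `S = l/c` (1 for a straight vessel), and the Frenet–Serret
curvature and torsion

\[
\kappa(s) = \frac{\lVert r' \times r'' \rVert}{\lVert r' \rVert^{3}},
\qquad
\tau(s) = \frac{\det(r', r'', r''')}{\lVert r' \times r'' \rVert^{2}},
\]

computed by central finite differences on the uniform arc grid (one-sided at
the endpoints, which are therefore excluded from closed-form comparisons;
where \(\lVert r' \times r''\rVert < 10^{-9}\) the torsion ratio is 0/0 and
is set to zero).

```{r descriptors}
library(stenowss)
helix <- resample_centerline(
  cbind(2 * cos(seq(0, 6 * pi, length.out = 500)),
        2 * sin(seq(0, 6 * pi, length.out = 500)),
        seq(0, 6 * pi, length.out = 500)),
  n = 640, target_length = sqrt(5) * 6 * pi)
d <- compute_descriptors(helix)
c(kappa = d$curvature[320], torsion = d$torsion[320])  # 0.4, 0.2 analytically
```

**Resampling convention.** Output samples are endpoint-inclusive with
spacing `L/(n-1)`, so the total arc length is exactly the 80 mm standard.
The resampler reparameterizes a per-coordinate natural cubic spline by arc
length and applies one exact global rescale.

**Synthesis.** Clinical shape statistics are not reproduced here; instead a
template family (straight, single-bend, S-bend, helical) is deformed by a
sum of Gaussian-kernel displacement bumps (random center, width 8–20 mm,
direction and amplitude), and candidates are rejected until the descriptor
vector (sinuosity, total curvature, max curvature) falls within bounds
measured over the template family. This simplified deformation keeps the
testable contract of the original diffeomorphic scheme — smooth paths with
descriptor-bounded tortuosity — without its kernel machinery. The
"integral measures of curvature" in the descriptor vector are realized as
\(\int\kappa\,ds\) and \(\max \kappa\), a documented stand-in since the
measures are not individually specified.

**Stenoses.** A lesion is specified by morphology class, stenotic area
ratio `AR = A_sten / A0` on `[0.1, 0.9]` (10% severe, 30% moderate, 50%
mild — smaller is severer), throat position on `[10, 70]` mm, eccentric
offset `d` of up to 50% of the local radius, orientation, and semi-axes
`a >= b` with `pi a b = AR * A0`. The axial transition is a cosine taper
over a configurable extent (default 8 mm; the transition shape is a design
choice, only the throat is prescribed). Throat positions snap to the
nearest lattice station so the minimum station area equals `AR * A0`
exactly. Dual lesions must be separated by at least one axial extent.
Cross-section frames are rotation-minimizing (double-reflection parallel
transport) rather than Frenet frames, which flip on near-straight segments.
The oval aspect ratio is drawn from a configurable 1.5–3 range (not
individually prescribed).

## The reduced-order WSS oracle

The oracle replaces transient 3D CFD entirely; it is a stand-in that
reproduces the statistical structure of stenotic WSS fields, not a
Navier–Stokes solution, and the package makes no claim of CFD-level
accuracy. Its backbone is mass conservation plus the Poiseuille wall
stress: with flow `Q` fixed by a 0.20 m/s cycle-averaged inlet velocity (the
steady training mode) on the nominal area,

\[
\bar U(s) = Q / A(s), \qquad
\tau(s) = \frac{4\,\mu_{\mathrm{eff}}\,\bar U(s)}{R_{\mathrm{eq}}(s)},
\]

with `R_eq = sqrt(A/pi)` and the Carreau effective viscosity evaluated at
the local Poiseuille wall shear rate `4U/R` (the rate does not depend on
viscosity, so no iteration is required). For a concentric lesion this gives
the exact cubic severity law: station-mean WSS scales as
\((R_0/R_{\mathrm{throat}})^{3}\).

Circumferentially the backbone is modulated by (i) the inverse in-plane
wall distance from the section centroid, normalized to ring mean one, which
raises WSS along the minor axis of oval throats; (ii) an explicit eccentric
asymmetry factor `1 + 0.8 (d/R) cos(theta - theta_offset)` peaking on the
offset side of eccentric throats (for an offset *circular* throat the
centroid-distance term alone is exactly uniform, so the asymmetry must be
injected explicitly); and (iii) a curvature factor
`1 + 0.5 kappa R cos(theta - theta_curv)`. Downstream of each throat a
low-WSS wake sector decays with recovery length six throat diameters,
ring-wide for concentric lesions and concentrated opposite the offset for
eccentric ones; depth, length and concentration are configuration with
defaults chosen to produce pronounced wakes in severe cases, with no
numeric claim attached. Optional seeded low-order Fourier noise (default
5% in cohort synthesis) emulates the mapping noise of interpolating CFD
results onto the lattice.

The inlet waveform is a periodic two-bump shape (small systolic shoulder,
dominant diastolic peak) affinely renormalized so its cycle average and
maximum are exactly the configured 0.20 and 0.55 m/s; the precise bump
shape is a parametric choice. The cycle period defaults to 0.6 s and the
outlet reference pressure to 13.3 kPa (100 mmHg). Carreau constants
(`mu0 = 0.056`, `mu_inf = 0.00345` Pa s, `lambda = 3.313` s, `n = 0.3568`)
are standard literature blood values.

```{r oracle}
cl <- resample_centerline(cbind(0, 0, seq(0, 80, length.out = 50)),
                          n = 640, target_length = 80)
sp <- make_stenosis_spec("concentric_round", area_ratio = 0.16,
                         position = 40, seed = 1)
lat <- build_surface(cl, apply_stenosis(cl, sp), n_theta = 40)
f <- oracle_wss_field(lat, flow_params(), rheology = "newtonian",
                      wake_depth = 0)
max(rowMeans(f$values)) / rowMeans(f$values)[10]   # (1.5 / 0.6)^3 = 15.625
```

**What the oracle does and does not emulate.** It reproduces severity
scaling, concentric/eccentric/oval asymmetries, curvature skew and
post-stenotic wakes — the features the surrogates must learn. It does not
contain jet breakdown, secondary vortices, unsteadiness, or pressure
fields; surrogate scores on this oracle therefore demonstrate that the
training machinery works and that the architectures rank as they do on
these smooth fields, not that any surrogate reaches CFD-level accuracy on
real vessels.

## Encoding: tensor, normalization, graph

The analysis window excludes 5 mm transition zones at both ends: stations
41–600 of the 640-station grid, exactly 560 stations spanning 70 mm (on
the desk grid, stations 11–150 of 160, i.e. 140 stations). Each kept node
carries 8 features `(X, Y, Z, C, A, d, a, b)`: position, station curvature,
circumferential angle `A = 2 pi (k-1) / n_theta`, and the station's blended
lesion parameters — 560 x 40 x 8 = 179,200 inputs against 22,400 WSS
outputs on the full-resolution grid. Targets are log-transformed and standardized,
`z = (log(w + 1e-6) - mean)/sd`, with statistics frozen on the training
split; the transform is exactly invertible.

The vessel graph joins the 8-connected structured-grid neighbourhood
(circumferential wrap, no axial wrap; interior nodes have degree exactly 8,
the two end rings 5) with spatial edges between non-grid-connected nodes
within a proximity radius, capped at 6 nearest partners per node. Every
edge carries the weight `w = exp(-dist / 0.1)` (mm). The 0.1 mm length
scale matches the characteristic full-resolution mesh spacing (0.125 mm); the
proximity radius defaults to 0.3 mm, ~2.5x that spacing, and the desk
preset scales it to 1.25 mm to preserve the same ratio on its 0.5 mm
spacing. The spatial search prunes station pairs with a rigorous
centerline-distance bound and is testably identical to the exhaustive
scan. Node angle `theta` entering the continuity term is measured from the
local curvature-normal direction within the cross-section plane — one
reading of an ambiguous definition, flagged as such.

## The three surrogates

All three are trained with Adam (initial rate 1e-3), learning-rate halving
on a 10-epoch validation plateau, early stopping after 30 stale epochs, a
500-epoch cap, batches of 4 models, and a seeded 80/10/10
train/validation/test split (60/20/20 in the desk benchmark). Weight
initialization, shuffling and dropout are all seeded; runs are
reproducible bit for bit on a fixed platform.

**Dual-autoencoder MLP.** The raw mapping (179,200 to 22,400 values) is
intractable for a dense network, so inputs are compressed by a small
strided-convolution autoencoder (3x3 kernels, two 2x2 downsampling stages)
and outputs by a symmetric MLP autoencoder, both to 128-dimensional
latents by default; a compact mapper with two 100-neuron ReLU hidden
layers and dropout 0.2 connects the latents. Stages are trained
sequentially: the two autoencoders on reconstruction loss, then the
mapper on latent targets.

**U-Net.** Encoder blocks of two 3x3 convolutions (reflective axial /
cyclic circumferential padding) with per-channel normalization and ReLU,
2x2 max pooling, a width-doubling bottleneck, transpose-convolution
upsampling with skip concatenation, and a linear 1x1 output head; dropout
grows from 0.1 to 0.3 with depth. Normalization here is per-sample
per-channel over the spatial grid (with running statistics at inference):
with batch-size-4 gradient accumulation over single samples this is the
natural batch-normalization variant, and it is what the package means by
the term. The composite loss is

\[
L = L_{\mathrm{MSE}} + \lambda_1 L_{\mathrm{relative}}
  + \lambda_2 L_{\mathrm{smoothness}},
\qquad \lambda_1 = 0.1,\; \lambda_2 = 0.05,
\]

with the smoothness penalty applied to the prediction's
forward-difference gradients in both grid directions (the printed form of
this term mixes reference and prediction gradients; the package treats
that as a typo and penalizes the prediction, the reading under which the
term is a smoothness prior). The 560 x 40 full-resolution grid supports three
pooling stages (both dimensions divide by 8) with channels 64/128/256 and
a 512 bottleneck; the desk grid (140 x 20) divides only by 4, so its
U-Net uses two stages.

**PI-GNN.** An 8-to-hidden linear input transformation, alternating GCN
and GraphSAGE layers with identity residual additions, and a linear output
head. The GCN layer is the symmetric-normalized aggregation with
self-loops,

\[
H' = \sigma\!\left(\hat D^{-1/2} (A + I)\, \hat D^{-1/2} H W\right),
\]

on the weighted adjacency (the activation is applied after the linear map,
the standard order; the printed equation places it before `W`, which is
treated as a typesetting artifact). The GraphSAGE layer is
\(\sigma(H W_1 + \mathrm{mean}_{j \in N(i)} H_j W_2)\) with the self node
excluded from the mean and empty neighbourhoods contributing zero. Four
layers (gcn, sage, gcn, sage) are the default; the count is not prescribed
and is configurable. Both layers are verified against dense and looped
brute-force oracles.

The physics-informed loss on Pa-scale fields is

\[
L = L_{\mathrm{MSE}} + \alpha L_{\mathrm{gradient}}
  + \beta L_{\mathrm{continuity}} + \gamma(t) L_{\mathrm{boundary}},
\]

with \(\alpha = 0.1\), \(\beta = 0.05\), and \(\gamma\) rising linearly
from 0.01 to 0.1 over 500 epochs so the network learns the data
distribution before the boundary constraint tightens. The gradient term
penalizes discrepancies of edge-wise finite-difference gradients over all
graph edges; the continuity term is the squared residual of

\[
\frac{d\hat y}{ds} + \hat y \left( \frac{d \ln R}{ds}
  + \kappa \cos\theta \right),
\]

the quasi-1D consistency relation an ideal Poiseuille-like field satisfies
(any `c/R(s)` profile on a straight taper has exactly zero residual); the
boundary term anchors the inlet ring to the Poiseuille stress at the inlet
radius and mean velocity, optionally multiplied by a curvature factor
`1 + c_b kappa R` with `c_b = 0` by default since the adjustment is named
but never specified. The network predicts on the normalized scale and is
mapped through the exact inverse log-z transform (with a +/-8 clamp as a
numerical overflow guard) before the loss, so normalization conditions the
optimization while the constraints stay physical.

## Desk preset and the benchmark

The desk preset exists so the complete loop — cohort synthesis, training,
evaluation — runs in minutes on one CPU, and it is first-class, tested
code. Its choices, made once:

* grid 160 x 20 (140 kept stations), same 80 mm length and 5 mm margins;
* cohort of 100 vessels, 60/20/20 split, deformation amplitude 1 mm,
  25% dual-lesion fraction, 5% oracle noise — the study conditions for all
  seeded benchmarks;
* architecture widths scaled down ~8x alongside the ~8x smaller grid:
  PI-GNN hidden 64 (vs 256), U-Net channels 8/16 with bottleneck 32 (vs
  64/128/256 with 512), MLP autoencoder channels 8/16;
* epoch budgets 20 (PI-GNN), 8 (U-Net), 30 autoencoder + up to 200 mapper
  epochs (MLP) — tailored per-architecture budgets in the same spirit as
  the full-scale training configurations, sized so the three-seed
  benchmark completes on one CPU.

Under these conditions the held-out node-wise Pearson correlation ranks
PI-GNN above U-Net above MLP on every tested seed (pooled values
0.85–0.89, 0.64–0.80, and 0.15–0.46 respectively across seeds 1–3),
reproducing the
qualitative ordering of the full-scale study. The test suite asserts the
ordering across three fixed seeds; the numbers themselves are
oracle-relative and are not comparable to CFD-trained scores.

**Bottleneck sweep.** The compression study runs PCA and the learned
autoencoder over bottlenecks {32, 64, 128, 256, 512}. PCA uses exact
nested projections of the raw Pa fields, so its error is non-increasing by
construction. The autoencoders are fitted on the log-z scale (the same
transform used for all surrogate training) and reported as NMAE% of the Pa
fields; the sweep trains them as a nested warm-start family — each larger
bottleneck starts from the smaller solution embedded exactly (new encoder
columns zero, new decoder rows small), and the best state seen is kept —
so the reported error is also non-increasing by construction while every
point remains a genuinely trained model. Cold-started autoencoders at desk
budgets reproduce the same downward trend but with ~0.1% optimization
wiggle near convergence.

## Numerical choices and degenerate inputs

* Derivatives: central differences, one-sided at endpoints, everywhere.
* Torsion on locally straight segments (cross-product norm below 1e-9): 0.
* Nearest-neighbour WSS mapping breaks exact ties by the lowest sample
  index.
* Log-transform stabilizer 1e-6 Pa; zero WSS maps to a finite value and
  the round trip is exact to 1e-9.
* Normalization guards: constant training targets raise a
  degenerate-statistics error rather than dividing by zero.
* Ring polygon areas at 40 sectors under-read continuum areas by
  `1 - sinc(2 pi / 40)` (~0.41%); area-ratio checks compare polygon to
  polygon, which cancels the factor.
* The resampling spacing `80/639` mm differs from the nominal 0.125 mm by
  0.16%; crop indexing is by station count, so the 560/140-station
  cardinalities are exact and the window spans 70 mm to within one
  station.

## Known limitations

* The oracle is a reduced-order stand-in; conclusions transfer to real CFD
  only qualitatively.
* Graphs come from the structured lattice only; arbitrary surface meshes
  are out of scope, as are volumetric meshing, patient image processing,
  pressure/FFR computation, and hypothesis testing between models.
* Training determinism is exercised on a fixed platform; bitwise equality
  across BLAS implementations is not guaranteed.
* The full-resolution configuration (640 x 40, 1,000 models, 500 epochs,
  width-256 networks) is expressible but compute-bound in R; the package's
  empirical claims are desk-scale.
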