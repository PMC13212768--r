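# stenowss

Synthetic stenotic coronary geometry and graph-based wall shear stress
(WSS) surrogates, end to end in R.

Wall shear stress — the tangential force per unit area blood exerts on the
arterial wall — governs where atherosclerotic plaque forms and how it
destabilizes: sustained WSS below ~1 Pa is atherogenic, while the elevated
stress at a stenotic throat marks rupture-prone lesions. CFD resolves WSS
but costs hours per vessel; surrogate regressors that map geometry directly
to the WSS field answer in seconds. This package implements such a
surrogate study at desk scale, for researchers in computational
hemodynamics and scientific machine learning who want a fully inspectable,
reproducible reference stack:

* **Geometry** — arc-length-parameterized centerlines (sinuosity `S = l/c`,
  Frenet–Serret curvature `kappa = ||r' x r''|| / ||r'||^3` and torsion
  `tau = det(r', r'', r''') / ||r' x r''||^2`), descriptor-constrained
  random synthesis, four lesion morphology classes (concentric/eccentric x
  round/oval) with stenotic area ratio `AR = A_sten / A0` in [0.1, 0.9],
  rotation-minimizing-frame wall lattices, STL/VTP/CSV export.
* **Oracle** — a quasi-1D hemodynamic ground-truth generator:
  `tau = 4 mu_eff U(s) / R_eq(s)` with mass conservation `U = Q/A`, Carreau
  shear-thinning viscosity, eccentric/oval circumferential asymmetry, and
  post-stenotic wake sectors. A documented stand-in for CFD.
* **Encoding** — the 560 x 40 x 8 feature tensor (X, Y, Z, curvature,
  angle, offset, semi-axes), log-z target normalization, and a hybrid
  graph: 8-connected grid edges plus capped spatial edges, all weighted
  `w = exp(-dist/0.1)`.
* **Models** — three surrogates with hand-derived backpropagation:
  a dual-autoencoder MLP, a U-Net with composite
  MSE + relative + smoothness loss, and a physics-informed GNN
  (alternating GCN/GraphSAGE layers with residuals) trained with
  `L = L_MSE + 0.1 L_gradient + 0.05 L_continuity + gamma(t) L_boundary`,
  `gamma` ramping 0.01 to 0.1 over 500 epochs.
* **Evaluation** — MAE / median AE / 75th-percentile AE / std error /
  RMSE / Pearson R / R^2, node-wise Bland–Altman limits of agreement
  (`bias +/- 1.96 sd`), axial mean WSS profiles, unwrapped-surface reports.
* **Pipeline** — `cmd_generate / cmd_oracle / cmd_encode / cmd_train /
  cmd_evaluate` with YAML config, config-hash-guarded resumption, and a
  thin CLI at `inst/cli/stenowss.R`.

## Worked example

Synthesize a severely stenosed vessel, generate its ground-truth WSS, and
check the analytic severity law:

```r
library(stenowss)

cl  <- resample_centerline(cbind(0, 0, seq(0, 80, length.out = 50)),
                           n = 640, target_length = 80)
sp  <- make_stenosis_spec("concentric_round", area_ratio = 0.16,
                          position = 40, seed = 1)
lat <- build_surface(cl, apply_stenosis(cl, sp), n_theta = 40)
f   <- oracle_wss_field(lat, flow_params(), rheology = "newtonian",
                        wake_depth = 0)

2 * sp$semi_major                       # throat diameter
#> [1] 1.2
max(rowMeans(f$values)) / rowMeans(f$values)[10]
#> [1] 15.625
```

A 16% area ratio on the 3 mm vessel leaves a 1.2 mm throat, and the
station-mean WSS amplification through the throat equals the Poiseuille
cubic law `(R0 / R_throat)^3 = (1.5 / 0.6)^3 = 15.625` exactly.

Train and compare the three surrogates on a small desk-preset cohort:

```r
ds  <- generate_wss_cohort(40, "desk", seed = 11)
cfg <- train_config(max_epochs = 20, split = c(0.6, 0.2, 0.2), seed = 2)
fit <- train_surrogate(ds, "pignn", cfg)
ev  <- evaluate_surrogate(fit, ds)
ev$pooled
#> <metrics> MAE 0.607  MdnAE 0.180  75thAE 0.315  Std 2.915  RMSE 2.936  R 0.852  R2 0.726 (n=22400)
```

Scores are relative to the package's reduced-order oracle: the surrogate
recovers the held-out WSS fields with sub-Pascal mean error and node-wise
Pearson R of 0.85 at this small cohort size.
`run_desk_benchmark(seed)` runs the full
comparison — on the 100-vessel desk cohort the held-out Pearson R ranks
PI-GNN above U-Net above MLP on every tested seed.

Bland–Altman agreement and a figure/table report for one case:

```r
s <- ds$samples[[fit$split$test[1]]]
bland_altman(predict_surrogate(fit, s), s$target)
render_report("test case", predict_surrogate(fit, s), s$target, "report/")
```

## Scope

The oracle replaces CFD; no Navier–Stokes solver, volumetric meshing,
clinical image processing, or pressure/FFR computation is included, and
oracle-relative scores do not certify accuracy on real vessels. See the
methods vignette (`vignettes/wss-surrogates.Rmd`) for the model details,
parameter choices and limitations.
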