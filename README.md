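# mvwss — a multi-view deep-learning surrogate for aortic wall shear stress

Regions of low time-averaged wall shear stress (TAWSS) on an abdominal
aortic aneurysm (AAA) are where rupture risk concentrates, but obtaining a
patient's TAWSS map means hours of transient CFD — too slow for
time-sensitive clinical decisions. `mvwss` is an R implementation of a
deep-learning surrogate for that computation, aimed at researchers in
cardiovascular biomechanics and scientific machine learning.

The core idea is a **domain transformation**: a triangulated vessel surface
(which has no fixed node count) is rendered into a ring of fixed-size
orthographic snapshots, rotating the geometry in 30° steps about the z axis
(plus x/y rings used as training augmentation). An image-to-image network —
**MultiViewUNet**, a UNet whose decoder levels aggregate *all* encoder
scales through full-scale inter-skip connections
(`Conv₁ₓ₁(Concat[{S(X_En^i, d)}ᵢ₌₁..d])`) and whose encoder/decoder paths add
sigmoid-gated intra-skips across their own scales — maps an input rendering
(surface mean curvature as a colormap, or a shaded view) to the TAWSS
colormap rendering from the same camera. Because background pixels carry no
information, training minimizes the **effective MSE**

    EMSE = (1/Nₑ) Σ (Y(iₑ) − Ŷ(iₑ))²,

summed only over the Nₑ silhouette pixels, and evaluation reports the masked
metrics NMAE / NMSE / NRMSE (as % of the per-geometry maximum stress
max|S|, after converting intensity differences to Pa through the colormap
span) and EPSNR (dB). An invertible 256-entry colormap codec makes the
stress values recoverable from any rendered or predicted image.

Since the original patient cohort and the CFD solver are not
redistributable, the package ships a first-class synthetic module: a seeded
parametric generator of AAA-like geometries (tube + Gaussian sac, ≥ 50%
dilatation by default, family structure for leakage-free splitting) and an
analytic **pseudo-CFD oracle** — a Poiseuille-like inverse-cube law
τ(s,t) = τ₀ (R₀/r(s))³ · w(t)/w̄ pulsed by a systolic waveform — that yields
WSS vector time series and TAWSS ground truth with the qualitative
low-stress-in-the-sac, anti-correlated-with-curvature pattern the surrogate
must learn.

## A worked example

```r
library(mvwss)

# one synthetic aneurysm: 120 mm vessel, 10 mm lumen radius, 75% dilatation
mesh <- generate_aorta(aorta_params(seed = 7))
mesh
#> mv_mesh: 2018 vertices, 4032 faces, fields: <none>

curv <- mean_curvature(mesh)             # cotangent-Laplacian, 1/mm
range(curv$values)                       # [-0.0000, 0.1620] 1/mm

series <- pseudo_cfd_wss(mesh, noise_sd = 0)   # 300 steps, dt = 0.01 s
field  <- tawss(series, cycle_index = 3)       # 3rd cycle: 100 steps averaged
range(field$values)                      # [0.278, 1.562] Pa — low in the sac

mesh <- attach_field(mesh, field)
views <- render_views(mesh, mode = "field", field = "tawss",
                      step_degrees = 30, resolution = 768)
length(views)                            # 12 views; exact silhouette masks
small <- downsample(views[[1]], 256)     # the 768 -> 256 capture pipeline
```

The end-to-end pipeline (generate → render → split → train → evaluate) runs
under one seed; `smoke_run_config()` is the desk-scale preset (40 synthetic
geometries, 64 px views, depth-3 width-8 network, ≤ 12 epochs):

```r
res <- run_pipeline(smoke_run_config(seed = 1), out_dir = "run1")
cat(format_comparison(res$comparison))
#> Model                  NMAE       NMSE      NRMSE      EPSNR
#> MultiViewUNet        7.293%     2.430%    11.906%    17.46dB
#> UNet                 6.936%     2.276%    11.828%    17.29dB
#> ConstantMean        27.096%    14.501%    30.335%     8.97dB
```

Reading the table: the trained surrogate reconstructs the held-out TAWSS
maps with a mean absolute error of ~7% of each geometry's peak stress —
about a quarter of the no-information (constant mean color) baseline — and
matches the equal-width vanilla UNet at this reduced scale. The run
directory holds the dataset manifest, rendered views, split, checkpoints,
per-epoch history, per-image/per-geometry metric reports and the resolved
YAML config; rerunning with the same seed reproduces all of them.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/mvwss.R run --seed 1 --out run1
Rscript inst/cli/mvwss.R render --mesh run1/dataset/meshes/fam001_g00.vtk --field tawss
```

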