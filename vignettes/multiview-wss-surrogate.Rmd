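---
title: "A multi-view image surrogate for wall shear stress on aneurysm surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-view image surrogate for wall shear stress on aneurysm surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Low wall shear stress (WSS) on an abdominal aortic aneurysm (AAA) marks
regions prone to rupture, but computing the time-averaged WSS (TAWSS) map for
one patient geometry requires hours of transient CFD. `mvwss` implements a
deep-learning surrogate built around a *domain transformation*: instead of
operating on meshes with varying node counts, the 3D surface is rendered
into a ring of fixed-size 2D snapshots, a convolutional image-to-image
network translates an input rendering (surface curvature encoded as a
colormap, or a shaded view) into the TAWSS colormap rendering from the same
camera, and masked image metrics score the prediction on the stress scale.
Because every geometry becomes a set of equally sized images, no mesh
registration or uniform node count is ever needed.

The pipeline stages map one-to-one onto package modules:

1. **Geometry core** — triangulated surface container (`tri_mesh`),
   STL/PLY/OBJ/VTK I/O, and signed mean curvature by the cotangent-Laplacian
   estimator with Meyer mixed vertex areas (`mean_curvature`, units 1/mm,
   convex bulges positive).
2. **Synthetic cohort** — a seeded parametric generator of AAA-like
   tube-with-sac surfaces (`generate_aorta`) and an analytic pseudo-CFD
   oracle (`pseudo_cfd_wss`) supplying per-vertex WSS vector time series and
   TAWSS ground truth (`tawss`).
3. **Multi-view rendering** — orthographic snapshot rings with exact
   silhouette masks (`render_views`), an invertible 256-entry colormap codec
   (`colormap_codec`, `encode_field`, `decode_image`), area-averaged
   downsampling and runtime random-zoom augmentation.
4. **Network** — `MultiViewUNet`: a depth-D encoder–decoder whose decoder
   levels aggregate *all* shallower encoder maps (full-scale inter-skips
   with 1×1 channel reduction) and whose encoder/decoder paths additionally
   aggregate their own shallower/deeper maps through sigmoid-gated
   intra-skips; a `vanilla_unet` mode restricts skips to the classic
   same-level copy.
5. **Training** — Adam on the *effective* (background-masked) MSE with
   family-stratified validation, early stopping and best-weight restoration.
6. **Evaluation** — masked metrics (EMAE/EMSE/ERMSE, NMAE/NMSE/NRMSE in %,
   EPSNR in dB) per image, per geometry and aggregated, plus model
   comparison tables.

## The masked loss and metrics

Plain MSE over a rendered view is dominated by background pixels that carry
no information. The training loss is therefore the *effective MSE*

$$\mathrm{EMSE} = \frac{1}{N_e}\sum_{i_e=1}^{N_e}\big(Y(i_e)-\hat Y(i_e)\big)^2,$$

where the sum runs only over the $N_e$ pixels covered by the geometry
(each contributing its channel-mean squared intensity difference). The mask
comes from a silhouette pass of the rasterizer — triangle coverage, not
white-pixel detection — so a bright specular pixel can never punch a hole in
it. With an all-true mask the loss reduces to plain MSE; background
corruption never changes it (both are property-tested).

Evaluation converts masked intensity differences to stress units through the
colormap span before normalizing: NMAE $= 100\cdot$EMAE$/\max|S|$ with
$\max|S|$ the per-geometry maximum ground-truth TAWSS (the codec's recorded
range maximum). NMSE is normalized by the *first* power of $\max|S|$ — the
convention of the source field's reporting — which is dimensionally odd for
a squared quantity; `nmse_squared_norm = TRUE` selects the
$\max|S|^2$-normalized variant. EPSNR uses the intensity scale with
$\mathrm{MAX}_I = 1$, so a perfect prediction reports `Inf`.
Aggregation over a test set is the unweighted mean over test *images*
(per-geometry breakdowns are included in every report); image- versus
geometry-weighting is not distinguishable from single reported scalars, so
the convention is recorded in the report object.

## The network

Channel width at level $d$ (1-indexed from the top) is
$n\cdot 2^{d-1}$: the published architecture text states both "$n\times 2^d$"
and "starting from *n* initial filters", which conflict at the first level;
the package resolves the exponent as 0-indexed depth so that level 1 has $n$
filters. Each convolution block is two 3×3 conv + batch-norm + ReLU layers.
Scale matching uses max pooling (downward) and bilinear upsampling (upward);
at full depth (D = 5) the encoder intra-skips into the bottleneck pool by
16, 8, 4, 2 and the top decoder level gathers deeper maps upsampled by
2, 4, 8, 16 — these factors are recorded in `model$structure` and asserted
in the tests. Sigmoid gates are applied directly to the scaled maps (no
extra learnable layer inside the gate), the literal reading of the
aggregation equations. The inter-skip 1×1 convolution reduces the
concatenation to the level-$d$ width, keeping decoder blocks uniform. The
final layer is a 1×1 convolution with a sigmoid, emitting valid `[0, 1]`
color images. Inter-skips aggregate encoder levels $1..d$ (the literal
summation bound), not all D levels.

The whole network — including the custom conv/BN/pool/upsample kernels and
the reverse-mode tape — is validated by finite-difference gradient checks at
the kernel level and on the assembled model, and by an
overfit-one-batch optimization check.

## The synthetic cohort and the pseudo-CFD oracle

The generator emulates what the surrogate needs from real data: AAA-like
geometry variation with family structure, and a smooth, positive,
geometry-determined stress field that is low inside the sac and
anti-correlated with surface curvature. It does **not** emulate patient
anatomy (no branching, no intraluminal thrombus, no lumen irregularity) or
flow physics (no turbulence, no pressure field, no oscillatory component) —
passing tests demonstrate that the pipeline can learn *a* smooth
geometry-to-stress map end-to-end, not that it reproduces clinical CFD.

A geometry is a circular cross-section swept along an optionally bent
centerline, radius $r(s) = R_0(1 + \beta\,G(s))$ with $G$ a Gaussian bump;
defaults are clinical-scale: $R_0 = 10$ mm, length 120 mm, bulge factor
$\beta = 0.75$ (maximum diameter 75% above baseline — beyond the 50%
dilatation threshold that defines an aneurysm), sac extent 45 mm
($4\sigma$), mild bend and 1% smooth radius noise. The seed perturbs bend
direction, sac asymmetry and radius noise, so one parameter set defines a
*family* of related geometries — the unit of leakage-free splitting.

The oracle assigns the instantaneous wall shear magnitude
$\tau(s, t) = \tau_0\,(R_0/r(s))^3\, w(t)/\bar w_{\mathrm{ref}}$ directed
along the local axial tangent: a Poiseuille-like inverse-cube law
($\tau = 4\mu Q/\pi r^3$) modulated by a two-phase pulsatile waveform with a
systolic peak at 30% of the cycle. $\bar w_{\mathrm{ref}}$ is the mean
velocity of the *default* waveform template — a fixed constant — so
$\tau_0$ (default 1.5 Pa, a typical aortic TAWSS) is the tube's
time-averaged stress under the default waveform, and scaling any supplied
waveform by $c$ scales TAWSS by exactly $c$. Doubling the sac radius
divides sac stress by 8, and the high-curvature sac surface receives low
stress — the qualitative pattern the surrogate must learn. Optional
Gaussian noise is added to the signed magnitude (along the tangent), so the
TAWSS perturbation scales linearly with the noise SD. TAWSS is the
arithmetic per-step mean (rectangle rule) of vector magnitudes over one
selected cycle; with dt = 0.01 s and a 1 s cycle, a 3 s series yields 300
snapshots of which the third cycle's 100 enter the average, discarding
start-up transients.

## Rendering choices

* **Orthographic projection, fixed per-geometry framing.** The camera ring
  is centred on the vertex centroid with the scale fixed from
  rotation-invariant bounds (maximal in-plane radius and axial extent) and a
  5% margin. Centroid centring makes rotating the mesh *exactly* equivalent
  to advancing the camera — a bounding-box centre is not
  rotation-equivariant and breaks that equivalence at the sub-pixel level.
  Perspective projection would make apparent size angle-dependent.
* **Counterclockwise steps viewed from the positive axis end**; view 0 is
  the unrotated front view, and `step_degrees` must divide 360 so the ring
  closes.
* **Colormap**: a fixed blue-to-red 256-entry LUT with 8-bit-exact entries
  (PNG round trips cannot perturb decoding), per-geometry `[min, max]`
  normalization ranges recorded in view metadata, and nearest-LUT-color
  inversion. Invertibility, not aesthetics, is the requirement: the
  round-trip error is at most half a quantization step, verified
  exhaustively over all 256 entries. Curvature values are clipped to the
  [1st, 99th] percentile per mesh before normalization because discrete
  estimators spike on sliver triangles and would crush the color range.
* **Shaded mode** uses a deterministic headlight with a
  metallic/roughness-style response (diffuse + narrow specular lobe),
  clamped strictly below white.
* **Augmentation**: x- and y-axis rings are rendered identically but
  flagged, and the pair builder admits them to training only; test sets are
  z-axis views exclusively. Runtime random zoom resamples nearest-neighbour
  (never blending colormap colors), draws one seeded factor per training
  pair and applies it to input and target alike. The zoom range default
  (0.9, 1.1) is a declared choice, not a published value.

## Training protocol

Adam (lr $10^{-4}$ full scale), at most 300 epochs, early stopping on the
validation loss with patience 30 and best-weight restoration. The published
protocol monitors a validation loss without defining a validation split;
this package holds out a family-stratified 10% of the *training* families —
never the test set — because early stopping needs unseen data and a base
geometry and its variants must not straddle the monitor boundary. Batch
size defaults to 8. Splitting precedes rendering, so no rendered view of a
test geometry can leak into training; the pair manifests are audited for
this in the tests.

## Desk-scale validation conditions

The validation suite runs the full pipeline at a reduced size chosen for a
single CPU (`smoke_run_config()`): 8 families × (1 base + 4 variants) = 40
synthetic geometries with 2 families (10 geometries) held out, 120° steps
(3 z-views + 6 augmentation views per geometry), 128 px renders downsampled
to 64 px, a depth-3, width-8 network, learning rate $2\times10^{-3}$, at
most 12 epochs with patience 5. The raised learning rate is deliberate: with
~200 images per epoch and a 47k-parameter network, the full-scale
$10^{-4}$ rate would barely move the weights within this epoch budget. At
this scale the trained MultiViewUNet reaches roughly a quarter of the
constant-mean baseline's NMAE and performs on par with the equal-width
vanilla UNet; the published full-scale ordering (the proposed network ahead
of UNet by a few hundredths of a percent NMAE) sits well inside the noise
of a desk-scale run, so the suite asserts the directional contract —
at least halving the no-information baseline and staying within 10% of the
vanilla UNet — rather than absolute values, which would require the real
23-patient cohort, hundreds of CFD hours and GPU-scale training.

## Numerical notes and degenerate inputs

* Curvature: boundary vertices of open meshes inherit their nearest interior
  value (cotangent weights are undefined there); zero-area triangles leave
  the stencil with a warning; meshes under 4 vertices error.
* Rasterization: z-buffer keeps the closest fragment; degenerate
  (zero-projected-area) triangles are skipped; an empty silhouette is an
  error, as is a zero-extent mesh.
* Batch norm uses biased batch variance, momentum 0.1 running moments for
  inference, epsilon $10^{-5}$.
* An empty mask makes the masked loss undefined ($N_e = 0$) and errors;
  EMSE $= 0$ reports EPSNR `Inf` rather than erroring.
* Early stopping requires strict improvement ($>10^{-12}$) to reset
  patience; a frozen model therefore stops after exactly `patience` + 1
  epochs.
* All randomness (geometry sampling, WSS noise, splits, shuffling, zoom,
  weight init) flows from explicit seeds; a single global seed fans out to
  per-stage seeds by stable string hashing, and every stage is reproducible
  in isolation.

## Known limitations

Predicted images are not reassembled into per-vertex 3D stress fields (view
consistency is unresolved by design). The pseudo-CFD oracle is axisymmetric
per cross-section and cannot express secondary-flow features (oscillatory
shear, recirculation). Metrics computed on image pixels weight visible
area, not mesh area, so strongly foreshortened regions contribute less than
their anatomical share.
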