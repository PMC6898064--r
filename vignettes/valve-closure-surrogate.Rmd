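---
title: "Learning valve closure: model, simulator, and design choices"
author: "valvecae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning valve closure: model, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bioprosthetic aortic valves are designed as three NURBS leaflet patches
sutured to a stent. Whether a candidate design closes well is usually judged
by shell finite-element (isogeometric) closure simulations, which yield the
deformed leaflet shapes and the *coaptation area* -- the area over which the
closed leaflets press against each other. Those simulations are far too slow
for interactive design-space exploration. `valvecae` implements the
alternative: a convolutional autoencoder that maps the undeformed
control-point geometry, the transvalvular pressure, and the leaflet material
description directly to the closed configuration and its coaptation area.

A full shell-contact solver is outside the scope of this package. In its
place, `simulate_closure()` is a fast, fully specified surrogate with the
same interface and the qualitative structure the learning problem relies on;
it provides unlimited ground-truth data at desk scale. A production IGA
backend could be substituted behind the same function without touching the
rest of the pipeline.

## Geometry

A leaflet is a tensor-product NURBS patch: an `m x n` control grid (default
`8 x 8`, cubic in both directions, open uniform knots on the unit square,
unit weights). Grid axis 1 runs circumferentially across the leaflet's
120-degree sector, axis 2 from the attachment (suture) edge to the free
edge. This orientation is fixed throughout the package because the
convolution layers act on it. The rational machinery (weights) is retained
and exercised by exact conic test surfaces, although generated leaflets are
polynomial.

The parametric family (`valve_params()`, `build_leaflet()`) has five
parameters: diameter `D` (default 2.3 cm, the average aortic valve
diameter), belly curve parameter `b`, free-edge curve parameter `f` (both
dimensionless in [0, 1]), free-edge height `h`, and commissure height `Hc`
(default 1.2 cm). The published construction this family stands in for is
not fully specified in the open literature, so the package uses an explicit
closed-form design in which each parameter has a monotone, localised effect:
`b` pulls the mid-leaflet belly toward the valve axis, `f` sags the centre
of the free edge, and `h` sets the free-edge height at the commissures. The
construction is mirror-symmetric within a leaflet, and leaflet `k` is
leaflet 0 rotated by `2*pi*k/3`, so every generated valve has exact 3-fold
rotational symmetry. Any construction with the same parameter names can be
swapped in behind `ValveDesignParams` semantics.

## The closure surrogate

`simulate_closure()` moves every control point radially toward the valve
axis:

* envelope `g(i, j) = sin(pi * i/(m-1)) * j/(n-1)`, zero on all attachment
  edges (the edge rows are zeroed explicitly so the fixed boundary holds
  bitwise, not merely to rounding);
* dimensionless load `L = p * R / (k_eff * t)` with `R = D/2`,
  `k_eff = c0 + c1*c2`, thickness `t`; pressure stays in mmHg and the unit
  conversion is absorbed into the saturation constant `lambda0 = 1`;
* saturating response `S = L / (L + lambda0)`; radial closure
  `dr = g * S * rho * r` with `rho = 0.95` so no point can cross the axis.

Angular and axial coordinates never change, which guarantees that leaflets
remain inside their sectors (no interpenetration) and makes the response
provably monotone: coaptation grows with pressure and shrinks with stiffness
and thickness. An optional smooth multiplicative field (amplitude 2% of
`dr`, four low-order sine modes, seeded per sample, shared by the three
leaflets so symmetry is preserved) emulates the run-to-run variability of a
real simulation corpus; without it the learning task would be an exact
deterministic function of nine scalars. Parameter sweeps that "re-simulate"
spot checks use the noiseless response, which is also what a trained network
approximates (the conditional mean).

Default sampling ranges -- `b, f` in [0, 1], `h` in [0.6, 1.2] cm, `c0` in
[300, 700], `c1` in [500, 1500], `c2` in [1, 2], `t` in [0.035, 0.065] cm,
`p` in [70, 90] mmHg -- were chosen once so that the load `L` traverses the
sensitive part of the saturation curve and peak displacements reach roughly
0.6-0.9 cm on a 2.3 cm valve, the physiological scale of diastolic leaflet
motion. With these conditions mean displacement magnitude is about 0.1 cm
and coaptation areas span roughly 0.003-0.25 cm².

**Coaptation area.** The contact computation of a shell solver is replaced
by a proximity rule: sampling each leaflet on a midpoint grid (default
`64 x 64`), a sample is *coapting* when its deformed position lies within
`eps = 0.05` cm of either sector-boundary half-plane **and** its
displacement magnitude exceeds `u_c = 0.01` cm (excluding undisplaced
attachment and commissure points). Qualifying samples contribute their
**reference** (material) area element, and leaflet contributions are summed
one-sidedly without division by two. Using the material measure rather than
the deformed one reflects that real leaflet tissue is nearly inextensible
(the surrogate's radial contraction artificially compresses the deformed
measure) and has a structural advantage: both qualifying conditions are
monotone in the load at fixed area elements, so the monotonicity of the
area response is exact rather than approximate.

## The network

`cae_config()` / `train_cae()` implement the convolutional autoencoder. Each
leaflet's control grid enters as an `m x n x 3` texture (channels = x, y, z
in cm). Three 3x3 stride-1 convolution blocks (default channels 8/16/32,
ReLU) and a dense layer produce a 64-dimensional per-leaflet embedding; the
encoder weights are shared across leaflets by default, exploiting the
valve's symmetry (per-leaflet encoders are available via
`share_encoder = FALSE`). The three embeddings are concatenated with the
four standardised material features and the standardised pressure repeated
ten times, and fused into a 128-dimensional code layer. The decoder mirrors
the encoder: a dense expansion to `m x n x 32`, two stride-1 transposed
convolutions (at stride 1 a transposed convolution is itself a convolution),
and a linear 9-channel output that is split into the three leaflets'
displacement grids. A small dense head with a final ReLU emits the
coaptation area, which is therefore non-negative by construction.

On an 8x8 grid stride-2 downsampling is counterproductive, so all blocks
are stride 1; channel widths of 8/16/32 (rather than wider stacks) keep a
CPU training run of the reference problem size inside minutes while leaving
the fit limited by data, not capacity. All layers, backpropagation, and the
Adam optimiser are implemented in the package on top of BLAS matrix
multiplication (im2col layout); gradient correctness is pinned by
finite-difference tests.

**Loss.** Displacement targets are the fields `u` (deformed minus reference
control points); deformed control points are recovered by addition. The
displacement loss is mean squared error weighted per node by
`w = |u_true| / max |u_true|`: fixed attachment nodes have exactly zero
weight, so the optimiser is never asked to drive outputs to exact zeros, a
request that would otherwise compete with fitting the moving nodes. The
magnitude weight is shared by the three Cartesian components of a node.
This nodal-vector reading matters here: the surrogate's displacement fields
are purely radial, so a componentwise weight would assign zero weight to
*every* z-component and leave a third of the output entirely untrained
(observed as a z-error plateau). If a target field is all-zero
(`max |u_true| < tau = 1e-12`) the loss falls back to unweighted MSE.

The total loss is the sum over leaflets of the weighted displacement term
plus `lambda_c = 1` times the squared coaptation error, both on
standardised scales: the displacement term is divided by the training-split
displacement standard deviation, and the coaptation head learns the area in
units of its training standard deviation (the ReLU output is rescaled to
cm² at the interface). Balancing the terms this way is essential in
practice -- with the raw scales the standardised coaptation gradient is two
orders of magnitude larger than the weighted-MSE gradient, the shared code
layer optimises only the scalar head, and the raw-scale ReLU output
collapses into the dead region within the first epoch.

**Training.** Adam (lr 1.5e-3, cosine decay to lr/20, minibatch 16, 50 epochs
by default), per-epoch validation, and checkpoint selection at the minimum
validation loss. Random-translation augmentation (shift all textures of a
sample by one uniform vector in [-0.5, 0.5] cm per axis with probability
0.5; targets are translation-invariant) is on by default. Everything --
initialisation, shuffling, augmentation -- derives from the config seed.
Divergence (non-finite loss) aborts with a diagnostic rather than returning
NaN weights.

**Boundary conditions at inference.** Because the fixed attachment nodes
carry zero loss weight, their raw network outputs are never trained and
retain initialisation-scale noise. The fixed mask is part of the geometry
definition -- an input, not a prediction -- so `predict()` imposes the known
essential boundary condition by zeroing those outputs
(`apply_fixed_mask = TRUE`, the default), exactly as a PDE surrogate imposes
hard Dirichlet conditions. The raw outputs are available with
`apply_fixed_mask = FALSE`.

## Metrics

`evaluate_run()` compares predicted and simulated deformed configurations
per valve: mean Euclidean distance over matched control points, symmetric
Hausdorff distance between densely sampled surfaces (control points do not
lie on the surface; the single-pair default is a 50x50 grid per leaflet,
corpus evaluation defaults to 20x20 for cost), and partial Procrustes
distance -- the RMSD after optimal translation and rotation *without*
scaling, so the statistic keeps length units (cm). Corpus-level summaries
are the max/mean/median of the per-valve values, one number per cell.
Coaptation quality is reported as RMSE (cm²) and Pearson correlation.

`max_principal_strain()` computes the in-plane Green-Lagrange strain from
the first fundamental forms of the reference and deformed surfaces,
`E = (Abar - A)/2`, and returns the larger eigenvalue of `E v = lambda A v`
on a parameter grid (closed form for the 2x2 pencil). Uniform in-plane
stretch by `s` gives `(s^2 - 1)/2` exactly; rigid motions give zero; points
with a degenerate reference metric are flagged `NA` rather than propagated.

## Pipeline and embedding

`split_dataset()` shuffles and cuts at `round(f * n)`; at the published
corpus size of 90,941 simulations the 0.8/0.1/0.1 defaults reproduce the
72,753 / 9,094 / 9,094 record counts, which is why those fractions (rather
than the also-quoted 60/20/20) are the default. `parameter_sweep()` varies
one input over a dense grid (default 1000 points -- a stated increment of
0.2 mmHg over 70-90 mmHg and a stated count of 1000 are mutually
inconsistent, so the explicit count wins), regenerating geometry when a
design parameter is swept, and can re-simulate random spot values to check
the +/-10% agreement band. `tsne_embed()` embeds code-layer activations
with an exact, seeded t-SNE implemented in the package (perplexity
bisection, early exaggeration, momentum with gain adaptation; defaults
perplexity 30, seed 0); design-parameter labels are attached for colouring
only and never enter the embedding.

## What the synthetic corpus does and does not show

The generator reproduces the *structure* of a closure-simulation corpus:
zero displacement on suture lines, 3-fold symmetry, saturating pressure
response, monotone material response, non-interpenetrating leaflets, a
smooth nuisance field, and a coaptation area coupled to the deformation.
It does not contain shell bending mechanics, true contact pressure
distributions, tissue anisotropy, or the high-curvature wrinkling of real
closed leaflets. Passing the end-to-end tests therefore demonstrates that
the architecture, loss, and pipeline can learn a deformation-and-coaptation
map of this structure at desk scale -- not that the specific published
accuracy figures transfer to a corpus of real isogeometric simulations,
which would require that corpus and longer training.

## Problem sizes used by the tests and acceptance script

The reference desk-scale study is 2,000 simulations on the default 8x8
grid, split 0.8/0.1/0.1, trained for 50 epochs (about 6-8 minutes on one
CPU core); the same conditions are used by `scripts/acceptance.R`. Kernel
oracles run on up to 100 random rational patches; the coaptation quadrature
is cross-checked against a 500x500 dense sampling; Hausdorff distances are
cross-checked against an all-pairs double loop.

## Known limitations

* The surrogate's displacement field is purely radial; real closure has
  axial sag and circumferential shear. The z-outputs of the network are
  therefore validated only against zero targets here.
* Coaptation by proximity threshold (`eps`) is a stand-in for a contact
  algorithm's contact set; its absolute scale depends on `eps`.
* The parametric design family is a documented stand-in, not the published
  supplementary construction.
* t-SNE is exact O(n^2): comfortable for thousands of codes, not millions.
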