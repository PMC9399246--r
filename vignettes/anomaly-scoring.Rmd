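---
title: "GAN-based anomaly scoring of breast reconstruction cosmesis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GAN-based anomaly scoring of breast reconstruction cosmesis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Radiotherapy after mastectomy and immediate reconstruction can degrade the
cosmetic result of the reconstructed breast (capsular contracture, deformity,
asymmetry). Objective, longitudinal measurement of that degradation is hard:
questionnaires are subjective, and photograph-based scoring lacks volume
information and requires dedicated photography sessions. `anoscore`
implements an alternative that works from routinely acquired chest CT: the
torso surface is rendered as a frontal depth image, a generative adversarial
network trained exclusively on *normal* breast surfaces assigns each image a
continuous anomaly score (AS), and AS trajectories across follow-up visits
(before radiotherapy, one and two years after) are analyzed with paired tests
and a random-intercept linear mixed model.

Because real CT and outcomes data are institutional, the package ships
first-class synthetic generators — torso phantoms with controllable,
severity-graded deformities, and longitudinal cohorts drawn from the exact
mixed model the analysis assumes — so that every stage is exercisable and
testable end to end.

# From volume to image

`load_dicom_series()` reads one axial CT series (slices sorted by position,
rescale slope/intercept applied so voxels are in Hounsfield units);
`make_phantom_volume()` produces synthetic density fields with the same
container. `extract_isosurface()` triangulates the body surface;
`render_frontal()` produces the image the GAN consumes.

The rendering is an orthographic frontal *depth map*: each pixel holds the
distance from the anterior image plane to the first crossing of the iso-level
along the anterior–posterior axis, min–max normalized to [0, 0.95], with rays
that miss the surface set to exactly 1.0 (white background, strictly the
brightest value). A depth map was chosen over a shaded surface capture
because it is deterministic, has no lighting or camera parameters, and
preserves precisely the 3D shape information a cosmesis score must see. It
is a proxy for, not a replication of, screenshots from commercial
visualization software.

Numerical choices:

* Default iso-level: −300 HU for CT (skin–air boundary), 0.5 for phantom
  density fields in [0, 1].
* Isosurface extraction is marching tetrahedra (six tetrahedra per cell
  sharing the main diagonal, chosen so face diagonals agree between
  neighbouring cells and the surface is crack-free). Piecewise-linear
  surface area converges to the analytic value under grid refinement on
  smooth fields (the test suite verifies monotone error decay to < 0.5% on
  an analytic sphere); on fields with interpolation kinks (e.g. clamped
  ramps) a small resolution-independent area bias of order 1% remains, which
  is inherent to piecewise-linear isosurfacing.
* Resizing is bilinear and clips to [0, 1]; resizing to the current size is
  an exact no-op. The full-scale configuration mirrors a 500 × 500 capture
  downsampled to a 256 × 256 model input.

# The anomaly GAN

## Model

A Wasserstein GAN with gradient penalty is trained on normal images only:
the critic $D$ maximizes $\mathbb{E}[D(X)] - \mathbb{E}[D(G(z))]$ subject to
the gradient penalty $\gamma\,(\lVert\nabla_{\hat X} D(\hat X)\rVert_2-1)^2$
($\gamma = 10$, interpolates $\hat X$ between real and generated samples),
while the generator $G$ maximizes $\mathbb{E}[D(G(z))]$, with five critic
updates per generator update. Training on normal anatomy only is what makes
the score an *anomaly* score: the model can only reconstruct what it has
seen.

A separate encoder $E$ then learns the inverse mapping image → latent code
with $G$ and $D$ frozen, minimizing

$$\mathrm{Loss}_{izi} = \mathrm{Loss}_{images} + k\,\mathrm{Loss}_{features},
\qquad
\mathrm{Loss}_{images} = \tfrac1n\lVert X - X'\rVert^2,\quad
\mathrm{Loss}_{features} = \tfrac1m\lVert f(X) - f(X')\rVert^2,$$

where $X' = G(E(X))$, $n$ is the pixel count, $f(\cdot)$ is the activation of
the critic's penultimate layer and $m$ its dimension. The weighting factor
defaults to $k = 1$ and is exposed in the configuration. The logged
per-step losses satisfy the decomposition identity exactly, which the test
suite asserts at every step.

## Scoring

An image is scored in a single pass:

$$\mathrm{AS}(X) = (1-\lambda)\,R(X) + \lambda\,D(X),$$

with $R(X) = \mathrm{Loss}_{images}$, $D(X) = \mathrm{Loss}_{features}$ and
$\lambda = 0.95$ by default. Raw scores are standardized as z-scores against
the distribution of raw scores on the normal reference set; by default the
reference is the normal training images themselves (switchable to a held-out
normal set). Standardization is global — one reference for all visits — so
that z-scores are comparable across time points. Higher AS means a more
abnormal surface.

## Architecture and implementation

The networks are compact fully-connected (dense) generator, critic and
encoder with leaky-ReLU hidden units, sigmoid generator output and linear
critic/encoder outputs, scaled by the input size. This architecture was
chosen deliberately: at the image scales the package targets it trains in
minutes on a single CPU, it is fully deterministic given a seed, and —
because hidden activations are piecewise linear — the parameter gradient of
the gradient penalty can be computed *exactly* by backpropagating through the
forward-mode directional-derivative chain (the second-order activation terms
vanish almost everywhere). All gradients, including that double-backprop,
are verified against central finite differences in the test suite.
Optimization is Adam with the published configuration (learning rate 0.001,
batch size 32, $\beta_1 = 0.5$, $\beta_2 = 0.999$, latent dimension 128,
256 × 256 input, 7000 epochs); toy-scale runs override size, latent
dimension and step counts, and the full-scale profile is available via
`pipeline_config(profile = "full")` but is long-running.

# The phantom generator

`make_phantom_volume()` builds a half-torso slab with two spherical mounds
on a gently curved chest wall, as a smooth ramped signed-distance density
field plus optional voxel noise. Four deformity kinds are defined, each
scaled continuously by `severity` in [0, 1] and applied to one mound:

| kind             | geometric effect                                     |
|------------------|------------------------------------------------------|
| `contracture`    | shrinks the mound and pulls it posteriorly           |
| `missing_mound`  | shrinks it to nothing at severity 1                  |
| `asymmetry`      | translates it cranially, mild rescale                |
| `expander_bulge` | mildly over-inflates it and ripples its surface      |

The kinds are geometric idealizations designed so that image deviation is
monotone in severity (making score-versus-severity monotonicity testable);
they are not anatomical models of clinical complications. The expander
signature deserves a note: because depth renders are min–max normalized per
image, a deformity that simply protrudes further anteriorly *reduces* the
contrast of everything else in the frame and can look *more* ordinary to a
reconstruction-based score. Rippling — the classic surface signature of a
tissue expander — adds high-frequency structure instead, which scores
monotonically like the other kinds. `severity = 0`
reproduces the normal phantom bit-exactly for every kind, which anchors the
severity scale. Per-image geometry jitter (mound radius ±8%, separation
±5%) emulates normal anatomical variability. A single integer seed governs
the whole dataset; image *i* uses a seed derived as
`(seed * 100003 + 7919 i) mod (2^31 - 1)`.

What the phantoms deliberately do **not** emulate: photorealistic anatomy,
CT noise texture and artifacts, posture differences between visits, and
registration error. Passing the discrimination tests therefore shows the
pipeline is wired correctly and sensitive to shape deviation of the intended
kind — not that the published clinical effect sizes transfer to real CT.

# The longitudinal model

Each patient contributes one (standardized) AS per visit at days 0,
roughly 340–510, and roughly 740–950 after baseline. The analysis layer
provides:

* `paired_t_test()` — classical paired t comparisons between visits, overall
  and stratified by complication and reconstruction type. Zero-variance
  differences are reported as degenerate rather than silently producing
  infinite statistics. P-values are unadjusted (an optional Bonferroni
  column is trivial to add downstream), matching how such pairwise visit
  comparisons are conventionally reported.
* `classify_trajectory()` — the four canonical trajectory patterns
  (decreasing, increasing, increase–decrease, decrease–increase) from the
  signs of the two consecutive changes. A tolerance is needed to make "no
  change" well defined; the default is 0.1 z-units and a fifth `flat` class
  absorbs doubly-flat trajectories. One flat leg inherits the other leg's
  direction, making the classifier exhaustive and mutually exclusive.
* `fit_lme()` — a random-intercept linear mixed model (via `lme4`), response
  AS, random effect patient, fixed effects: days after baseline,
  reconstruction type (+ interaction with days), fractionation
  (+ interaction), mastectomy type, supraclavicular and internal-mammary
  irradiation, boost, plan, major complication, age (centred at 50 years)
  and BMI category. "Days after RT" and "days after baseline" are treated
  as one time variable (days since the pre-RT scan). Estimation is maximum
  likelihood rather than REML so nested-model contrasts remain coherent;
  intervals and p-values are Wald (normal approximation) with no
  small-sample degrees-of-freedom correction. Convergence and singularity
  are reported honestly in the fit object; rank-deficient designs are
  rejected naming the collinear columns.
* `predict_contrasts()` — the model-implied between-group difference
  $\beta_{main} + d\,\beta_{interaction}$ over a day grid (default 0, 180,
  360, 540, 720), with delta-method intervals from the fixed-effect
  covariance.

## The cohort generator and parameter recovery

`generate_cohort()` simulates from exactly this model:
$AS_{ij} = \beta_0 + \sum_k \beta_k x_{ijk} + b_i + \varepsilon_{ij}$ with
$b_i \sim N(0, \sigma_b^2)$ and $\varepsilon \sim N(0, \sigma_e^2)$. Default
binary covariate marginals follow the reported cohort composition (expander
0.23, hypofractionation 0.131, nipple-/skin-sparing mastectomy 0.36, boost
0.197, IMRT 0.213, major complication 0.164, BMI > 23 0.475); the nodal
irradiation covariates are not tabulated in the source cohort and default
to 0.5. Visit days are uniform over the reported interquartile ranges
(1-year scan: 343–512 days; 2-year scan: 741–951 days) — only medians and
IQRs are published, so a uniform-over-IQR sampler is the least-committal
choice. Age is uniform over 30–70 years and centred at 50 in both the
generator and the model, so the age coefficient has the same meaning in
both.

`run_recovery()` is the calibration experiment: 20 replicate cohorts of 200
patients are generated with truth days = 0.004, expander = 2.223,
age = 0.073 (all other coefficients zero; random-intercept SD 1.5, residual
SD 1.0), the model is refit on each, and replicate means, Monte-Carlo
standard errors and CI coverage are reported. `scripts/acceptance.R` runs
exactly this experiment.

# Problem sizes used by the tests

The test suite trains at two deliberately small scales chosen as the
package's own demonstration sizes: a shared 32 × 32 model (56 training
normals, 300 generator and 300 encoder steps, latent 8) for scoring-layer
properties, and a 64 × 64 discrimination study (230 training normals, 30
held-out normals, 30 severity-1 anomalies, 2000 generator steps, latent 32,
hidden widths 96/48, batch 16) for the end-to-end separation claim, which is
assessed with a one-sided Mann–Whitney test. Mixed-model properties use
cohorts of 60–200 patients and 8–20 replicates. These sizes give stable,
seeded results while keeping a full run in the minutes range.

# Known limitations

* The dense architecture does not exploit translational structure; at
  256 × 256 a convolutional backbone would be preferable. The module
  contract (training, logging, scoring) is architecture-agnostic.
* Min–max depth normalization discards absolute depth scale per image.
* The anomaly kinds are stylized; real post-surgical change includes skin
  texture and scar features no depth map captures.
* Wald inference is anti-conservative in very small cohorts; with ~60
  patients the intervals are adequate but not exact.
* The score reference uses the training normals by default; a held-out
  reference removes the mild optimism in the reference SD at the cost of
  data.
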