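---
title: "Modeling the neural code for 3D shape: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the neural code for 3D shape: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`shapecode` models how visual-dominant neurons in the anterior
intraparietal area (AIP), which drive hand pre-shaping for grasping,
could derive their 3D-shape tuning from the depth-gradient and curvature
signals carried by the caudal intraparietal area (CIP). The package
compares two candidate shape parameterizations as the basis of AIP
tuning — superquadric parameters, the robotics standard for compact
graspable-shape description, and a data-driven Isomap embedding of
depth-derivative features — and asks which can be (a) fit to
AIP-like tuning curves by cosine-tuned spiking neuron models and
(b) approximated by feedforward networks from CIP-like input.

This vignette documents the model components, the tunable parameters and
their defaults, what the synthetic data emulate, and the numerical and
design choices made where the design was genuinely open.

## 1. Shapes: superquadrics and their canonical parameters

A superquadric is described by nine free parameters: semi-axis scales
$A_{1..3}$ (meters), shape exponents $\epsilon_{1..3}$ (dimensionless),
and rotation angles $\theta_{1..3}$ (radians). The surface is the level
set $F = 1$ of

$$F(x, y, z) = \left(\frac{|x|}{A_1}\right)^{2/\epsilon_1} +
\left(\frac{|y|}{A_2}\right)^{2/\epsilon_2} +
\left(\frac{|z|}{A_3}\right)^{2/\epsilon_3}.$$

Exponents near 0 give squared edges, 1 gives rounded edges; a sphere has
equal scales and unit exponents. We use the standard form with absolute
values and exponents $2/\epsilon$: this is the unique convention that is
both well-defined for fractional exponents and reproduces the stated
special cases (a sphere at $\epsilon = 1$). Rotation uses an explicit
Euler-style matrix (`rotation_matrix()`); a world point $p$ maps into
the object frame as $R\,(p - c)$.

**Canonicalization.** Several parameter vectors describe the same
surface (every superquadric is symmetric under half-turns about its own
axes; boxes additionally under axis relabelings; cylinders under spin
about the long axis; spheres under all rotations). For the
depth-to-parameter mapping to be learnable, the parameterization must be
injective, so `canonicalize()` reduces each class to a unique
representative: box-like shapes are relabeled through the 24-element
cube rotation group to the candidate with the smallest maximum absolute
angle (angles end up in roughly $\pm\pi/4$), cylinder-like shapes get a
hemisphere-reduced axis with $\theta_3 = 0$, and sphere-like shapes get
zero angles. The mapping is idempotent and preserves rendered depth maps
to well below the renderer tolerance. One consequence adopted
deliberately: *sphere-like* database entries use exactly equal semi-axes
— the canonicalization contract (all rotations of a sphere are the same
stimulus) only holds exactly for true spheres; near-spheres with
unequal axes would be weakly orientation-dependent and belong in the
box-like class.

**The shape database** (`sample_database()`) emulates a graspable-object
ensemble: box-like, sphere-like and cylinder-like shapes in equal
proportions; semi-axes uniform on $[0.01, 0.06]$ m so widths span
0.02–0.12 m; squared edges drawn from the shifted exponential
$p(\epsilon) = 10\,H(\epsilon - 0.01)\,e^{-(\epsilon - 0.01)/0.1}$
(mean 0.11; the shift avoids numerically degenerate corners); round
edges fixed at $\epsilon = 1$. Rotations are sampled uniformly per angle
over each class's canonical range — uniformity over SO(3) is not
required, only arbitrary (non-redundant) rotations. The database splits
70/30 into train/validation.

## 2. Stimuli: the 36 augmented tuning-curve shapes

Published AIP shape-tuning curves cover fewer stimuli than even a
minimal cosine-tuning model has parameters. The augmented design
extends four base shapes (sphere, cube, plate, cylinder) across four
sizes (uniform scalings $3/6 \ldots 6/6$ of the reference dimensions)
and four orientations (horizontal, vertical, tilted forward 45°, tilted
backward 45°). Rotational symmetry makes some orientations the same
stimulus: all four for the sphere (1 kept), horizontal–vertical and the
two tilts for the cube (2 kept), and the two tilts for plate and
cylinder (3 kept each). That yields $9 \times 4 = 36$ distinct stimuli.

The duplicate ruleset is verified by rendering
(`verify_stimulus_symmetries()`). For the plate and cylinder the two
tilts are congruent via a half-turn about the viewing axis rather than
pointwise-identical views, so duplicate detection compares depth maps
under the dihedral grid symmetries {identity, left–right flip, up–down
flip, half-turn} — the group under which the stimulus ensemble treats
mirror presentations as the same object. Kept stimuli are confirmed to
stay distinct under the same comparison (closest pair differs by
~1.4 cm in depth, versus < 1 µm residuals for true duplicates).

## 3. Rendering: observer-centered depth maps

Depth maps are grids of Euclidean distances from a viewpoint at the
origin to the object surface, along rays parameterized by visual angle.
The grid covers ±10° with 16 points per axis, warped so that spacing is
finer near the center (`angle = sign(a) |a|^{1.5} \cdot 10°` for evenly
spaced $a \in [-1, 1]$), mimicking foveal acuity and guaranteeing that
the smallest shapes intersect a few rays. Objects sit at the fixation
distance 0.75 m. Intersections are found by a 512-step coarse march
over ray distances 0.6–0.95 m followed by bisection to $10^{-6}$ m;
sphere renders agree with the closed-form ray–sphere solution to that
tolerance at every grid point.

**Rays that miss.** The default fill for missed rays is the distance
along the ray at its *closest approach* to the object surface
(parabolically refined arg-min of $F$; exact for spheres, whose $F$ is
quadratic along a ray). This extension is continuous at silhouettes: as
a shape grows through tangency with a ray, the fill converges to the
grazing depth. Continuity matters because the whole Isomap premise is
that similar shapes have similar depth-derivative features; with a fixed
background fill (also available, `fill = "plane"`, background plane at
0.9 m) a pixel jumps ~0.15 m the moment a shape first crosses its ray,
which fragments 1-parameter shape families into feature-space plateaus
and can even disconnect the neighborhood graph. The plane fill is
retained for figure/ground experiments; all shipped analyses use the
continuous fill.

## 4. CIP-like features

Each depth map yields five channels: depth and its horizontal and
vertical first and second derivatives, approximated by correlating with
separable 3×3 kernels $[1\,1\,1]^T[1\,0\,-1]$ and
$[1\,1\,1]^T[0.5\,-1\,0.5]$ (and transposes), replicate-padded, in
grid-index space (the warped angular metric is deliberately not undone —
the kernels model fixed receptive-field structure, not calibrated
differential operators). Flattened in fixed channel order this gives
$16 \times 16 \times 5 = 1280$ network inputs; the Isomap uses the four
derivative channels (1024 values).

Curvature utilities implement the curved-surface stimulus family
$z = (K_1 x^2 + K_2 y^2)/2$, the principal-curvature formula
$K_x = z_{xx} / (1 + z_x^2)^{3/2}$ (so $K_x = K_1$ at the stimulus
center), curvedness $C = \sqrt{(K_{max}^2 + K_{min}^2)/2}$ and shape
index $SI = (2/\pi)\arctan\!\big((K_{max}+K_{min})/(K_{max}-K_{min})\big)$
with the symmetric-cap limit $SI = \pm 1$. `legendre_expand()` adds the
quadratic tuning variables $(3X^2 - 1)/2$ in the second derivatives —
the nonlinearities best reconstructed linearly from LIF populations
tuned to $X$ — and `v3a_channels()` provides a 7-channel pointwise
disparity-tuning front end (five Gaussians at 0.65–0.85 m, SD 0.05 m;
complementary near/far sigmoids at 0.75 m, slope 25 /m). The Gaussian
centers and widths are exposed as arguments; no physiological values
are published for them, so the defaults just tile the working depth
range around fixation.

## 5. Neuron models

**Cosine-tuned LIF.** Drive $I = \tilde\phi^T x + b$; normalized LIF
rate $r = 1/(\tau_{ref} - \tau_{RC}\ln(1 - 1/I))$ for $I > 1$, else 0
(the closed form is undefined at threshold; zero is the standard
convention). $\tau_{ref} = 5$ ms; fitted $\tau_{RC} \in [0.02, 0.2]$ s.

**Noisy variant.** Gaussian background current noise smooths the rate
function from compressive through sigmoidal toward nearly linear.
Rates come from a simulated lookup table over $(I, \sigma)$
(Euler–Maruyama, $dt = 10^{-4}$ s, 5 s per cell, seeded; bilinear
interpolation). The noise is white with amplitude scaled to the
membrane time constant (per-step increment
$\sigma\sqrt{2\,dt/\tau_{RC}}$, stationary subthreshold SD $\sigma$):
a per-step current perturbation of fixed SD would vanish from the
voltage as $dt \to 0$ and could never smooth the threshold. At
$\sigma = 0$ the table matches the closed form within 2% over
$I \in [1.1, 3]$.

**Dendritic-branch model.** For tuning curves that defy cosine tuning,
a 50-branch model: each branch is cosine-tuned to a 3×3 depth patch
through a random standard-normal kernel and a logistic sigmoid; the
cell rate is a weighted branch sum fit by a truncated-SVD pseudoinverse
(typical ranks 14–40). "Point-wise product" of kernel and stimulus is
read as the summed elementwise product (a dot product) feeding the
sigmoid — the only reading under which branches are cosine-tuned to the
depths.

**Population decoding.** Linear decoders $\Phi$ are fit by
ridge-regularized least squares ($\lambda = 0.1 \times$ mean Gram
diagonal, the usual population-noise term), and cosine tuning over
decoded parameters composes into direct synaptic weights
$w^T = \tilde\phi^T \Phi$ — an exact identity, tested over 1000 random
instances.

## 6. Tuning curves: augmentation and fitting

`augment()` builds a 36-point curve from four per-shape base rates:
$r = \max\{0,\; b_0 + (r_{shape} - b_0)\, f_{size}\, f_{orient}\}$, with
$f_{size} = 1$ (size-invariant) or proportional to the size scale
reaching 1 at the largest size (size-monotone), and $f_{orient}$ a
Gaussian in pose angle (default SD 45°, "fairly narrow") with the
angular difference respecting each shape's symmetry period (cube 90°,
plate/cylinder 180°, sphere none). The multiplicative-with-baseline
combination is one consistent reading of how shape, size and
orientation selectivity interact; at reference size and preferred
orientation the base rates are reproduced exactly. Thirteen synthetic
archetype curves ship with the package (six neuron archetypes ×
size-selective/invariant, plus an orientation-selective curve equal for
plates and cylinders); their base rates are invented stand-ins shaped
by qualitative descriptions — no published rates are reproduced.

`fit_cosine_lif()` minimizes squared rate error by multistart bounded
Levenberg–Marquardt (`minpack.lm`): per restart, $\phi \sim N(0, s^2)$
with $s$ set from the current needed for the peak target rate,
$b \sim U(-2, 2)$, $\tau_{RC} \sim U(0.02, 0.2)$; 200 restarts by
default (raise for production fits). Orientation enters the stimulus
vector as the 2D direction $(\cos\psi, \sin\psi)$, avoiding angle
wrap-around; with three scales and three exponents the fitted preferred
direction is 8-dimensional. Noiseless planted neurons over the
36-stimulus set are recovered to rate-RMSE $< 10^{-3}$ spikes/s.
`levene_test()` implements the classical Levene W (one-way ANOVA on
absolute deviations from group means) for comparing fit-error variances
across parameterizations.

## 7. Isomap shape space

`isomap_fit()` builds a k-nearest-neighbor graph on Euclidean feature
distances (default $k = 10$; a disconnected graph is an error naming
component sizes, never silently repaired, so geodesics stay
interpretable), computes all-pairs Dijkstra geodesics, and embeds by
classical MDS (deterministic eigen-sign convention). Features enter in
native units (no standardization) by default. `residual_variance` is
the classic diagnostic $1 - R^2$ between geodesic and embedding
distances; it decreases with dimension on multi-dimensional manifolds,
though not by mathematical necessity (for an essentially 1-D family it
is already ~$10^{-5}$ at $d = 1$ and may fluctuate at that scale).
Out-of-sample shapes are embedded by a Nyström extension through the k
nearest training points; training points reproduce their coordinates
exactly, and queries far outside the training support are flagged.
Above 5000 points a landmark variant (2000 landmarks by default) avoids
the full geodesic matrix.

Two properties motivate the embedding and are tested: similar shapes
land nearby (a 1%-of-range parameter perturbation stays below the 5th
percentile of pairwise distances for ~90% of shapes — the exceptions
are sharp-edged shapes whose 16×16 renderings respond steeply to
sub-pixel pose changes), and the superquadric discontinuity disappears
(a tall box just below $+\pi/4$ and the equivalent wide box just above
$-\pi/4$ are neighbors in the embedding but far apart in canonical
parameters).

## 8. Feedforward mapping and the headline comparison

`train_mlp()` is a two-hidden-layer perceptron (default 1280–600–300–d;
logistic hidden, linear output — the output models the drive to
downstream cosine-tuned neurons) trained by backpropagation with
adaptive-moment mini-batch gradient descent (batch 64, lr $10^{-3}$,
optional decay), early stopping on a held-out tenth of the training
data, deterministic given a seed. Inputs and targets are z-scored
internally with training statistics (undone at prediction), mirroring
the input/output normalization of standard neural-network toolboxes;
raw modes are available. `train_nef_population()` is the spiking
alternative: cosine-LIF hidden units with random preferred directions
over local patches and ridge-decoded outputs; it needs more units than
the fully optimized perceptron for comparable error, and its decode
error decreases with population size.

**Study conditions.** The full-scale experiment (40 000 shapes,
28 000/12 000) is supported but deliberately not the default. The
shipped analyses use sizes chosen once for a single-workstation run:

* desk-scale mapping run: 4000 shapes (2800/1200), exact Isomap,
  $d = 8$, $k = 10$, MLP 1280–600–300–8, up to 60 epochs with
  patience 10. The trained network's median per-shape validation error
  is ~13% of the median pairwise Isomap distance (the figure-of-merit
  threshold is 20%).
* headline contrast: a 1200-shape subset (840/360) of the same
  pipeline, three seeds, identical architecture and schedule (30
  epochs, patience 8) for both target spaces. Across all seeds the
  normalized validation error (mean Euclidean error ÷ RMS norm of
  centered targets) for Isomap targets (~0.31) is well below that for
  canonical superquadric targets (~0.64), and superquadric angle errors
  concentrate near the $\pm\pi/4$ canonical boundaries — the
  discontinuity signature.

Superquadric targets use canonicalized parameters; the three angles can
be target-encoded either raw or as 2D direction vectors
(`db_parameters(angle_encoding = "direction")`).

## 9. What the synthetic data do and do not show

All inputs are self-generated: the shape database, the 36-stimulus
augmented curves, and the curved-surface stimuli. The generator
emulates the *structure* of the modeled experiments (shape classes and
their proportions, size ranges, symmetry-deduplicated stimulus designs,
qualitative selectivity profiles), not recorded spike rates — published
tuning-curve values from figures are not reproduced, so fitting
machinery is exercised on synthetic curves only. Consequently, passing
tests show that the pipeline behaves as specified on idealized,
noise-free, single-object scenes with disparity-equivalent depth input;
they do not show that real AIP neurons are cosine-tuned to an Isomap,
nor that the specific augmented assumptions (monotone size scaling,
Gaussian orientation tuning, multiplicative combination) hold
physiologically. Texture, perspective and occlusion cues, binocular
geometry, response dynamics, and motor-dominant neurons are all out of
scope.

## 10. Numerical notes and limitations

* Ray marching can miss grazing intersections thinner than the 0.7 mm
  march step; silhouette-adjacent pixels are the least accurate part of
  any render.
* Box canonicalization picks the minimum-max-angle relabeling with a
  deterministic lexicographic tie-break; exactly symmetric shapes
  (equal scales and exponents) have genuinely tied representatives and
  resolve by that tie-break.
* The exact Isomap keeps the full geodesic matrix in the fitted object
  (needed for out-of-sample extension); at 5000 training shapes this is
  ~200 MB. The landmark variant trades that for an approximation.
* `fit_cosine_lif()` error surfaces are flat wherever all stimuli are
  subthreshold; multistart handles this, but curves with many zero
  rates fit slowly.
* The LIF population alternative uses 95th-percentile drive
  normalization per neuron; with very few training samples the radius
  estimate is noisy.
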