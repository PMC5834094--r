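---
title: "Dot mapping: model, numerical choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dot mapping: model, numerical choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotmapr)
```

## The problem

Catheter ablation procedures routinely produce several scalar datasets on
one cardiac chamber geometry: bipolar electrogram voltage and local
activation time from the electroanatomic mapping system, and late gadolinium
enhancement intensity from pre-procedural MRI registered onto the same
shell. Colour shading can display exactly one of these at a time; switching
back and forth forces the operator to integrate maps from memory. Dot
mapping displays a second dataset as a stipple layer whose local density is
proportional to the data value, over (or inside, for tetrahedral volumes)
the colour-shaded mesh.

## The model

Let an element (triangle or tetrahedron) have measure $V$ (mm² or mm³) and
normalized scalar $S \in [0,1]$. With $D$ the viewpoint–centroid distance
frozen at scene start and $D'$ the current distance, the element weight is

$$\lambda = V \, S \, \frac{D^2}{D'^2}, \qquad
  \lambda_{\mathrm{adj}} = b\,\lambda^{c},$$

and the realized dot count is $x = \min(X, N)$ with
$X \sim \mathrm{Poisson}(\lambda_{\mathrm{adj}})$ and cap
$N = \lceil q V \rceil$. Each dot is placed uniformly at random inside its
element. Under the package's scaled-orthographic camera (screen scale
$\propto D/D'$) the projected area of any surface patch scales as
$1/D'^2$, exactly cancelling the $D^2/D'^2$ factor: expected dots per unit
*screen* area is independent of zoom. This is the property the
`density_sweep()` acceptance tests verify empirically.

Per-vertex data are converted to per-element data by averaging the
element's vertex values, the usual convention for electroanatomic shells
whose measurements live on map points.

### Two deliberate corrections

Two formulas are implemented in their standard (normalized/uniform) form
rather than in a literally transcribable one:

* **Poisson pmf.** The count distribution is the standard
  $\lambda^k e^{-\lambda}/k!$; the weight is the distribution's mean *and*
  variance, which pins it down uniquely.
* **Triangle placement.** The parametrization
  $P=(1-s)A + s(1-r_2)B + s\,r_2 C$ is applied with $s=\sqrt{r_1}$. Without
  the square root the map from the unit square piles density up near vertex
  $A$ (its Jacobian is proportional to $s$); with it the placement is
  exactly uniform, which is what "density proportional to the dataset
  value" requires and what the sampler tests check against a rejection
  oracle. The tetrahedral two-stage folding of three uniform variates is
  uniform as specified and is implemented literally, including evaluating
  its branch conditions with `<=` (the boundaries have measure zero, but
  keeping them as stated makes single-point hand traces exact).

### Normalization

The weight requires $S \ge 0$, but clinical fields arrive in mV or
arbitrary signal intensity. Every field therefore carries a window
$(\mathrm{lo}, \mathrm{hi})$ and is clipped-then-scaled onto $[0,1]$ before
weighting — mirroring how voltage maps are windowed in practice (e.g. an
atrial 0.05–0.5 mV scar window). Constant fields get an anchored default
window (a constant-1 field keeps $S = 1$) so uniform test fields behave as
expected.

## Parameters that matter

| Parameter | Units | Default | Role |
|---|---|---|---|
| `b` (brightness) | dimensionless | 1 | scales all weights; calibrate as `dots_wanted / sum(V*S)` |
| `c` (contrast) | dimensionless | 1 | bends the density response; $c>1$ suppresses low values |
| `q` (cap) | dots / mm² or mm³ | `Inf` | bounds per-element dots at $\lceil qV\rceil$; finite values trade close-zoom fidelity for speed |
| `offset` | mesh units | 0.5 | lift of surface dots along the outward normal; also the renderer's depth bias |
| `seed` | integer | 1 | every cloud is a pure function of (mesh, field, view, config, frame) |

The cap uses a ceiling so that no positive-measure element is structurally
barred from receiving a dot, and capping truncates the realized draw
(`min(x, N)`) rather than resampling. $D$ and $D'$ are global scalars
(viewpoint to model centroid), not per-element distances: with an
orthographic projection this keeps density uniform across the model, which
is the behaviour the flat density-vs-distance curves describe. Dots are
fully regenerated whenever the view changes; each regeneration uses a
substream keyed on `(seed, frame)`, so animation frames are individually
reproducible. Dot persistence across frames is an explicit non-goal.

## Rendering

The renderer is a deliberately small software rasterizer: orthographic
projection, per-triangle z-buffer fill (flat per-element colour or Gouraud
per-vertex interpolation through a 256-entry palette LUT), then dot splats
depth-tested against the surface with a bias equal to the dot offset so a
lifted dot layer never loses to the surface it hovers over. Output goes
through `png::writePNG`, which is byte-deterministic — the determinism
regression tests compare files byte-for-byte, something a graphics device
with metadata or antialiasing could not promise. Perspective projection is
not offered: under perspective the density-invariance law would hold only
approximately (per-element depth varies), and the clean orthographic law is
the property worth testing.

## Synthetic data: what it emulates, what it does not

No clinical meshes are redistributable, so `fixtures` regenerates the
shapes the method is exercised on:

* `make_disc_gradient()` — the 2 cm gradient-direction perception task:
  a planar disc with a linear ramp at angle $\theta$.
* `make_square_scar()` — the 2 cm focal-source task: a raised-cosine bump
  (peak 1, zero beyond its radius).
* `make_shell_pair()` — nested endo/epi icospheres with plateau-plus-patch
  bipolar "voltage" (4 mV plateau, 0.2 mV patch floor, smooth 10° edge);
  `overlap` rotates the epicardial patch from coincident (1) to antipodal
  (0).
* `make_lv_wedge()` — a curved tetrahedralized wall slab (Kuhn 6-tet hex
  subdivision) with an LGE-like field enhanced in the subendocardial
  fraction of wall thickness given by `scar_transmurality` (default
  emulating a 75% subendocardial scar) plus Gaussian noise.
* `make_activation_voltage_pair()` — activation time as geodesic distance
  from a source vertex at fixed conduction velocity, wrapped over a cycle
  length, with an independent patchy voltage field.

The original perception test sets (n = 10 per task) are emulated as
parameter sweeps — 10 random gradient axes, 10 random scar centres — since
the originals are not deposited and their exact scalar profiles are not
printed; the linear ramp and radial bump are this package's assumed shapes.
These fixtures are idealized: no fractionated signals, no registration
error, no mesh slivers, no anisotropic conduction. A green test therefore
establishes that the *algorithm* behaves as claimed on well-posed inputs,
not that any clinical pipeline upstream of it is sound.

## The perception bench measures code, not people

The published evaluation of this display technique reports accuracies of
*human observers* reading the maps. Those numbers are not reproducible
computationally and are not acceptance targets here. Instead the bench asks
the weaker, checkable question: is the information present in the stipple
pattern recoverable at all?

* `estimate_gradient_axis()` bins dots on a grid, keeps the bins that lie
  fully inside the disc (a point-symmetric set, so a linear least-squares
  fit of count on position is unbiased for a linear intensity), and returns
  the slope direction. Clouds whose fitted trend is within two standard
  errors of flat are flagged `no-gradient`.
* `estimate_focal_source()` returns the `MASS::kde2d` density peak
  (normal-reference bandwidth, 65-point grid). Nearly flat patterns are
  flagged `low-confidence`.

At a 10⁴-dot budget the bench achieves a mean absolute error around 1–2°
(gradient direction) and under 0.05 cm (source location) over ten seeded
trials. Directional errors are folded into $[0,180]$ because the generated
ramps are directed; an axis-only task would fold at 90°. One numerical
subtlety: the focal estimator's error reaches a bias floor (KDE grid
spacing ≈ 0.03 cm plus bandwidth smoothing) by roughly 10³ dots, so mean
errors across budgets can wiggle within sampling noise around that floor;
the budget-consistency check accordingly requires that no step *worsen*
beyond twice its paired standard error and that the 10²→10⁴ decrease be
strict, rather than strict monotonicity of raw sample means.

## Numerical and design choices

* **Indices.** In-memory objects use R's native 1-based indexing; every
  file format (VTK/PLY/OFF cells, sidecar CSV, dot-cloud exports) uses the
  formats' 0-based convention.
* **I/O precision.** Coordinates and field values are written with
  `%.17g`, which round-trips IEEE doubles exactly; a write→read→write cycle
  is byte-identical, and files are written over binary connections so line
  endings are LF on every platform.
* **Degenerate elements** (zero area/volume) are kept, receive
  $\lambda = 0$, and never emit dots — clinical meshes contain slivers and
  silently dropping them would change totals. Mixed triangle/tet files are
  rejected: the two pipeline variants are distinct.
* **Exactness of the weight law.** $\lambda$ is computed as
  $V\,S\,(D/D')^2$; when $D' = D/2$ the ratio is exactly 2 in floating
  point, so quadrupling holds bit-exactly, and the tests assert it with
  `identical()`, not a tolerance.
* **RNG.** A single Mersenne-Twister stream per cloud, seeded explicitly;
  counts are drawn before placements and placement variates are consumed in
  element order (two per surface dot, three per volumetric dot). Bit-level
  agreement with the original MATLAB implementation is not attempted — no
  RNG policy for it was ever specified.
* **Units.** The 2D perception geometries are in cm (they are specified in
  cm); anatomical fixtures are in mm. Coordinates are otherwise
  unit-agnostic: only `q` and `offset` carry the mesh's unit.

## Known limitations

Rendering is CPU-side and unlit, intended for reproducible figures and
automated measurement rather than interactive use. The activation fixture
propagates over the edge graph, so its isochrones carry the mesh metric's
discretization error. The gradient estimator assumes a linear intensity;
on strongly curved fields it reports the best linear direction. Volumetric
renders draw dots only (no silhouette of the enclosing volume). None of
the package's accuracy figures say anything about human readers.
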