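---
title: "Image statistics across the visual field of a spherical model retina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image statistics across the visual field of a spherical model retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinastats)
```

# The question

Classical natural-image ensembles are photographs: planar sensor, narrow
field of view, human-selected content. The stimulus that reaches a
visual system differs in three ways that `retinastats` makes explicit
and manipulable:

1. **geometry** — light lands on a (roughly) spherical retina, not a
   plane, and statistics are measured far into the periphery;
2. **viewpoint** — a human at 1.8 m and a cat at 0.25 m sample very
   different distributions of surfaces;
3. **behavior** — gaze follows locomotion, so the statistics at a
   retinal location depend on how the observer looks around.

The package simulates all three: procedural 3D scenes, a walking avatar
with a thin-lens eye model, active-gaze strategies, patch-wise wide-field
imaging, projection onto the spherical retina via tangent-plane
homographies, and spectral plus edge-orientation statistics per
visual-field position.

# Imaging geometry

The eye is a sphere of radius $r$ centered at $c = (0, 0, -r)$ in camera
coordinates, focused at infinity, so the focal length is $f = 2r$. The
human preset uses $f = 16.67$ mm (reduced schematic eye), the cat
$f = 12.5$ mm. A visual-field position is an eccentricity $\varphi$ (angle
from the gaze axis) and polar angle $\chi$ (counter-clockwise from the
image x axis, +y up). Its image on the projective plane $z = -2r$ and on
the sphere are

$$p = \big(2r\tan\varphi\cos\chi,\; 2r\tan\varphi\sin\chi,\; -2r\big),
\qquad
p' = \big(2r\sin\varphi\cos\varphi\cos\chi,\;
          2r\sin\varphi\cos\varphi\sin\chi,\; -2r\cos^2\varphi\big),$$

which lie on the same ray through the center of projection. Rendering is
an off-axis pinhole frustum: a patch at $(\varphi, \chi)$ is a square
window of the full frame centered on $p$, with the pixel pitch of a
notional full frame covering the field of view (120° over 5,954 px at
full scale, so that central resolution matches classical calibrated
image ensembles).

Planar image processing applies to the spherical image through a local
approximation: the tangent plane at $p'$, with its first in-plane axis
along the local radial direction. Both planes see the scene from the same
center, so centered pixel coordinates are related by a homography
$H \propto A^{-1}B$, normalized here to $H_{33} = 1$; `warp_to_tangent()`
resamples a planar capture into the tangent frame (bilinear taps,
optionally supersampled, since a tangent pixel integrates several source
pixels away from the center). `tangent_approx_error()` quantifies the
approximation by casting a ray through every pixel of the tangent patch
and measuring its distance to the sphere: 0.054 mm at
$\varphi = 30°$ and 0.074 mm at $\varphi = 50°$ for a 128-px human-eye
patch at the full-scale pitch. Pairing points along rays is the imaging
correspondence; a perpendicular (nearest-sphere-point) variant is
available and is strictly smaller.

Two conventions deserve note. Pixel grids are symmetric about the patch
center (centers at $\pm(n-1)/2$), which keeps FFTs, crops and warps
mutually aligned; the asymmetric 0-based alternative changes the
approximation-error figures only in the fourth decimal. And the tangent
frame is radial-aligned, so orientations measured on tangent patches are
expressed relative to the local radial direction — rotation-invariant
quantities ($A$, $b$, $\beta$, $\kappa$) compare directly across
projections, orientations do so after adding $\chi$.

# The synthetic environment

No scene assets are shipped; everything is generated procedurally from a
seed.

* **Forest** (`build_forest_scene()`): vertical cylinders (trunks) from a
  Poisson process (0.15 m⁻², radii 0.12–0.4 m), a ground plane with
  track-like striping toward a vanishing point plus perpendicular grass
  strokes, sparse fallen branches, and a canopy-textured background
  dome. All albedo textures are Fourier-synthesized periodic power-law
  noise tiles (`powerlaw_field()`), slope 1.6, with amplitudes and
  banding calibrated once so that rendered central-field ensembles show
  the natural $1/f^{\alpha}$ radial spectrum with $\alpha \approx 2$
  (measured 2.2 for straight gaze, 1.9 for ground-dominated views at the
  test profile). An earlier hash-based fractal value noise proved
  intrinsically too steep ($\alpha \approx 3$) and was replaced by the
  spectrally exact tiles.
* **Random-edge control** (`build_random_edge_scene()`): line segments
  with i.i.d. uniform 3D orientations suspended around the viewing
  region, mid-gray background, no ground. Segment radii (5–12 cm) are
  chosen so projected widths resolve at the 64-px test profile. Since
  the scene is isotropic by construction, any orientation anisotropy in
  its projections is a property of the projection.
* **Trajectory** (`generate_trajectory()`): a correlated random walk —
  heading increments Gaussian (SD 15°/step), speed 1.4 m/s (a typical
  human walking pace; the source trajectory's speed is not documented),
  one pose every 2 s, eye height fixed by the species, confined to the
  scene's extent by steering back toward the center. The full-scale
  condition records 663 poses; the walk is a stand-in and makes no claim
  to match any particular recorded path's statistics.
* **Gaze** (`gaze_spec()`): *straight* (heading, elevation 0), *down*
  (elevation −30°), *random* (independent Gaussian heading/elevation
  offsets, SD 1 rad = 57.30°). Random draws are reproducible through the
  gaze seed.

Everything — scenes, trajectories, gaze, renders — is bit-reproducible
given seeds; textures are hash- or tile-based with no hidden RNG state in
the renderer.

# Statistics

**Spectra.** Patches are converted to the CIE luminance channel (sRGB/D65
primaries; the rendering primaries are not otherwise specified), divided
by their mean, weighted by a radially symmetric Hamming window
($w = 0.54 + 0.46\cos(\pi\rho/\rho_{max})$, endpoint 0.08), and
transformed; squared magnitudes are averaged over the ensemble. The
stored spectrum is scaled so total power equals windowed-contrast energy
(Parseval). The radial profile's log–log slope $-\alpha$ is fit over
0.05–0.4 cycles/px on the raw annulus cells — fitting on radially binned
means instead biases a pure power law by about 0.005, which matters when
the slope itself is the target. The oriented elliptical power law
$\Gamma = A(u_r^2 + v_r^2/b)^{-\beta}$ is fit in the log domain below
0.45 cycles/px (avoiding the square grid's corner anisotropy) within the
bounds $10^{-3} < A < 1$, $10^{-3} < b \le 1$, $0.5 < \beta < 2$,
$0 < \theta < \pi$, multi-started over four orientations. Three choices
here were genuinely open:

* the placement of $b$ is typographically ambiguous in its source; the
  form $v_r^2/b$ is adopted (so $b < 1$ strengthens the bias) with the
  multiplicative alternative available as `b_form = "multiply"`;
* $\theta$ is reported as the *image orientation* of the bias. The
  spectral energy of an edge lies perpendicular to it, so the ellipse's
  long frequency-space axis sits at $\theta + 90°$ internally. This
  makes $\theta$ directly comparable to the edge-histogram mode $\mu$
  (a vertical-trunk ensemble fits $\theta \approx \mu \approx 90°$) and
  gives the radial bias its natural positive $\theta$-vs-$\chi$ sign;
* model frequencies are in cycles per patch, and the fitted spectrum is
  normalized by the window's squared mass (the DC-gain-normalized
  periodogram), which is what places natural-ensemble amplitudes inside
  the $A$ bounds; amplitudes are therefore comparable within this
  convention only.

When $b \ge 0.98$ the orientation is unidentifiable and the fit carries
an `isotropic` flag instead of a meaningful $\theta$. A flat (white)
spectrum is outside the model family: the fit rides its $\beta$ bound
with weakly constrained $b$, which is why pipeline checks on white noise
assert $\alpha \approx 0$ rather than the isotropy flag.

**Edges.** Gradients use the matched 5-tap prefilter/derivative pair
(rotation-invariant by design; gradient energy of a rotated grating
agrees within a fraction of a percent). The orientation tensor is the
5×5 Gaussian-weighted ($\sigma = 1.2$ px) average of the gradient outer
product — the smallest window that gave stable orientedness on gratings.
Edge pixels must exceed the per-image 68th energy percentile (computed
over valid, border-excluded pixels; strict inequality) and orientedness
0.8. On pure pixel noise this tensor still shows median orientedness
near 0.4 and a mild cardinal bias ($\kappa_2 \sim 0.3$) from the square
lattice — worth remembering when interpreting small concentrations.
Histograms use 36 bins of 5°. Von Mises fits double the angles, estimate
$(\mu, \kappa)$ by maximum likelihood (Newton-refined Bessel-ratio
inversion, $\kappa$ capped at 500 for degenerate inputs), and report both
the doubled-space estimates and the halved values — halving $\kappa$ as
well as $\mu$ is unusual but kept as the reporting convention for
comparability. The two-component mixture EM initializes at the two
strongest well-separated histogram modes, stops at a log-likelihood gain
below $10^{-6}$ or 500 iterations, and degrades to a single component
(with a warning) if a weight collapses below $10^{-3}$ *or* the two modes
coincide within 1° — the latter is how single-mode data actually fail.

**Circular inference.** The circular–circular correlation uses the
classical mean-direction form, switching to the uniform-marginal
correction (choosing means to extremize the coefficient) when either
marginal's resultant falls below 0.05 — the polar angles of a
visual-field ring are exactly uniform, where the classical form returns
an arbitrary value. Radial-bias correlations double *both* variables:
orientation has period 180°, and the radial direction at $\chi$ and
$\chi + 180°$ is the same orientation (with single-period $\chi$ the two
harmonics are orthogonal and the correlation is zero by construction).
P-values come from seeded permutations. The Watson–Williams F test
carries the standard $(1 + 3/8\kappa)$ correction and flags low
concentration ($\bar R < 0.45$); its type-I rate calibrates to 3–7% at
nominal 5% in simulation. The two-sample Kuiper statistic
$V = D^+ + D^-$ is rotation invariant; its asymptotic tail series is
valid only away from zero, so $p = 1$ is returned below $\lambda = 0.4$.

# Scaled-down study profiles

The full-scale conditions (5,954-px frame, 512-px captures, 128-px
analysis patches, 17 grid positions, 663 poses) are the `run_config()`
defaults. The test suite exercises the same pipeline at desk scale:
64-px patches, 512-px frames, 40–72 poses, 800 segments — sizes chosen
so each property is measured on a few hundred to a thousand rendered
patches. Two profile details matter:

* at a 512-px frame a 64-px *tangent* patch at $\varphi = 50°$ subtends
  roughly 39° of visual angle (the tangent plane sits closer to the
  center of projection than the projective plane), far from the
  full-scale geometry; the planar-versus-spherical comparison therefore
  runs at a 2,048-px frame, where patch extents are production-like;
* that comparison also uses eccentricity rings $\{30°, 40°, 50°\}$ — the
  finer-eccentricity layout on which the upper-versus-lower field
  divergence of $A$ and $\beta$ is an established readout — giving nine
  mirrored position pairs for the sign test.

What passes at desk scale supports the *directions* of the effects
(radial bias positive and growing with eccentricity, central cardinal
bias, strategy contrasts, asymmetry damped by the spherical projection),
not any particular full-scale effect size; exact correlations and
t-statistics depend on the scene ensemble and are not reproduced here.

# What the generator does and does not emulate

The forest emulates the statistical skeleton of a wooded environment:
dominant vertical structure, a textured ground with oriented track
features, near-1/f² albedo and clutter at several scales. It does not
attempt photorealism — no shadows, global illumination, leaves-as-geometry,
occlusion-graded depth of field, or optical blur (modulation-transfer
functions are deliberately out of scope, also because eccentricity-
dependent measurements do not exist for the cat). Trunks are perfectly
straight cylinders, which makes long vertical edges — and hence the
cardinal bias — somewhat cleaner than in real forests. Passing tests
therefore show that the *pipeline* measures what it should measure on
scenes with known structure; they do not certify effect sizes for any
natural environment.

# Known limitations

* Orientations on tangent patches are measured in the local radial frame
  (see above); cross-projection comparisons of $\theta$ or $\mu$ must
  add $\chi$ first, and the shipped projection comparison restricts
  itself to rotation-invariant parameters.
* The amplitude $A$ is convention-bound (window-mass-normalized
  periodogram, cycles/patch); compare within the package only.
* The thin capsule renderer pulls hits toward the viewer by the chord
  depth, an approximation that is visually and statistically adequate
  for thin clutter but not exact geometry.
* The walk model (speed, turning, arena confinement) is a plausible
  stand-in, not a fit to recorded locomotion.
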