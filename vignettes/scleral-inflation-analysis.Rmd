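---
title: "Thin-shell analysis of scleral inflation tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thin-shell analysis of scleral inflation tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In a whole-globe inflation test, an enucleated eye is glued to a fixture,
cannulated, and pressurized in steps from a reference pressure `P0` (the
lowest pressure at which the sclera is unwrinkled, typically 6–8 mmHg) up to
30 mmHg. A camera views the eye from above and an image-correlation system
tracks points along the scleral edge, so the raw data are ordered 2D point
coordinates per pressure step in a fixed camera frame `(e1, e2)`, with `e2`
the axis of revolution. The mechanical question is how much the scleral
shell stretches, and how much membrane force it carries, as pressure rises —
and whether those curves differ between cohorts (mutant vs wild type,
glaucomatous vs naive).

`sclerashell` implements that analysis as a reusable, testable pipeline,
together with the cohort metrics such studies report (sampled optic-nerve
axon counts, percent axon loss, positive integral IOP exposure, morphometry
percent changes), and a synthetic-data generator whose ground truth is known
in closed form.

## Model and assumptions

The posterior sclera is treated as an axisymmetric thin membrane: a shell of
revolution whose meridian is well described by an ellipse. The working
assumptions are

* axisymmetry: the traced edge is a meridian, and the circumferential
  direction is recovered from distances to the axis of revolution;
* membrane behavior: shear strains and bending stress gradients are
  negligible away from the optic nerve head (ONH) and the fixture, and
  stresses are constant through the thickness (local scleral thickness is
  deliberately not used);
* the configuration at `P0` is the reference. Strains are therefore relative
  to a pre-stressed state; this is documented, not corrected.

**Kinematics.** With `X(s)` the reference edge, `x(s) = X(s) + u(s)` the
deformed edge, and `s` the reference arc length, the meridional
Green–Lagrange strain is

    E_phi = dX/ds . du/ds + 1/2 du/ds . du/ds,

which equals `(|dx/ds|^2 - 1)/2` because `|dX/ds| = 1` when `s` is the
reference arc length — the package parameterizes by arc length precisely to
honor that reduced form. The circumferential strain uses the deformed (`d`)
and reference (`D`) cross-section diameters at the same material point:

    E_theta = ((d/D)^2 - 1) / 2.

Displacement components are fitted to 4th-order polynomials in the
parametric angle of the fitted reference ellipse (counterclockwise from its
major axis), and all derivatives are taken analytically through the
angle-to-arc-length map. Fitting first and differentiating the fit avoids
amplifying the ~0.5 µm tracking noise, which pointwise finite differences
would do.

**Statics.** For a thin shell of revolution under internal pressure `p`,
equilibrium gives

    n_phi   = p r_t / 2
    n_theta = p r_t (2 r_m - r_t) / (2 r_m)

with `r_m` the radius of curvature of the deformed meridian and `r_t` the
transverse radius (distance from the surface to the axis of revolution along
the outward normal). We note that verbal descriptions of this formula
sometimes swap the two radii; the assignment above is the statically
consistent one — it reduces to Laplace's `p r / 2` on a sphere and to
`n_theta = pR`, `n_phi = pR/2` in the cylinder limit, and satisfies the
normal-equilibrium identity `n_phi / r_m + n_theta / r_t = p`, which the
test suite verifies with independently (finite-difference) computed radii.
Pressures are converted at 1 mmHg = 133.322 Pa; resultants are reported in
N/m.

**Curvature route.** The deformed curvatures are evaluated analytically on
the displaced curve — the fitted reference ellipse plus the fitted
displacement polynomial — rather than from a separate ellipse fit of each
deformed image. Both routes are defensible; the displaced-curve route was
chosen because it uses exactly the same analytic description of the
deformed configuration as the strain computation, so strains and resultants
refer to one consistent surface, and because it keeps the statics exact
whenever the true displacement lies in the quartic function space (which the
generator exploits for validation). The closed-form curvature of a fitted
ellipse remains available as `ellipse_curvatures()`.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `P0` | 7 | mmHg | middle of the typical 6–8 mmHg unwrinkling range |
| analyzed steps | 10, 14, 18, 22, 26, 30 | mmHg | the analyzed window runs from 10 to 30 mmHg; the exact step list is protocol configuration, not a constant |
| region bands | 5 equal arc-length bands | — | region extents between ONH and fixture are a labeling convention; R1 (peripapillary) and R5 (fixture) are excluded from analysis because membrane assumptions fail near edges |
| evaluation points | 8 in R2–3, 4 in R4 | — | up to 8 points are evaluated in regions 2–3 and averaged into one curve per region; R4 gets a separate curve |
| noise floor | 0.46 | µm | displacement error budget: 0.36 µm calibration + 0.10 µm correlation error |
| QC: step rejection | fit rms > 3 × 0.46 µm | — | anchors exclusion to the stated measurement error |
| QC: eye exclusion | > 50% steps invalid/missing | — | mirrors the practice of dropping eyes with poor polynomial fits or poor correlations |
| correspondence limit | 0.15 | mm | raw displacements an order of magnitude above any physiological response indicate broken point correspondence, not deformation |
| anisotropy epsilon | 1e-4 | strain | ratios with near-zero denominators are reported as undefined (`NA`), not errors |

## What the synthetic generator emulates

The generator drives an ellipsoid of revolution (defaults: equatorial
semi-axis 1.7 mm, polar 1.9 mm — a mouse eye) with a *prescribed kinematic
map*, not a constitutive solve: the analysis only measures kinematics, so
ground truth only requires a known deformation. Two field families are
provided, and the difference between them is a deliberate design decision:

* **Affine** (`stretch_affine()`): the semi-axes scale independently, so
  every deformed configuration is an exact ellipsoid with closed-form
  curvatures. This mode anchors the curvature/resultant ground truth and
  the spherical-symmetry identities.
* **Quartic displacement** (`stretch_polynomial()`,
  `stretch_polynomial_from_affine()`): the displacement components are
  4th-order polynomials in the meridian angle. Because the analysis itself
  fits 4th-order displacement polynomials, ground truth generated this way
  lies inside the method's own function space, and noise-free recovery can
  be required to numerical precision (observed: ~1e-11 strain error, ~1e-9
  relative resultant error). A sinusoidal field — e.g. the displacement of
  an affine scaling — is *not* exactly representable by a quartic, and the
  truncation residual (~1e-4 strain on mm-sized eyes at percent-level
  stretch) would otherwise be indistinguishable from implementation error.

Pointwise stretches are derived from the map and validated to be ≥ 1 at all
sampled angles and pressures; compressive fields are rejected as
unphysical. The pressure response is `w(p) = ((p - P0)/(30 - P0))^e` with
`e = 0.5` by default, giving the concave (stiffening) strain–pressure curves
seen in sclera. Default amplitudes (equatorial scale 1.015 at 30 mmHg)
produce circumferential strains of ~1.5% at 30 mmHg, the order observed in
mouse sclera. Tracking noise is i.i.d. Gaussian, 0.46 µm per coordinate,
matching the stated error budget. Cohorts add a per-eye log-normal
amplitude multiplier (sd 0.15) as a stand-in for biological variability.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: correlated or heteroscedastic tracking error,
lost or drifting tracked points, non-elliptical reference geometry,
viscoelastic creep during the ramp (only the loading portion of the first
cycle is modeled), fixture contact, regional thickness variation, and any
constitutive relation between pressure and stretch. The pipeline's accuracy
on real eyes is bounded by how well those assumptions hold, not by the
recovery numbers reported here.

IOP series, axon-count samples and morphometry cohorts are generated at the
study's observed scales: a 6-week schedule (days 0, 3, 7, then weekly), an
exponentially decaying treated-eye elevation whose cumulative exposure
(~105 mmHg·days) matches reported positive integrals, five 40×40 µm fields
comprising 9% of a 0.0889 mm² nerve, and morphometry cells drawn from the
reference cohort table.

## Numerical choices

* **Ellipse fitting**: direct algebraic least squares with the
  ellipse-specific constraint (Halir–Flusser partitioning), on centered and
  scaled coordinates, followed by orthogonal-distance refinement with
  Levenberg–Marquardt (log-parameterized semi-axes keep them positive).
  Exact data are recovered to ~1e-12; the refinement matters at the 0.46 µm
  noise scale. Collinear input and non-ellipse conics are rejected.
* **Projection**: points are projected to the ellipse by Newton iteration on
  the parametric angle (8 iterations, vectorized); points farther than
  `max(5 × rms, 1 µm)` from the fitted ellipse are refused.
* **Arc length**: cumulative trapezoid of the perimeter integrand on a
  4001-node grid (error well below 1e-7 mm on mm-sized eyes); the inverse
  map `nu(s)` uses cubic spline interpolation on the same grid because the
  strain operators differentiate through it — linear interpolation would
  leave a first-order kink error (~5e-5) in the unit-speed check.
* **Displacement fit**: quartic Vandermonde least squares in the angle
  normalized to [-1, 1] for conditioning; `fit_rms` pools both components.
* **Degenerate cases**: at a pole (point on the axis) the transverse radius
  is set to the meridian radius, the correct limit for a smooth shell of
  revolution; non-convex (inflected) fitted meridians are an error.
* **Positive integral IOP**: read as the time integral of the positive part
  of the pointwise treated-minus-fellow difference (not the difference of
  total areas), trapezoidal on measurement days with linear interpolation
  at sign crossings — exact for piecewise-linear series, non-negative by
  construction, and matching the quantity's use as cumulative exposure. One
  consequence, verified in the tests: under measurement noise the metric is
  upward-biased wherever the true difference is near zero, so its
  Monte-Carlo expectation, not the noiseless trapezoid, is the correct
  oracle.
* **Rounding**: percent metrics are reported at one decimal; comparisons to
  integers quoted at coarser precision use round-half-away-from-zero
  (`round_half_away()`), since base R's banker's rounding would turn 8.5
  into 8.
* **Orientation**: left/right eyes are mirrored to a common orientation
  upstream of the fit (the fit itself is rigid-motion invariant); the ONH
  end of a trace defaults to the low-angle end and is configurable
  (`onh_end`), since nothing in a coordinate table marks it.

## Open design points resolved in this implementation

* Displacement polynomials are fitted **independently per pressure step**;
  nothing in the protocol couples steps, and independent fits keep step QC
  local.
* The number of tracked points per eye is not dictated by the method;
  the default of 40 is exposed in configuration.
* The analyzed step list is configuration (`pressure_schedule()`), because
  the protocol fixes only the 10–30 mmHg window, not the exact steps.
* Group comparisons use rank tests (Wilcoxon pairwise, Kruskal–Wallis
  overall) with Bonferroni correction across pressure steps within each
  region × direction family. These are off-the-shelf conveniences; the
  aggregation layout (2 regions × 2 directions × steps) is the deliverable.

## Validation problem sizes

The test suite validates at sizes chosen to keep the full run within a few
minutes on one CPU while leaving no operation untested: 20 random
geometry/field pairs for noise-free recovery (< 1e-6 required, ~1e-11
observed); a 200-replicate Monte-Carlo of strain error under 0.46 µm noise
against a frozen bound of 1.7e-4 (replicate study: mean 1.48e-4, sd
5.3e-5); a 200-replicate ellipse-fit noise study against a frozen 2e-3 mm
bound; a null calibration of the two-group comparison over 100 replicates
at n = 6/6 eyes (≥ 94% of replicates must show no significant step); and a
power check at n = 20/20 eyes with the circumferential response reduced
30%, which must be detected at a majority of steps (all six detected in
practice).

## Known limitations

* Strains are relative to the pre-stressed `P0` configuration; absolute
  stretch from the stress-free state is not recoverable from these data.
* No shear strain, no bending, no thickness: the resultants are membrane
  forces per unit length, not stresses.
* The sampled axon-count estimator is unbiased for uniformly random fields
  only; real sampling concentrates on countable regions.
* The percent-loss-of-the-mean equals the mean per-eye percent loss only
  against a common pooled reference; cohort tables built with per-animal
  references will not reproduce it exactly.
* The CLI (`inst/cli/sclerashell`) is a thin convenience wrapper; the R
  functions are the supported interface.
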