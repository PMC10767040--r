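---
title: "Helical polymorphism of tubular assemblies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical polymorphism of tubular assemblies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubewrap)
```

## The model

Many tubular protein assemblies — the baculovirus VP39 nucleocapsid is the
motivating example — are best described as a 2D crystal lattice rolled
seamlessly onto a cylinder. Two basis vectors **a** and **b** (components
in Angstrom: equatorial first, axial second, in the frame of a reference
wrapping) fix the local packing of the repeating unit. A *wrapping vector*

$$\mathbf{w} = n_1 \mathbf{a} + n_2 \mathbf{b}$$

is the lattice vector that is rolled onto the tube equator; its length is
the circumference $C = |\mathbf{w}|$ and each integer pair $(n_1, n_2)$
defines a distinct *polymorph* that preserves local packing while changing
the tube diameter and helical symmetry. Decomposing each basis vector into
components along $\hat{\mathbf{w}}$ (arc lengths $x_1, x_2$) and along the
axis (rises $y_1, y_2$) gives the helical operators per lattice direction:
twist$_i = 360^\circ x_i / C$.

The rotational order is $\mathrm{gcd}(|n_1|, |n_2|)$. The gcd is the
general condition for a seamless $C_n$ rotation; the special case "one
index an integer multiple of the other" follows from it. For the VP39
lattice, $(14,14)$ gives C14 and $(6,13)$ gives C1.

### The canonical one-start operator

Axial positions of lattice points follow from a projection identity: the
axial coordinate of point $(u_1, u_2)$ is
$\det(\mathbf{a}, \mathbf{b})\,(n_1 u_2 - n_2 u_1)/C$, so consecutive
subunit levels are spaced by

$$\mathrm{rise}_{1\text{-start}} = \mathrm{order} \cdot
|\det(\mathbf{a}, \mathbf{b})| / C,$$

always reported positive. The generating lattice vector is obtained by
solving $n_1 u_2 - n_2 u_1 = \mathrm{order}$ with the extended Euclidean
algorithm, and its twist is reduced into $(-180/\mathrm{order},
180/\mathrm{order}]$; the sign of the twist then encodes the handedness of
the one-start family. On the VP39 lattice with $(14,14)$ this yields rise
43.86 Å and twist $-7.16^\circ$:

```{r}
helix_from_wrapping(vp39_lattice(), 14, 14)
```

### Enumeration sector

`enumerate_wrappings()` lists all polymorphs in a circumference range.
The selection sector is a free choice (the observed polymorphs cluster
near the reference wrapping); the default predicate keeps wrappings whose
pitch angle is at most 20 degrees and canonicalizes signs with
$n_1 + n_2 > 0$, and is injectable for other conventions. No particular
reference count is asserted for the default sector.

## Building tube models

`build_tube()` radially translates the asymmetric unit (its
scattering-weighted center of mass to the helix radius, outward reference
along $+x$), then places one copy per lattice point: a rotation about the
radial axis by the tube's *spin* angle — the angle between the reference
equator and this wrapping's equator, which accounts for the orientation of
the common 2D lattice on each polymorph — followed by the azimuthal
rotation and axial translation. Positive spin tilts the lattice
counterclockwise seen from outside. Axial windows are half-open,
$[z_\min, z_\max)$ with a $10^{-7}$ relative tolerance, so stacked windows
partition the tube exactly even when lattice points fall on a boundary.

The unit is the full dimer; no dyad symmetrization is applied. Building
from the dimer reproduces the D-like symmetry of dimeric tubes
automatically, and non-dimeric units remain usable.

## Flattening

Tubes embedded in thin ice are often compressed to an approximately
elliptical cross-section. `flatten()` models this at *fixed perimeter*:
for a major-axis scale $s \ge 1$ the semi-major axis is $a = s\,r$ and the
semi-minor axis $b$ is root-found so the elliptic line integral equals the
round circumference to $10^{-8}$ relative (bracketed root on $b$ with
adaptive quadrature; `scale 1` short-circuits to the circle). A scale of
$1 + k/100$ corresponds to $k\%$ flattening, with the study-range
$1.00$–$1.09$.

Each subunit keeps its axial coordinate; its circular arc-length position
$s = r\,\theta$ is mapped to the point at the same arc length along the
ellipse (helical twists matched to elliptical path lengths), and the
subunit is rotated about the vertical axis through its center of gravity
so its outward reference aligns with the exact ellipse normal. The map is
rigid within each subunit. Arc-length inversion uses a dense cumulative
table (4096 intervals, 7-point Gauss–Legendre per interval) plus Newton
refinement on the exact integrand, giving round-trip arc-length errors
well below $10^{-6}$ Å. The registration between azimuth zero and the
flattening axis is a free phase (default: azimuth 0 maps to
$(+a, 0)$); any fixed choice differs only by an in-plane rotation, which
classification absorbs into its azimuth search.

## Rendering and simulation

Density is rendered as one isotropic Gaussian blob per atom with
amplitude proportional to atomic number (uniform for pseudo-atoms); the
projection of a 3D Gaussian is analytic, so projection images are splatted
directly from atoms, while `render_volume()` + `project()` provides an
independent line-integral path used for cross-validation (trilinear
interpolation; the two paths agree to interpolation accuracy on toys).
Views are restricted to directions perpendicular to the tube axis — the
geometry of filament segments lying in the ice plane — with free azimuth
$\varphi$ and in-plane rotation $\psi$; out-of-plane tilt is not modeled.
Band-limiting is a hard radial low-pass; noise is additive white Gaussian
scaled so that signal variance over the tube mask (pixels above 5% of the
signal maximum) divided by noise variance equals the requested SNR. Power
spectra are $|\mathrm{DFT}|^2 / N$, so they sum to the image energy.
No CTF is simulated: classification operates on band-limited data where a
corrected CTF would be approximately flat, and adding image-formation
physics would not change what the desk-scale experiments test.

The synthetic generator (`make_pseudo_unit()`, `generate_dataset()`) is a
first-class module: a seeded, deliberately chiral blob cluster with a
roughly 100 x 50 x 45 Å footprint (tangential x axial x radial, echoing a
compact dimeric repeat unit) stands in for the atomic dimer, so the whole
pipeline runs with no downloads. Every random stage draws from a named
stream (`unit`, `pose`, `noise`) derived from one master seed, so stages
can be varied independently and datasets are bit-reproducible. What the
generator does *not* emulate — CTF, ice gradients, carbon edges, dose
damage, out-of-plane tilt, real protein texture — bounds what passing
tests mean: they validate the geometry, rendering and search machinery,
not performance on micrographs.

### Pose priors

Real segment stacks come from traced filaments, so the in-plane angle is
known to within a few degrees at extraction time; the generator draws
$\psi \sim U(-6^\circ, 6^\circ)$ and shifts $\sim U(-15, 15)$ Å, while the
azimuth $\varphi$ is uniform over the full circle (nothing constrains it).
These priors were fixed once as the generator's definition of a
"pre-aligned" segment stack.

## Supervised classification

`build_reference_bank()` renders band-limited projections of one tube
model per (wrapping, flattening) pair over a per-entry azimuth grid. The
grid covers one rotational period — $360/\mathrm{order}$ for round tubes;
flattened tubes are 180- or 360-periodic depending on whether the order is
even, because the flattening-axis orientation becomes part of the pose —
at a step that keeps the equatorial arc motion per step below 25 Å, about
twice the 12 Å scoring band limit.

The score is the maximum masked normalized cross-correlation over integer
pixel shifts (computed for all shifts at once with FFTs, with the segment
mean and norm evaluated inside the shifted mask window), over the azimuth
grid and over the in-plane angle grid; a brute-force double-loop oracle
verifies the FFT path exactly in the tests. The mask is circular and
shared by all entries (widest reference plus three blob sigmas by
default). `classify()` assigns each segment to the highest-scoring entry
with a deterministic tie-break (first key in sorted order) and records the
best-versus-runner-up margin; no confidence cutoff is imposed, since
supervised classification can produce confidently wrong assignments and
users should inspect margins themselves.

For throughput, `classify()` uses a coarse-to-fine search per entry
(every third azimuth at the central in-plane angle; local refinement of
the two best candidates; one sweep of coordinate descent over azimuth and
in-plane angle). The exhaustive single-grid mode is retained and the tests
check the two agree on clean segments. Scoring of (segment, entry) pairs
is independent, so results do not depend on evaluation order.

## Numerical choices

* Quadrature: `integrate()` at `rel.tol 1e-12` for perimeters; the
  solver re-verifies $|\Delta C|/C \le 10^{-8}$ and errors otherwise.
* Root finding: `uniroot()` on the semi-minor axis, bracket
  $(10^{-3} r, r)$, tolerance $10^{-11} r$.
* Interpolation: bilinear for image rotation, trilinear for volume
  sampling; stated as the accuracy contract for the dual-path checks.
* Degenerate inputs: zero wrapping index, collinear basis vectors,
  non-positive radii/axes, sub-Nyquist band limits and mask radii beyond
  half the box raise errors; an axial window containing no lattice point
  returns an empty model with a warning.
* Boundary ties in lattice windows are resolved by the $10^{-7}$
  relative tolerance described above; azimuths are reported in
  $[0, 360)$.

## Problem sizes

The shipped test conditions are desk-scale by design: 128-pixel images at
5 Å/pixel, six wrappings, three flattening levels, 20 segments per class
(360 segments), SNR 0.3, band limit 12 Å, master seed 20240104. The
acceptance script runs the same pipeline at 72 segments and two flattening
levels. Full-survey banks (hundreds of wrappings, ten flattening levels,
912-pixel boxes) are supported by the same code paths but are not part of
the test conditions.

## Known limitations

* Flattening discrimination is intrinsically degenerate at oblique
  azimuths: a flattened tube viewed roughly 45 degrees from its
  flattening axis projects at the same apparent width as a round tube, so
  at low SNR the score ranking between non-adjacent flattening levels can
  be decided by the noise realization. Lattice (wrapping) recovery does
  not suffer from this degeneracy. The recovery tests assert strict
  adjacent-level flattening confusion, and an occasional failure of that
  assertion at SNR 0.3 reflects this physical degeneracy rather than a
  search defect (finer search grids shrink the score gap but need not
  flip it). For the same reason, adjacent-level mixing biases the
  recovered fraction of exactly non-flattened segments upward in mixtures
  whose flattened levels outnumber the round one: a 2% flattening changes
  the projected width by well under the scoring band limit.
* The elliptical deformation is geometric, not elastic; real compressed
  tubes need not be elliptical.
* Supervised classification against rendered references can assign wrong
  symmetries with high scores; margins are reported, thresholds are not.
* The apical/basal cap structure of real nucleocapsids is not modeled;
  tubes are infinite cylinders windowed in z.
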