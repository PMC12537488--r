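---
title: "Models and numerical methods in giantmag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in giantmag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`giantmag` models the full computational chain used to study the
three-dimensional magnetic structure and magnetoreceptive potential of giant
magnetofossils — micron-scale biogenic magnetite crystals (needles, giant
bullets, spearheads, spindles) preserved in marine sediments.  The chain has
five stages: synthetic particle geometry and magnetization phantoms, a
phase-XMCD projection forward model, gradient-based magnetic vector
tomography, voxel micromagnetics, and a Boltzmann torque-transducer model of
magnetointensity reception.  This vignette records the models, the numerical
choices, and their limitations.

## Particle geometry and vortex phantoms

The spearhead particle is represented as a stack of elliptical frustrums
along the long axis `z`.  The reference particle has base major radius
0.55 µm, tip radius 0.058 µm, length 2.25 µm, 90 slabs of 25 nm, and a
minor/major cross-section ratio of 0.85.  Because the real radial profile is
traced from micrographs, an idealized but fully reproducible profile is
used: a cylinder over the first 55% of the length, a linear taper to the tip
radius thereafter, smoothed with a two-slab moving average at the junction.
`voxelize()` samples the solid with voxel centers
(`origin + (index − 0.5)·h`); volumes converge to an independent
Monte-Carlo estimate within 2% at 20 nm voxels and by less than 3% between
successive grid refinements.

`make_vortex_phantom()` builds the analytic single-vortex texture that makes
every downstream stage testable without any measured data.  Its ingredients,
each controlled by a `phantom_spec`:

* in-plane circulation of unit magnetization about a core path interpolated
  through user control points (natural spline in `z`);
* a Gaussian cant of the core toward ±`z` with a 1/e radius of 60 nm by
  default, comparable to the ~50 nm experimental resolution floor.  The
  polarity sign reverses at each `polarity_flip_position`, creating a Bloch
  point;
* a weaker lateral `M_z` half-pattern (`tanh` across a wall of width three
  voxels, amplitude 0.4 of saturation) that is antisymmetric across the
  medial plane through the core — this is the medial domain wall.  With
  `tip_mz_reversal` the wall normal rotates by 180° across the tip region,
  reversing the half-pattern and twisting the wall;
* renormalization so |M| equals the saturation magnetization everywhere
  inside the mask.

The phantom reproduces the qualitative observables of the real particle
(bipolar side-on XMCD contrast, curved core, one Bloch point, twisted medial
wall) but it is *not* an energy-minimizing state: magnitudes are exact and
textures are prescribed, not emergent.  Tests passing on phantoms therefore
validate the measurement and analysis chain, not micromagnetic physics —
that is what the micromagnetic module is for.

## Projection model and tilt series

A phase-XMCD projection is the line integral along the beam of the
magnetization component parallel to the beam.  The implementation resamples
the volume on a beam-aligned grid (bilinear in the tilt plane — tilts only
mix two axes — and exact along the tilt axis) and sums along the beam.  This
rotate-and-sum form was chosen over per-ray marching because its adjoint is
exact by construction (same interpolation weights, scatter instead of
gather), which the reconstruction's gradient requires; a dense 4×-sampled
ray-march oracle in the test suite guards its accuracy (<1% on resolved
fields).  Positive tilt is a right-handed rotation about the tilt axis; the
second acquisition axis is realized by first rotating the sample 90° about
the beam (an exact array permutation) and then tilting.  The experimental
angular ranges are −30°…+43° (first axis) and −42°…+34° (second); the
simulator takes an explicit angle list, since the printed projection counts
and the printed ranges differ slightly in the source acquisitions.

`simulate_tilt_series()` adds per-image Gaussian signal noise and rigid
shifts (integer plus subpixel), records the true shifts, and emits matched
non-magnetic thickness maps (charge images) as the alignment reference.
All randomness is seeded; no global RNG state is touched.

## Alignment and reconstruction

Alignment follows tomographic practice: integer registration of angular
neighbors by FFT cross-correlation (walking outward from the image nearest
zero tilt), then subpixel refinement of the tilt-axis coordinate by aligning
the center of mass of the charge profile, which is invariant under tilt in a
parallel-beam geometry.  The two axes are registered by cross-correlating
the near-zero-tilt images after a 90° in-plane rotation; both rotation
senses are scored and the better one kept.  The magnetic images are used for
this, because the charge image of a near-axially-symmetric particle is
mirror-symmetric and cannot distinguish the senses.

`reconstruct_vector()` is the gradient-based iterative algorithm: start from
a zero-filled object; at each iteration forward-project all three components
at every angle of both series, form the sum-squared difference against the
data, back-project the residuals weighted by the per-angle beam-direction
components, and step along the negative gradient with an exact line search
(the objective is quadratic in the step, so the optimal step is in closed
form; the error is then non-increasing by construction).  The particle mask
is re-applied after every update.  Ten iterations are the default.  No
regularization is applied.  With wide dual-axis coverage the phantom round
trip reaches a masked relative vector error below 0.25 and recovers the core
within two voxels; with the restricted experimental ranges the point spread
of a magnetic impulse elongates along the beam axis — the familiar missing
wedge — which the tests measure directly.

## Voxel micromagnetics

The energy functional is the standard one: exchange, cubic
magnetocrystalline anisotropy, demagnetizing and Zeeman terms, with
magnetite room-temperature constants (Ms = 4.80768e5 A/m,
K1 = −1.32658e4 J/m³, Aex = 1.33487e-11 J/m).  Discretization is by regular
voxels rather than the tetrahedral finite elements used with MERRILL-class
codes: voxel grids need no mesh generator and admit an FFT demagnetizing
convolution, at the cost of staircase surfaces.  Choices:

* exchange: 6-neighbor Laplacian with free (Neumann) boundaries — a missing
  neighbor contributes nothing;
* anisotropy: evaluated in the crystal frame through a proper-rotation
  `crystal_orientation`; the default places [113] along the particle axis
  with [111] (the easy axis of magnetite, K1 < 0) in the x–z plane, the
  orientation that best matches spearhead observations;
* demagnetization: FFT convolution with the Newell cell-averaged tensor,
  zero-padded to at least twice the grid so the circular convolution is
  exactly linear.  The tensor elements follow the analytic cuboid-cell
  formulas evaluated on a 27-point second-difference stencil; unit tests pin
  them against a Monte-Carlo surface-charge oracle, the point-dipole far
  field, and the exact 1/3 demag factor of cube and sphere;
* minimizer: projected gradient flow on the unit sphere — move each moment
  toward its effective field, renormalize, accept only energy-non-increasing
  steps — with a Barzilai–Borwein secant step and backtracking.  The
  convergence measure is the maximum per-voxel reduced torque
  |m × H|/|H| (default tolerance 1e-5, iteration cap 20 000; the test suite
  uses 1e-3 and a few hundred iterations, which is where the spearhead's
  structure and moment have long stabilized).

Protocols: `hysteresis_loop()` sweeps the field with warm starts and
extracts coercivity and squareness; `backfield_remanence()` implements the
DC demagnetization protocol for the coercivity of remanence; both tilt the
applied field by 1° by default, the customary symmetry-breaking device
without which a perfectly antiparallel field exerts no torque on a collinear
state.  `susceptibility()` is a ±1 mT central difference about the ground
state.  `growth_simulation()` adds one slab at a time (seeded random
initialization of new material, full re-minimization), emulating particle
growth from base or tip.

Test problem sizes are deliberately desk-scale: the spearhead relaxes at
40 nm voxels (≈20 000 magnetized voxels), where the relaxed state reproduces
the observed phenomenology — a single curved vortex core near the medial
plane, a medial M_z = 0 wall, a net moment of order 1e-14 A m² within ~10°
of the long axis, squareness of order 0.02 — and a −26 mT back field along z
reverses the core polarity.  Quantities that require full field sweeps at
fine resolution (Bc ≈ 2 mT, Bcr ≈ 12 mT) are exercised as protocol
correctness tests on small particles, not reproduced at the spearhead scale.
The nudged-elastic-band barrier between core polarities is out of scope;
only the start and end states of that calculation (the ±2 core-strength
vortex initializations) are provided.

## Topology extraction

`trace_core()` finds, per z-slice, the plaquette (2×2 cell) with unit
winding of the in-plane angle field, refines the core to subpixel precision
by a quadratic fit of the in-plane magnitude minimum, links slices by
nearest neighbor, and takes the polarization as the sign of the interpolated
M_z on the core.  Two robustness rules matter on coarse grids: the first and
last traced slices (the particle end caps, where closure fields flip M_z)
are excluded from polarity-flip detection, and a flip only counts when the
flanking core |M_z| values reach 20% of the path median.  A deliberate
distinction: the *winding number* (topological degree) of a vortex is +1
regardless of its sense of rotation — global negation of the field adds π to
every in-plane angle and changes no degree — so the rotation sense
(chirality) is reported separately, as the sign of the discrete curl at the
core; it is the chirality that flips when the field is negated.
`extract_medial_wall()` takes the M_z = 0 level set per slice (contour
extraction restricted to a one-voxel-eroded mask, to suppress spurious
boundary contours), measures the wall-trace orientation as the principal
axis of the contour points, unwraps it along z with period 180°, and flags a
tip twist when the tip-region orientation rotates more than 45° from the
body median.

## Torque-transducer model of magnetointensity reception

An elastically anchored magnetic particle with magnetic energy `MB` and
torsional stiffness `K` (both in thermal units) deflects by an angle ψ with
energy `u(ψ) = −MB·cos(θ − ψ) + K ψ²/2` on ψ ∈ (−π, π], where θ is the
field angle to the rest position.  The deflection is Boltzmann-distributed;
`deflection_statistics()` computes its mean and standard deviation by
adaptive quadrature (relative tolerance 1e-10, stabilized by subtracting the
minimum energy).  The fluctuation amplitude Δψ is the full standard
deviation over the possibly bimodal distribution — that is what produces the
rapid rise of Δψ near MB/K = 1 for antiparallel fields (θ = 180°), where the
quadratic well degenerates into a quartic one and the system sits at a
critical point.  Closed forms anchor the numerics: the harmonic limit
Δψ = (K − MB)^(−1/2) for MB/K < 1 and the quartic-well value
[(24/K)^(1/2)·Γ(3/4)/Γ(1/4)]^(1/2) at MB = K, both matched within 5%.

`sensitivity_curve()` reports the sharpness d(Δψ)/d(MB/K) both **at** the
critical point MB/K = 1 and at its numerical maximizer.  The two differ at
finite K: the maximizer sits at 1 + O(K^(−1/2)) (≈1.10 for K = 121, ≈1.39
for K = 6) while the critical-point comparison between a spearhead-like
transducer (K = 121) and a nanoparticle-cluster-like one (K = 6) gives the
≈2.4-fold sensitivity advantage; both values are exposed because "at the
critical point" and "at the maximum" are equally defensible readings of the
physics.

`minimum_detectable_angle()` finds the smallest deviation η from
antiparallel alignment at which the mean-deflection shift exceeds the
thermal fluctuation of the deflection *at the operating angle*:
|⟨ψ⟩(180°−η) − ⟨ψ⟩(180°)| ≥ Δψ(180°−η).  Evaluating the noise at the
deflected angle (rather than at 180°) is a deliberate design choice: the
read-out fluctuates at the angle the system actually occupies, the
criterion is then monotone in η, and it yields η ≈ 1.2° at K = MB = 121
versus η ≈ 15° at K = MB = 6 — degree-scale versus tens of degrees.  With
the noise frozen at 180° the weak transducer never satisfies the criterion
at all, which contradicts the physical picture of a usable (if poor)
compass.  The signal-to-noise factor is exposed as a parameter.

`fossil_energy_stats()` summarizes MB/k_BT over a user-supplied table of
fossil moments.  The package ships a *synthetic* 24-row example table
(`inst/extdata/synthetic_moment_table.csv`, clearly labelled synthetic)
whose morphology clusters imitate the published pattern — needles and giant
bullets a few tens of k_BT, spearheads near 100 k_BT, spindles the largest —
for the worked example and the arithmetic-oracle tests; it is not a
measured dataset.  Users supply real moment tables as CSV files with
`label` and `moment` columns.

## Reproducibility and problem sizes

All stochastic operations take explicit seeds and restore the caller's RNG
state.  The test suite builds every fixture in code: no binary data ship
with the package.  The heavy test cases are the 40 nm spearhead relaxation
(~3 minutes), the −26 mT backfield protocol (~5 minutes) and the 40 nm
dual-axis phantom round trip (~1 minute); everything else runs in seconds.
`scripts/acceptance.R` recomputes the critical-point quantities of the
torque-transducer model from scratch and writes them as JSON; see the
README for how to run it.

## Known limitations

* Voxel discretization at 40 nm under-resolves the ~9 nm exchange length of
  magnetite; relaxed structures are phenomenologically correct but energies
  and switching fields are resolution-dependent.  20 nm voxels are the
  intended production resolution.
* The phantom prescribes textures rather than deriving them; its medial-wall
  amplitude and core profile are conventions.
* The reconstruction assumes parallel-beam geometry, perfectly known angles
  and equal weighting of the two series; angle refinement is not modelled.
* The torque-transducer model is planar (a single deflection angle); a full
  spherical rotor and time-domain (Langevin) dynamics are out of scope.
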