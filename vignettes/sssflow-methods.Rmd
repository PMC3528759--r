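---
title: "Models and methods: synthetic 4D PC-MRI versus sectionwise CFD of cervical CSF flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: synthetic 4D PC-MRI versus sectionwise CFD of cervical CSF flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sssflow` is a desk-scale, fully synthetic reimplementation of a classic
comparison in CSF biofluid dynamics: time-resolved, three-directionally
velocity-encoded phase-contrast MRI (4D PC-MRI) of flow in the cervical
spinal subarachnoid space (SSS) versus subject-specific rigid-wall CFD of
the same anatomy. In vivo, such comparisons consistently find that measured
peak CSF velocities exceed simulated ones, more so in Chiari I-like
stenosed anatomies, and attribute the difference to fine anatomy
(nerve roots, denticulate ligaments, trabeculae) and tissue motion that the
CFD geometry omits. This package makes every stage of such a comparison
executable and verifiable without clinical data: the in vivo acquisition is
replaced by a forward simulator with known ground truth, and the commercial
3D finite-volume solver by an in-repo flow-rate-constrained pulsatile
solver with analytic references.

Two principles organise the design:

* **Known ground truth everywhere.** Every measured quantity can be traced
  to a generator parameter, so recovery can be asserted exactly (noiseless)
  or within calibrated noise bounds.
* **The discrepancy between the arms is a designed mechanism, not an
  artefact.** The MRI arm's ground-truth velocity field carries anterior
  weighting, nerve-root velocity deficits and stenotic jets; the CFD arm
  solves smooth inclusion-free sections. The package therefore reproduces
  the structure of the in vivo finding — measured peaks exceeding simulated
  ones, more in stenosed subjects — by construction, and the tests verify
  that the pipeline transports this designed contrast faithfully. Passing
  does not show that real MRI exceeds real CFD; it shows the measurement
  and simulation chain behaves correctly on data whose truth is known.

# Geometry model

A subject is an ordered stack of planar cross-sections (caudal to cranial,
`z` increasing): dura outer contour, spinal-cord inner contour, optional
inclusion polygons standing in for nerve roots. Anterior is `+y`; caudal
flow is negative axial velocity. The healthy template is an elliptical cord
(4.5 x 3.5 mm semi-axes) set 0.8 mm posteriorly inside an elliptical dura
(9 x 8 mm), with nine labelled levels (FM, C1, C2M, C2P, C3-C7) spanning
112 mm and a 50 mm caudal inlet extension below C7. Subjects differ by a
seeded smooth low-order radial perturbation (SD 0.15 mm, modes <= 3).
Contours are Laplacian-smoothed (default 10 iterations, relaxation 0.5 —
the smoothing method applied to segmented surfaces in this field names no
parameters, so defaults are ours). Chiari-like (`cm_like`) geometries
blend the outer contour toward the cord over FM-C1 so the FM luminal area
equals the healthy template area times `1 - stenosis_severity`; a
root-finding step makes that exact. No quantitative subject anatomy exists
to copy, so the templates are explicitly synthetic stand-ins with
field-plausible dimensions.

# The MRI arm

## Ground-truth velocity model

Within each slice the axial velocity profile is built from the distance to
the nearest wall (zero at walls, tent-like across the gap), multiplied by
an anterior weight `aw^(2*yhat - 1)` (`yhat` the normalised anterior
coordinate; default `aw = 2` gives mid-gap anterior/posterior speed ratios
of about 2.4), multiplied by `1 - f * exp(-(d/sigma)^2)` near each
inclusion (default deficit `f = 0.5`, `sigma = 0.8` mm), plus, for
`cm_like` subjects at and above C1, an anterolateral Gaussian jet whose
amplitude is solved so the slice peak equals `jet_peak_factor` (default
2.5) times the slice mean. The profile is then rescaled so its areal
integral on the sampler's quadrature lattice (midpoint rule, default
0.1 mm; 0.25 mm in cohort runs) equals the prescribed flow `Q(t)` exactly —
conservation holds by construction, and the conservation tests compare
against an independently coded quadrature on the same lattice, which is
the stated contract. In-plane true velocities are zero.

The driving waveform is a two-harmonic pulse with a sharper, dominant
caudal (systolic) lobe, normalised so the systolic peak equals the
`amplitude` parameter (default 2 mL/s), zero-net by construction.

## Encoding

The encoder samples the ground truth at voxel centres (default 1.5 mm
isotropic), maps velocity to phase `pi * v / VENC`, adds Gaussian phase
noise (default SD 0.1 rad, i.e. velocity noise `VENC * 0.1 / pi`), wraps to
`[-pi, pi)` and maps back. Velocities beyond +/-VENC therefore alias by
wrap-around exactly (`encode(v + 2 VENC) = encode(v)`), and noiseless
encoding below VENC is the identity. VENC defaults follow the clinical
protocol this emulates: 10 cm/s for healthy-like subjects, 20 cm/s for
patients. Two measurement confounders are optionally injected:

* **Vascular confounders** — small unidirectional regions outside the dura
  near the FM (arterial cranial on one side, venous caudal on the other,
  |v| about 0.55 VENC, never changing sign over the cycle), emulating
  vertebral/basilar vessels adjacent to the FM ROI.
* **Background velocity offset** — a constant thru-plane bias
  (`velocity_offset_cm_s`, cohort defaults 0.18-0.27 cm/s) standing in for
  residual eddy-current offsets, which makes measured net flow per cycle
  nonzero. It lives in the encoder, not in the physical waveform, so the
  truth stays zero-net; the quantification pipeline removes it via the
  zero-net offset and reports it both in flow units and as flow over ROI
  area (cm/s) — the unit the in vivo literature reports (the ambiguity
  between the two is real, so both are exposed).

We do not model k-space, eddy-current filters, gating jitter, or
through-plane partial volume beyond voxel-centre sampling; noise magnitude
and jet strength are generator parameters because the source material
reports them only qualitatively.

## Quantification

ROIs are rasterised from the geometry as the annular gap at each level
("ring"), or with a thin posterior wedge removed ("cuff") mirroring
tracing software whose single-closed-contour limitation forces a cuff
around the cord with tips meeting posteriorly. Inclusion interiors stay in
the ROI — a reader tracing around the cord cannot exclude structures below
image resolution. Per level: vascular pixels are excluded by the
flow-direction rule (|v| above `0.2 VENC` — a reproducible threshold in
place of the visual judgement used in vivo — and never changing sign);
flow is the pixel-velocity sum times pixel area; the waveform is offset by
subtracting its periodic cycle mean (a constant is the minimal offset
consistent with a single scalar per subject being reported in vivo); peak
systolic (most negative) and diastolic (most positive) thru-plane
velocities are extracted with a zero floor when a direction is absent; and
stroke volume is half the cycle integral of |Q| (periodic trapezoid, which
on a uniform cyclic grid is the sample mean). The inlet waveform for the
CFD arm is the one with the greatest `max |Q|`, ties to the more caudal
level.

# The CFD arm

## Model reduction

The in vivo comparison used a 3D unstructured finite-volume solve (about
two million tetrahedra, hours per subject). Here the rigid-wall,
incompressible, Newtonian, laminar flow (rho = 1000 kg/m^3, mu = 0.001
Pa s) is solved section-by-section as fully developed axial flow:

    rho dw/dt = G(t) + mu Laplacian(w),  w = 0 on walls,

with the driving pressure gradient `G(t)` determined at every step so the
areal flux of `w` equals the prescribed `Q(t)`. For axially invariant
lumens the advective term vanishes identically, so this is an exact
reduction of the Navier-Stokes momentum balance, verifiable against
closed forms; for slender, slowly varying lumens it is a controlled
surrogate. Near strong stenoses real 3D effects (jets, secondary flow)
are not represented — which is precisely the limitation the comparison is
designed to expose, and is documented in the report. Because the model is
rigid and incompressible, the same `Q(t)` traverses every section: CFD
stroke volume is constant along the spine (the tests assert level
invariance to 1e-6 relative), the mechanistic contrast to the MRI arm
where SV varies with noise and offsets. The zero-pressure cranial outlet
of the 3D model has no sectionwise analogue; pressure is reported as the
gradient series `G(t)`, i.e. relative to the cranial end.

## Discretisation

Masked 5-point finite differences on a uniform Cartesian lattice with
Shortley-Weller embedded Dirichlet boundaries: arms cut by a contour use
the exact ray distance to the polygon (floored at 1e-3 of a spacing — a
larger floor shifts the wall and demonstrably degrades convergence to
first order). Flux quadrature uses cut-cell weights (arm-fraction
products), which keeps the flow-matching constraint second-order
consistent. Time integration is implicit: backward Euler, or BDF2
(`implicit_second_order`) which the verification studies use — the phrase
"second-order backward Euler" in solver lore is self-contradictory, so
both are provided. Each step costs one sparse triangular solve with the
prefactorised operator plus a scalar update for `G(t)` via a precomputed
unit-forcing solution (superposition; the model is linear and the tests
assert linearity directly).

## Start-up transients and periodicity

A flux-constrained annular gap of width L relaxes at rate
`nu (2 pi / L)^2` — about 2.5 1/s for a 4 mm gap — so marching from rest
leaves ~1e-3 relative transient after three 1 s cycles; no small cycle
count can reach 1e-6 periodicity from rest. The default `"periodic"`
initialization therefore starts from the harmonic-balance solution of the
*same* discrete stepping operator (per waveform harmonic, one complex
sparse solve of `(lambda_k I - mu L) u = 1` with `lambda_k` the scheme's
characteristic factor at `z = exp(i omega_k dt)`, flux-matched per
harmonic). The march then stays on the periodic orbit to round-off, and
the periodicity diagnostic measures exactly that. A `"zero"` mode is kept
for demonstrating transient decay. The analytic Womersley/Poiseuille
oracles used in tests are independent of this machinery.

## Analytic references

Steady flow uses the annular Poiseuille closed form; oscillatory flow uses
the Womersley-type annulus solution assembled from modified Bessel
functions I0/K0 of complex argument (power series below |z| = 10,
large-argument asymptotics above, exponentially scaled so high Womersley
numbers neither overflow nor lose the boundary layers; worst-case relative
accuracy ~1e-8 at the switch radius, ample for percent-level solver
verification). Per-harmonic pressure amplitudes are flux-matched by
Simpson quadrature (2001 radial points). At the benchmark conditions
(5/9 mm annulus, T = 1 s) the gap Womersley number is about 10, the regime
where profiles flatten and annular boundary layers (~0.56 mm) form.

## Independence studies

The grid study solves at three strictly refining spacings and compares
peak-systolic probe velocities with
`e = 100 max|V_fine - V_coarse| / max|V_fine|` (the exact in vivo formula
survives only as symbols; this convention is ours and is documented, not
asserted as the original). The time study sweeps T/100, T/1000, T/10000
and reports successive solution differences, which must shrink
monotonically. Convergence order against the Bessel oracle at spacings
0.36/0.18/0.09 mm lands near 1.9, consistent with the second-order design.

# Motion analysis

Paired extreme-phase sagittal images are generated analytically (a smooth
two-lobed tonsil or a sharp block over a constant background, default
noise SD 1 intensity unit on a 100-unit feature), the caudal image being
the rostral one with the feature translated caudally by the prescribed
displacement — analytic re-evaluation makes sub-pixel shifts exact. The
mask is `|rostral - caudal| <= threshold` (static); the default threshold
is 3x the median-absolute-deviation noise SD of the difference image,
since the in vivo overlay threshold is unstated. The moving fraction is
this module's quantification — the in vivo analysis was purely visual — and
for the block phantom the moving area equals the analytic symmetric
difference; the fraction is monotone in displacement (until saturation)
and antitone in threshold. Cohort defaults give CM-like subjects 1-3 mm
tonsillar displacements and healthy-like ones 0.4-0.6 mm, with the least
motion among patients assigned to the third one, echoing the qualitative
in vivo ranking.

# Cohort experiments and problem sizes

The default cohort is 3 healthy-like + 4 CM-like subjects (VENC 10/20,
stenosis severities 0.3-0.5, amplitudes 1.6-2.2 mL/s, fixed seeds; one
global seed expands to per-stage seeds by a documented splitting rule so
every stage is independently reproducible). Single-section verification
runs use the reference resolution: 0.15 mm grid, T/1000 steps, 3 cycles.
A cohort run solves 63 sections, so it uses a reduced configuration —
0.35 mm grid with per-section refinement to gap/10.5 at stenoses, T/400
steps, 2 cycles with periodic initialization, BDF2, and 0.25 mm slice
quadrature in the MRI generator — chosen so a full cohort completes in a
few minutes on one CPU while leaving the verified physics unchanged. The
comparison report operationalises "consistently greater" as the
per-subject count of levels with |MRI| > |CFD| peak systolic velocity, and
the group contrast as the mean FM-level gap difference between classes;
the in vivo claims are visual/tabular, so these statistics are ours.

# Known limitations

* The sectionwise solver omits 3D advection, in-plane velocities, moving
  walls and porous-media effects; near severe stenoses it understates jets
  — by design, as the CFD arm of the comparison.
* The MRI simulator's fine-structure effects are parametric, not
  hydrodynamic: deficits and jets are imposed on the profile, not solved.
* Geometry templates are synthetic; no claim of anatomical fidelity beyond
  plausible dimensions and the healthy/stenosed contrast.
* Tests passing on synthetic data validate the pipeline's correctness and
  calibration, not the in vivo magnitudes, which derive from unavailable
  clinical data.
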