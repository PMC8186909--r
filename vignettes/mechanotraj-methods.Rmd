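---
title: "Methods: models, conventions and numerical choices in mechanotraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mechanotraj implements the trajectory-analysis layer of a "push-to-open"
gating study of a tethered mechanosensitive channel: pore-radius profiling,
essential-dynamics PCA with a sharp-change filter, TRP-domain angle
analysis, ankyrin-repeat (AR) spring mechanics from restraint reaction
forces, ion permeation counting, and hydrogen-bond occupancy. This
vignette records the models behind each stage, the conventions and
defaults, and the choices made where the design was genuinely open. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## Units and coordinate conventions

Coordinates are Angstrom throughout the `Structure`/`Trajectory` layer;
the mechanics layer reports lengths in nm (conversion at the boundary,
divide by 10). Times are ps, forces pN, energies pN·nm, spring constants
pN·nm⁻¹. The membrane normal is the z axis with the extracellular side at
+z; analyses assume the channel has been oriented that way (the
superposition utilities make this explicit rather than relying on an
externally oriented frame). 1 kJ·mol⁻¹·nm⁻¹ = 1.66054 pN, derived from the
Avogadro constant, is available through `convert_force_units()` for
MD-engine output.

## The bead-spring AR model

`spring_model()` represents the AR region as `n_chains` helical chains of
`n_beads` beads (one bead per repeat), C4-arranged about z, each chain
anchored by a harmonically restrained head bead (the LH anchor, default
stiffness 100 pN/nm, reaction forces recorded) with the external force
applied to the terminal bead. Defaults are the studied conditions: 4
chains × 29 repeats, relaxed span `n_beads × rise` = 15.0 nm, per-chain
stiffness 3 pN/nm, forces on the 1–5 pN scale, and a flat-bottom lateral
confinement (radius 3 nm, stiffness 166 pN/nm = 100 kJ·mol⁻¹·nm⁻²) on the
force-bearing terminal beads.

Consecutive beads are connected by springs that are **harmonic in the
displacement of the bond vector from its relaxed reference** (the
elastic-network form), with per-bond stiffness `n_beads × k_chain`. This
choice is deliberate: a chain of springs harmonic in bond *length* is not
Gaussian — at 300 K the radial-shell entropy stretches each soft bond and
dresses the effective stiffness, so the generator's nominal `k_chain`
would not be the true stiffness it generates, and the chain additionally
needs bending terms to avoid folding under thermal noise. The
displacement-vector network is exactly Gaussian, so series composition
gives an end-to-end stiffness of exactly `k_chain` in every direction at
any temperature: the generator's ground truth is exact, which is what a
parameter-recovery test needs. The trade-off is that the harmonic network's
force response is achiral — the supercoil twist shapes the geometry, not
the force field — so an emergent torque under axial load is outside this
toy's scope; torque analysis is validated on constructed force/point
fixtures instead.

Dynamics are overdamped (first-order) Langevin,
`dx = (F/γ)dt + √(2kBT dt/γ) ξ`, integrated in compiled code with R-seeded
noise: only steady-state and propagation observables matter here, so
inertial dynamics would add cost without information. The friction
coefficient γ (default 1 pN·ps/nm) is a model constant, not a fit to any
physical solvent: it sets the relaxation clock. With the defaults the
end-to-end length autocorrelation time is ≈7 ps, so runs of a few ns
contain hundreds of independent samples. Because the network is linear,
the Euler–Maruyama mean is exact at any stable step; the default
`dt = 0.004 ps` keeps the stiffest mode (bond Laplacian, ≈350 pN/nm) well
inside the stability region. A diagnostic abort triggers if any bond
reaches 10× its reference length.

**Problem sizes.** The spring parameter-recovery analyses use a free
4-chain run of 16 ns (4×10⁶ steps), forced runs of 8–16 ns per force
(longer at 1–2 pN where the response is smallest relative to the thermal
end-to-end fluctuation of σ ≈ √(kBT/k) ≈ 1.2 nm per chain), and 16 ns
single-chain runs. These lengths were chosen from the measured
autocorrelation time so that the standard error of each Δz estimate sits
well below the 15% recovery band; they are the package's own convergence
choice.

## Pore-radius profiles

`pore_profile()` computes, per z slice, the largest-inscribed-sphere
radius: the maximum over in-plane probe centres c of
`min_i(‖p_i − c‖ − vdW_i)`, over atoms within a slab of half-width
`z_step` (default 0.5 Å) around the slice — overlapping slabs avoid
empty-slab artifacts. The in-plane maximisation is a gradient-free pattern
search (8 directions, step halving from 1 Å to 0.05 Å) seeded at the
previous slice's centre, on-axis at the first slice. This is HOLE-like in
spirit; for near-axial channel pores the local search is adequate and
deterministic, and the profiler recovers constructed cylinder radii within
0.1 Å across 0.5–10 Å (tested). Radii beyond 15 Å are flagged unbounded
(membrane-less slabs), negative maxima are clamped to zero and flagged
occluded. Van der Waals radii default to a Bondi-style table
(`vdw_radii()`, config-overridable); hydrogens participate when present.
`backbone_only = TRUE` restricts the selection to N/CA/C/O, which can only
widen the profile (fewer obstacles) — the all-atom vs backbone comparison
distinguishes side-chain from backbone dilation. Ties in
`min_radius_near()` resolve to the smaller z.

## Sharp-change filter and PCA

Monitored distance series (e.g. TM–AR29 centre-of-mass distance) are
filtered by the discard-after-sharp-change rule: baseline mean and SD from
the first 10% of frames (at least 5), change = first index where the
deviation exceeds 5 baseline SDs for ≥3 consecutive frames, retention =
strictly before that index. The rule is inherently
qualitative; the 5σ/3-frame/10% defaults are exposed configuration, and a
zero-variance baseline falls back to an absolute threshold with a warning.
The filter is idempotent on retained prefixes (tested).

PCA is the covariance eigendecomposition of superposed coordinates,
computed through the thin SVD of the centred frame matrix; frames are
expected to be concatenated post-filter and rigidly superposed (Kabsch,
proper rotations only — mirror inputs keep a nonzero RMSD rather than
silently reflecting). Cα coordinates of the moving domain are the intended
selection, the standard essential-dynamics choice. Eigenvector signs are
arbitrary; when group labels exist (free/push/pull),
`positive_group` fixes each component's sign so the designated group's
mean projection is non-negative, matching the convention that larger
gating-component values correspond to more dilated states. Extreme
structures are the frames with minimal/maximal projection; ties resolve to
the earlier frame.

## Domain axes and tilt/rotation angles

A domain's axis is the dominant principal axis of its Cα coordinates. The
tilt angle is the change, relative to the reference frame, of the angle
between the axis and z; the rotation angle is the signed angle between the
XY projections of the current and reference axes. Positive rotation =
clockwise viewed from −z (the intracellular side); the torque sign in the
mechanics module is tied to the same convention, so a positive torque
drives the gating-direction rotation. Frames are first superposed on an
immobile reference selection (e.g. the TM core). The axis sign is fixed by
a reference direction where that is decisive (|dot| ≥ 0.1) and by
continuity with the previous frame otherwise; an axis parallel to z leaves
the rotation undefined and is reported NA. These operations exactly invert
the rigid-rotation fixture generator (tested to 10⁻⁶ degrees). Note the
axis is only well-defined when the selection's leading principal component
is well-separated — a C4-symmetric multi-chain selection has a nearly
degenerate covariance and no meaningful single axis; use one chain's
domain.

## Spring constants, torque, transfer speed

`spring_constant()` implements k = F/Δz with Δz the difference of
equilibrated mean region lengths between a free and a forced run, where
the region length is the z-projection of the head–tail separation (the
force acts along z; a projection convention is needed and this matches the
force axis). Stationarity gate: the last half of each series must have a
split-half mean drift below 0.5 SD; the equilibration window is that last
half. Uncertainty comes from block averaging (5 paired blocks). Responses
below a 0.05 nm resolution floor raise an "inelastic/no response" error
rather than returning an unstable quotient. `elastic_range_scan()` calls
the response elastic when the relative spread of k across forces stays
under 25% (config).

`planar_torque()` projects time-averaged per-chain reaction forces onto
the membrane plane and sums per-chain contributions τ_z = (r × F)_z at the
mean application points (r relative to the pore axis, reported in pN·nm).
Because each chain's contribution is a rotation-invariant scalar, the
total is the plain sum whether or not the C4 symmetrization is applied;
symmetrization averages the four chains' force vectors after rotation into
a common quadrant and is what zeroes the reported net planar force for
C4-consistent input.

Force-transfer onset is the first time the difference between a free and a
perturbed reaction-force trace exceeds 3 baseline SDs of the difference
for ≥5 consecutive samples (defaults; deviation onset is by nature a
judgement call, so these thresholds are configuration), at 10 fs sampling. Transfer speed is
v = L/t̄ over replica onsets with first-order error propagation. The
synthetic fixtures impose the delay directly (a step response delayed by
L/v): a bead-spring's emergent signal speed depends on friction and mass
choices that nothing in the reduced model constrains, so speed recovery is
validated against an imposed ground truth rather than an emergent one.

## Permeation counting

A crossing is a complete two-plane traversal of the pore cylinder: an ion
must pass from beyond one boundary plane to beyond the other with its
radial distance inside the cylinder radius for every frame spent between
the planes; re-entries without completion never count. This is the
strictest convention — conclusions rest on complete permeation events
only. Periodic z-jumps are unwrapped by minimum image before testing;
wrapped-looking jumps without box information raise an error rather than
silently miscounting. A slab skipped within one frame step counts as a
crossing only if the unwrapped displacement actually points through it
(excluding periodic boundary jumps). Currents are I = Δq/Δt with Δq the
signed transferred charge over the full analysed duration and events
attributed to their exit time; conductance is C = I/U. The detector is
validated exactly against the drifting-ion generator's ground-truth log,
which applies the same event definition during generation.

## Hydrogen bonds

The geometric criterion defaults to donor–acceptor heavy-atom distance
≤ 3.5 Å and donor–H–acceptor angle ≥ 120° — the common geometric standard;
the criterion is configuration and recorded in outputs because no single
standard exists. Boundaries are inclusive (within 10⁻⁹ numerical
tolerance). For structures without hydrogens (cryo-EM models) the angle
condition is dropped — a strict relaxation (tested). When a structure does
carry hydrogens, only H-bearing N/O atoms donate. Residue-level pairs use
the any-atom-combination rule in both donor directions, because interfaces
are reported at residue resolution. Occupancy is the fraction of bonded
frames; "stable" means occupancy ≥ 0.7 (config). The default TRP–LH pair
set is W1572–S1421 (backbone acceptor — the serine side chain is not
involved, and the report carries backbone/side-chain attribution),
Q1253–S1577, K1244–E1571 and D1236–R1581; atom-level pairings beyond the
first two are configuration and overridable.

## The synthetic closed-state model

`synthetic_channel_model()` is a deterministic geometric stand-in for a
closed-state tetrameric channel, used by the structure-dependent analyses
and tests: an S6-like pore lining whose side-chain wall narrows to an
accessible radius of 0.6 Å at residue 1554, a TRP–LH/S4–S5 interface with
three of the four named pairs in bonding geometry and Q1253–S1577 held
5.5 Å apart, and a 29-repeat ankyrin Cα trace spanning 15 nm — all by
construction, with no hydrogens, as in a typical cryo-EM deposition. It
validates the machinery end to end (selection resolution, profiling,
census, extent measurement) but is not a model of any deposited
coordinates; analyses of a real structure should be run on the deposited
PDB file with a domain map for its numbering. Residue ranges are always
user configuration — the package hard-codes no domain boundaries.

## What passing tests do and do not show

The generators emulate known-truth geometry and exactly Hookean mechanics
with uncorrelated Gaussian noise. Real MD data differ in essentially every
inconvenient way: anharmonicity and slow conformational drift, correlated
solvent forces, ions with finite size and hydration shells, protonation
ambiguity in hydrogen-bond typing, and domain axes that deform rather than
rotate rigidly. Passing the suite therefore shows the analyses are
implemented correctly — estimators recover constructed truths at stated
tolerances — not that any specific biological number is reproduced.
Quantities that require the original MD trajectories (absolute spring
constants of a real AR supercoil, its torque, its conductance) are outside
what synthetic validation can certify.

## Known limitations

* The harmonic bead-spring toy cannot exhibit emergent chiral torque or an
  emergent force-transfer speed; both are validated on constructed
  fixtures.
* The pore profiler's local pattern search assumes a near-axial pore; a
  strongly kinked channel would need a curved-axis extension.
* Angle series for nearly z-parallel or axis-degenerate selections are
  reported NA / are unreliable by construction, respectively.
* The permeation detector assumes ion step sizes below half the box height
  between saved frames; sparser saving risks misclassified boundary jumps.
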