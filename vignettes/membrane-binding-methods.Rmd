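---
title: "Methods: models, estimators and design choices in membind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in membind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`membind` implements the analysis protocol of ensemble coarse-grained
studies of peripheral protein–membrane binding: encounter kinetics,
orientation-density binding-mode analysis, umbrella-sampling/WHAM
potentials of mean force (PMFs), alchemical free-energy perturbation (FEP)
of PIP₂ head groups, lipid contact/clustering statistics, and the
FEP-vs-ΔPMF internal consistency check. It does **not** run molecular
dynamics: the MD engine is replaced by a rigid-body Brownian-dynamics toy
model whose ensemble statistics have the same structure as the real data
and whose free energies are exactly computable, so that every estimator can
be validated against ground truth.

# The toy model

**Geometry.** A rigid body of n ≥ 4 non-coplanar beads (body frame centred
on the COM) above a planar bilayer at height `plane_z`. Only the
protein-facing (upper) leaflet is explicit: head groups are 2D points in a
periodic box (default 7 × 7 nm, 80 lipids/leaflet; the canonical anionic
composition PC:PS:PIP₂ 80:15:5 gives 64/12/4 per leaflet by
largest-remainder allocation, i.e. 8 PIP₂ per bilayer). The built-in
`c2_body()` preset mimics a C2 domain: three +1e "basic" beads form a
membrane-binding loop face, two −1e "terminus" beads cap the opposite face.

**Energetics.** Bead–lipid interactions are screened Coulomb
u(r) = qQ·B·e^(−r/λD)/max(r, r_core) with xy minimum image and lipid z at
the plane; a soft exponential wall A·e^(−z/w) per bead keeps the body above
the plane; an optional harmonic upper wall at 7 nm (k = 50 kJ mol⁻¹ nm⁻²)
confines the unbound body during encounter runs, and head-group charges are
PC 0, PS −1, PIP₂ −5 e. In mean-field mode the leaflet is a uniformly
charged plane, U_i(z) = 2π σ q_i B λD e^(−z/λD) per bead — the closed-form
limit of the explicit model.

**Parameters (units nm, ps, kJ/mol, K; k_B = 0.0083145).**

| parameter | default | rationale |
|---|---|---|
| temperature | 323 K | the standard production temperature of the emulated protocol |
| λD (Debye) | 1.1 nm | the electrostatic cutoff scale of the emulated CG force field |
| B (Coulomb prefactor) | 138.935/100 | effective interfacial dielectric ≈ 100, chosen **once** so bound-state per-PIP₂ free energies land on the 4–21 kJ/mol scale reported for CG protein–PIP₂ FEP; a bare CG dielectric (≈15) gives pair energies far too large when head charges are point-like |
| r_core | 0.47 nm | CG bead contact distance (excluded volume cap) |
| wall | A = 200, w = 0.05 nm | steep enough that the bound-pose well position barely shifts as PIP₂ are decharged (keeps the FEP-vs-ΔPMF identity tight); soft enough that bound basic beads sit ≈ 0.3–0.45 nm above the plane, inside the 0.5 nm contact criterion |
| diffusion D_t = D_r = D_lip | 0.01 | toy-scale mobilities: encounter, binding and lipid clustering equilibrate in nanoseconds of model time (seconds of wall time) |
| timestep | 0.05 ps | Euler–Maruyama stability against the steep wall; the integrator raises an error if any drift step exceeds 0.5·λD |

**What the toy reproduces** (and the tests verify): reversible binding on
zwitterionic membranes, stronger binding with PS, quasi-irreversible
binding with PIP₂ (well depths ≈ 0 / 4–10 / 30–40 kJ/mol); PIP₂ clustering
under the bound basic face with all four upper-leaflet PIP₂ bound at
equilibrium while PS and PC do not cluster; per-PIP₂ decharging free
energies of ≈ 8.5 kJ/mol. **What it does not have:** lipid–lipid
interactions (lipids are ideal), solvent, bending/curvature, cholesterol
ordering, atomistic contact chemistry, and any non-electrostatic
protein–lipid attraction (so pure-PC well depths are ~0 rather than the
8–30 kJ/mol of real force fields). A green test therefore establishes the
correctness of the *estimators and protocol logic*, not force-field realism.

**Ideal lipids make the model exactly solvable.** With no lipid–lipid
forces the z-profile factorises over lipids:
G(z) = wall(z) + Σ_s n_s·(−kT)·log⟨e^(−u_s(z,xy)/kT)⟩_box, evaluated by 2D
midpoint quadrature (`ideal_lipid_pmf()`); the mean-field profile is
`analytic_pmf()`. These oracles generate umbrella-window and λ-window
samples by inverse-CDF sampling on fine grids with an
independence-Metropolis correction against the exact density, so the
estimators under test receive statistically exact i.i.d. input. This is a
deliberate substitution for time-correlated biased dynamics: it removes
autocorrelation as a confounder when validating WHAM/BAR/MBAR. The
equilibration-skip plumbing is still exercised (flagged samples are
dropped), but a green equilibration test does not establish correct
handling of genuinely non-stationary data.

# Estimators

**WHAM.** Standard self-consistent iteration in kT units over window shifts
f_i and unbiased bin probabilities, tolerance 1e-7 kT on the shifts,
max 1e5 iterations. Numerical choices: default bin width 0.05 nm (the
window spacing); near a steep repulsive wall the bias varies strongly
within such a bin and a finer width (0.01 nm) should be used — the
acceptance checks do. Bins with fewer than `min_counts = 5` pooled samples
are reported as unoccupied: single-sample tail bins otherwise produce
spurious free-energy dips. The profile zero is anchored to the
**count-weighted** mean over the outermost 0.5 nm of the occupied range;
an unweighted mean lets near-empty tail bins inject O(1) noise into the
offset and visibly breaks the 1/√n error scaling. Errors are a
window-level bootstrap (resample each window's production samples,
re-solve, per-bin SD; 50 replicates default). The well depth is −min G
under this anchoring (the far-separation zero is implied by the plots of
the emulated protocol; its exact printed definition was not available), and
a profile whose minimum is shallower than 1 kJ/mol or sits at the boundary
raises a no-well error rather than reporting noise.

**BAR/MBAR.** `bar_pair()` solves the Bennett/logistic self-consistency
Σ_F φ(−(M+w_F−Δf)) = Σ_R φ(M−w_R−Δf) by bracketing; variance is the
standard Fermi-weight expression, and the overlap diagnostic is the mean
Fermi weight (error below 1e-6). `multistate_free_energy()` iterates the
MBAR self-consistency on the full reduced-potential matrix with
log-sum-exp stabilisation; asymptotic errors come from the SVD form of the
weight-matrix covariance. Both estimators are cross-checked against each
other and against closed-form/quadrature oracles; MBAR is the default (as
in the emulated protocol) with the BAR chain as the independent route.

**The λ ensemble.** The tagged PIP₂ head charge is scaled to (1−λ)Q over 21
evenly spaced states ("20 steps"). Two bound-ensemble conventions exist:
body pinned at a pose (used for oracle tests), and — the default in
`run_fep()` — the body height z sampled alongside the tagged lipid's xy, as
an unrestrained bound protein would relax. The z-relaxing convention is
what makes the summed FEP match ΔPMF tightly: with the body pinned at the
PIP₂-membrane minimum, the end-state well sits ≈ 0.1 nm higher and the
comparison inherits an O(10 kJ/mol) mismatch from evaluating the end-state
profile off its minimum. Each of the four upper-leaflet PIP₂ is converted
individually with the others kept fully charged; per-lipid values are
means over 5 independently seeded repeats and the total error is the SD of
the per-repeat totals. Counterion bookkeeping is implicit (the screened
potential needs no explicit ions): the number of monovalent ions to
neutralise each transformation (5 for PIP₂ → PC) is computed and reported.

**The consistency check.** The toy's ΔPMF compares the PIP₂ membrane with
its exact alchemical end state (upper leaflet 85:15 after converting the
four PIP₂) rather than a separately built 80:20 membrane, making the check
a clean thermodynamic-cycle identity up to well-shape entropy (≈ 0.4
kJ/mol by quadrature at the default parameters). The report flags
|FEP − ΔPMF| ≤ 2σ (combined in quadrature). Because the structural gap is
real and the errors are sub-kJ/mol, individual seeds can land marginally
outside 2σ with ≈ 10 % probability — that is a property of the check, not
a defect of either estimator.

# Orientation analysis

R_zz is the (3,3) element of the proper Kabsch rotation (COMs removed,
det +1 enforced) from the reference bead coordinates to the frame's.
Because only the zz element is read, R_zz is invariant to any extra
rotation about the membrane normal applied before or after — the xy
pre-fitting of the original tooling is a no-op for rigid bodies, asserted
as a test. The initial reference is the last frame of the first repeat;
after mode detection all values are recomputed against the primary mode's
representative frame (which maps to R_zz = 1 by construction) and the same
reference serves the sister membranes. Density maps use 0.1 nm × 0.05 bins
(the source figures state no binning; these resolve the mode structure at
toy ensemble sizes), normalised to unit mass, log-transform at rendering
only. Modes are 8-neighbourhood local maxima among cells with ≥ 2 % of
frames and distance below a bound; frames are assigned to the nearest
centre in bin-scaled coordinates. "Probable" is occupancy ≥ 2 % (the
original analysis identified modes by eye; a numeric threshold makes it
reproducible); "physical"/"productive" are user-supplied bead-label height
predicates evaluated on the representative frame. Refinement trajectories
are classified unbound if the minimum protein–lipid distance exceeds
1.5 nm for ≥ 5 consecutive frames, else rotated if the geodesic angle
acos((tr R_rel − 1)/2) versus frame 0 ever exceeds 45°, else retained; the
45°/1.5 nm thresholds are package decisions (the source defines the
categories pictorially, and its orientation-change metric is never given a
formula — the geodesic angle is the canonical choice).

# Kinetics

Contact is min bead–lipid distance < 0.5 nm (3D, xy minimum image, lipid z
at the plane; for mean-field bilayers the bead–plane distance). Unbinding
uses hysteresis — the trace must exceed 1.0 nm for ≥ 5 frames — because
the emulated protocol thresholds contacts but never states an unbinding
criterion, and frame-level chatter otherwise fragments events. Ensemble
averaging linearly interpolates to a common grid. The decay fit
d(t) = d∞ + (d₀−d∞)e^(−t/τ) profiles the amplitudes out by linear least
squares and optimises τ on a log scale over [span/1000, 100·span]; a τ
pinned at the search boundary (e.g. a constant trace) is reported
unconverged. The 3-parameter form is itself a decision — the source states
exponential fits without a formula.

# Degenerate inputs and numerical edges

Collinear beads → degenerate-geometry error (Kabsch undefined); fractions
not summing to 1 or negative → composition error; λ outside [0,1] → range
error; non-PIP₂ alchemical tags → invalid-tag error; disconnected umbrella
chains name the gap; non-convergence of WHAM/MBAR reports the residual;
adjacent windows without histogram overlap warn (not error) at generation
time. Trajectory containers are plain text (CSV frames + JSON metadata,
17 significant digits: round-trips are lossless to < 1e-12).

# Test-suite scaling

Acceptance-style checks run the stated protocol constants (0.05 nm window
spacing, k = 2000, 21 λ states, 5 FEP repeats, 323 K) but scale ensemble
sizes down to fit desk budgets: encounter ensembles use 8 repeats × 16 000
steps rather than 25 × (2 μs-equivalent), window samples 4–5 × 10³, and the
clustering run 80 000 lipid steps. The ordering and recovery margins are
large relative to these sizes (e.g. fraction-bound ratios of ~10× between
membranes), so the scale-down does not sit near any threshold.
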