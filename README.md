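# membind

Quantitative analysis of how peripheral membrane-binding protein domains —
the motivating case is the C2 domain, a β-sandwich module that docks onto
anionic plasma-membrane leaflets — associate with lipid bilayers. The
package bundles the full analysis chain used in ensemble coarse-grained
studies of protein–membrane encounter:

* **Encounter kinetics** — minimum protein–lipid distance traces, bound /
  unbound event segmentation with hysteresis (contact defined as distance
  < 0.5 nm), ensemble averaging, and exponential decay fits
  d(t) = d∞ + (d₀ − d∞)·e^(−t/τ).
* **Binding-mode analysis** — the orientation statistic R_zz (the zz element
  of the least-squares Kabsch rotation relating each frame to a reference
  structure; R_zz = 1 is the reference orientation, −1 a 180° flip), pooled
  (distance, R_zz) density maps, grid-based mode detection, re-referencing
  to a primary mode, and probable / physical / productive mode scoring.
* **Potentials of mean force** — a from-scratch WHAM solver for harmonic
  umbrella windows along the protein–membrane COM separation (standard
  protocol: windows every 0.05 nm, k = 2000 kJ mol⁻¹ nm⁻², 323 K), with
  window-level bootstrap errors, well depths and well-depth differences
  (ΔPMF) between membrane compositions.
* **Alchemical free energies** — Bennett acceptance ratio (BAR) and
  multistate (MBAR) estimators for PIP₂ → PC head-group decharging over a
  21-state λ schedule, bound-minus-free differencing, per-lipid and total
  values over 5 independent repeats, and counterion bookkeeping (PIP₂ → PC
  frees 5 monovalent cations).
* **Lipid contacts and clustering** — per-residue-class contact
  frequencies, basic-bead/phosphate contact counts, and radial enrichment
  of PIP₂ (and PS/PC contrasts) around the bound protein footprint.
* **The internal consistency check** — converting all upper-leaflet PIP₂ to
  PC turns a PC:PS:PIP₂ (80:15:5) leaflet into PC:PS (85:15), so the summed
  FEP must match the ΔPMF between those compositions; the package computes
  both routes and flags agreement at 2σ.

Because reproducing real coarse-grained MD ensembles takes ~1 ms of
simulation, the package ships a **rigid-body Brownian-dynamics toy
simulator** with analytically known free energies: a charged bead body
(built-in C2-like preset: three +1e "basic" loop beads, four neutral core
beads, two −1e termini) above a planar bilayer of explicit 2D-diffusing
head-group charges (PC 0, PS −1, PIP₂ −5) or a mean-field charged plane.
Lipids are ideal (no lipid–lipid forces), so exact PMFs and transformation
free energies are available by quadrature — every estimator is tested
against ground truth.

## Worked example: two views of the binding energetics

```r
library(membind)
body   <- c2_body()
params <- sim_params()

bil_pip2 <- build_bilayer(80, c(PC = 0.80, PS = 0.15, PIP2 = 0.05), seed = 103)
bil_end  <- build_bilayer(80, c(PC = 0.85, PS = 0.15), seed = 104)

centers <- seq(0.75, 4.0, by = 0.05)
ws <- wham_settings(bin_width = 0.01, temperature = 323,
                    n_bootstrap = 30, seed = 105)
depth <- lapply(list(pip2 = bil_pip2, end = bil_end), function(bil) {
  st  <- system_state(body, bil, c(3.5, 3.5, 2))
  win <- generate_umbrella_windows(st, params, centers, force_constant = 2000,
                                   n_samples = 4000, n_equil = 400, seed = 106)
  well_depth(bootstrap_pmf(win, ws))
})
dp <- delta_pmf(depth$pip2, depth$end)

st_bound <- system_state(body, bil_pip2, c(3.5, 3.5, depth$pip2$z_min))
fep <- run_fep(st_bound, params, n_states = 21, n_samples = 300,
               n_repeats = 5, seed = 107)
fep_pmf_consistency(fep, dp)
```

Output (about 1 minute on one CPU):

```
PMF well depth (PC:PS:PIP2): 37.7 +/- 0.5 kJ/mol at z = 0.98 nm
PMF well depth (end state):  3.5 +/- 0.4 kJ/mol
delta-PMF: 34.2 +/- 0.7 kJ/mol
per-lipid FEP: 8.6, 8.6, 8.5, 8.5 kJ/mol
total FEP: 34.2 +/- 0.2 kJ/mol (sodium converted per lipid: 5)
FEP vs delta-PMF: discrepancy 0.07 kJ/mol (2 sigma = 1.36) -> consistent: TRUE
```

Reading: binding to the PIP₂-containing membrane is ~38 kJ/mol deep and
quasi-irreversible, binding to the PIP₂-free end state only ~3.5 kJ/mol;
the four bound PIP₂ each contribute ~8.5 kJ/mol (the printed per-lipid
range in comparable coarse-grained studies is 4–21 kJ/mol), and the two
independent routes to the PIP₂ contribution — ΔPMF from umbrella sampling
and total FEP from alchemical decharging — agree within error.

## Layout

`R/` implementation (simulator, kinetics, orientation, WHAM, FEP, contacts,
pipeline); `tests/testthat/` unit/property tests plus
`test-acceptance.R` implementing the acceptance criteria;
`vignettes/membrane-binding-methods.Rmd` the methods notes (model,
parameter choices, what the toy does and does not establish).
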