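---
title: "Methods: binding-mode, interaction and affinity analysis of cardiotonic steroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-mode, interaction and affinity analysis of cardiotonic steroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsbind)
```

# Scope and model

Cardiotonic steroids (CTS) — bufadienolides such as bufalin and
cardenolides such as digoxin — inhibit Na⁺,K⁺-ATPase by occupying a
binding site between the transmembrane helices of the E2P phosphoenzyme.
`ctsbind` implements the analysis layer for studies that combine molecular
dynamics of such complexes with equilibrium biochemistry: it classifies
ligand poses into rotational binding modes, quantifies per-mode
hydrogen-bond interactions, fits lactone–ion distance distributions,
measures pose stability and sugar-site localization, and fits the
equilibrium-binding and force-field models used around such simulations.
It does **not** run molecular dynamics, docking, structure preparation, or
quantum-chemical scans; trajectories and energy tables are inputs.

## The rotational binding-mode taxonomy

The steroid core sits roughly upright in the site, and its *β-surface*
(the face carrying the C18/C19 methyl groups) can point toward different
helices. Four rotational states are distinguished by the helix the
β-surface faces: **BM0** → αM2 (the crystallographic pose), **BM1** → αM1,
**BM2** → αM4, **BM3** → αM6.

The classifier reduces each frame to one angle. With the membrane normal
as *z* (extracellular positive, as in OPM-aligned systems), the long axis
of the core is its largest-variance principal axis, sign-oriented from the
C3 end to the C17/lactone end so rotation angles have a reproducible sign.
The β-vector runs from the core centroid to the β-methyl centroid, is
orthogonalized against the long axis, and projected into the membrane
plane. The rotation angle φ is the signed angle from the αM2 in-plane
direction to this β-vector, counterclockwise when viewed from the
extracellular side, in (−180°, 180°]. Helix directions themselves come
from a configured reference frame: the site origin is the centroid of
configured site atoms and each helix contributes the in-plane unit vector
toward its Cα centroid.

Two assignment methods are provided. `nearest` (default) labels a frame
by the mode helix with maximal cosine to the β-vector; exact ties break
toward the lower BM index, and an optional `min_cos` leaves ambiguous
frames unassigned (off by default, because four directions tile the
circle). `cluster` first fits a wrapped-Gaussian mixture to φ (component
count by BIC, capped at four) and labels each cluster by the helix nearest
its circular mean; this recovers a state straddling ±180° as one cluster.
Location along *z* is deliberately **not** mixed into the classifier; it is
reported separately by the stability series, so the two signals can be
interpreted independently.

Helix residue ranges are configuration, not code: transmembrane
boundaries differ between constructs and numbering schemes, so the
package never hard-codes them. Which atoms anchor trajectory alignment is
equally a choice; this package uses the Cα atoms of the configured
αM1–αM6 ranges (`helix_ca_labels()`), superposing every frame onto the
topology coordinates with a proper-rotation Kabsch fit (reflections are
never returned; the smallest singular direction is flipped when needed).

## Interaction prevalence

Hydrogen bonds are detected per frame per candidate (ligand-group,
residue) pair. The geometric criteria are configurable because no single
convention is universal; defaults are donor–acceptor ≤ 3.5 Å and
D–H–A ≥ 150°, with a distance-only fallback when hydrogens are absent
(coarse models and the synthetic systems used for validation carry no
hydrogens). The prevalence matrix reports, for each pair and each binding
mode, the bonded fraction *within that mode's frames only*; repeats are
pooled frame-by-frame, and modes occupying ≤ 5% of the pooled simulation
time are dropped from the matrix — rare modes yield prevalences too noisy
to interpret. These occupancy fractions act as a proxy for the enthalpic
side of binding; entropic contributions are out of scope.

## Lactone–ion distances and mixtures

Direct coordination between the lactone and the cation in transport site
II is diagnosed from the per-frame distance between a lactone oxygen and
the ion (the representative atom is configurable; the default is the
lactone oxygen nearest the ion, since conventions differ on which atom to
quote). Distances are pooled per binding mode and fitted with 1-D
Gaussian mixtures by EM: k = 1..4, ten restarts per k with
quantile-anchored means, convergence at 1e-8 on the log-likelihood
(monotonicity asserted at every step), at most 500 iterations, and a
standard-deviation floor of 1e-3 Å preventing component collapse. The
component count minimizes BIC = p·ln n − 2·lnL with p = 3k − 1; ties go to
the smaller k. The bound component is expected near the optimal
coordination distance — about 2.8 Å for K⁺ and 2.1 Å for Mg²⁺ — and the
synthetic generator plants its mixtures there by default.

## Stability and sugar sites

Pose stability is summarized by two per-frame series after alignment:
tilt (angle between the core long axis and the membrane normal, 0–180°)
and vertical displacement (z-shift of the core centroid relative to frame
one). Sugar-site localization clusters the in-plane position of the
para-hydroxyl oxygen of a sugar moiety with k-means (k = 2, ten starts,
seeded); centroids closer than 1.5 Å merge into one site, which handles
one-site ligands with a fixed k. The higher-occupancy site is labeled X,
the other Y, matching the empirically two-site picture seen for
N-glycosylated bufalin. Modes with fewer than 20 frames are skipped.

# Equilibrium-binding models

When enzyme and ligand concentrations are comparable, free ≠ total ligand
and the bound-enzyme fraction follows the Morrison ("square-root")
single-site solution,

$$\theta = \frac{(E+L+K_d) - \sqrt{(E+L+K_d)^2 - 4EL}}{2E},$$

evaluated in its conjugate form \(2L/(S+\sqrt{S^2-4EL})\), \(S=E+L+K_d\),
which is stable near the discriminant root. Percent inhibition is
amplitude × bound fraction, with the amplitude fixed at 100% by default
(assay saturation is rarely known; it can be fitted on request).
Heterogeneous, biphasic inhibition — coexisting fast- and
slow-dissociating complexes — is modeled as enzyme species with distinct
\(K_d\) sharing the free-ligand pool; the shared free concentration is
found by bracketed root finding polished with Newton steps. One- and
two-species fits are compared by AIC; \(K_d\) is log-parameterized, the
species split logit-parameterized, and confidence intervals come from a
seeded case-resampling bootstrap (default 1000 resamples). Fits are
unweighted by default, with optional inverse-variance weighting
(\(w = 1/y^2\)) — the efficient choice when readings have a constant
coefficient of variation. Data too flat to constrain any \(K_d\) are
flagged `non_binding` rather than raising an error. Whether the two
phases of a heterogeneous fit share their amplitude is not standardized;
here both species share one amplitude, and the functional form of the
literature "square-root equation" is fixed to the Morrison quadratic
above.

## AO competition and relative affinity

Relative affinities come from displacement of anthroylouabain (AO), a
fluorescent ouabain derivative. Enzyme (0.1 µM) is incubated to
equilibrium with equimolar AO and competitor X (0.2 µM each); the free-AO
reference reading comes from a sample with 1 mM unlabeled ouabain. With
\(f = (F_\mathrm{mix}-F_\mathrm{ref})/(F_\mathrm{AO}-F_\mathrm{ref})\)
the residual AO-specific fraction, the estimator is

$$\frac{K_X}{K_\mathrm{AO}} = \frac{X_\mathrm{tot}}{\mathrm{AO}_\mathrm{tot}}
\cdot \frac{f}{1-f},$$

so a 50% fluorescence decrease at equal totals means equal affinities.
The estimator uses total concentrations; it is exact in the
excess-over-enzyme regime and its bias at finite totals can be checked
against the package's exact two-ligand competition solver (bracketed root
finding on free enzyme), which is also what the synthetic reading
generator uses. Readings with essentially no or complete displacement are
reported as censored bounds (default detection limit f = 0.02 from
either end) instead of infinite or zero ratios. Overnight incubations
are treated as equilibrium; no kinetic modeling is attempted.

# Dihedral-term fitting

Torsional force-field terms follow the CHARMM convention
\(V(\varphi) = \sum_n k_n\,(1+\cos(n\varphi - \delta_n))\) with integer
multiplicities, \(k_n \ge 0\) and \(\delta_n \in \{0°, 180°\}\). Targets
are energy scans over ±180° in 10° steps (the difference of a QM scan and
the unfitted-MM baseline, supplied as tables — no QM is run here). Scans
of the same dihedral share terms; each scan keeps a free constant offset.

With both phases in the dictionary plus free offsets, the CHARMM basis is
an exact linear reparameterization of \(c_n\cos(n\varphi)\) plus a
constant: a negative \(c_n\) is a 180°-phase term with \(k=|c_n|\). The
fitter therefore solves ordinary least squares in the cosine basis and
converts signs to phases — the unique-energy solution of the equivalent
(rank-deficient) nonnegative problem, deterministic and convex. Only when
the caller restricts the phase set does an active-set nonnegative solve
run instead. Terms with \(k\) below 1e-3 kcal/mol are pruned and the
system refit; the reported RMSE pools all grid points of all scans (a
convention choice; per-scan RMSEs are available from the residuals).
Fitted parameters serialize to a CHARMM parameter-stream `DIHEDRALS`
block.

# The synthetic-data generator

Every validation closes a loop: a generator with known ground truth
produces inputs, the analysis recovers them. `generate_system()` builds a
pseudo-protein of straight Cα helices on a 12 Å circle at configured
azimuths (defaults place αM2/αM1/αM4/αM6 at 0/90/180/270°; real
structure-derived azimuths may replace them, and any two azimuths closer
than 20° are rejected as ambiguous), plus a rigid steroid-core template
whose β-methyls mark one face. Per frame: the mode follows a Markov chain
(the convenience `sticky_transition_matrix()` has any prescribed
stationary distribution); the core rotates to the mode helix's azimuth
plus wrapped-Gaussian jitter (default sd 15°), tilts by Gaussian noise
(default sd 5°) about a random in-plane axis and shifts vertically
(default sd 0.5 Å); each configured contact is "on" by a Bernoulli draw at
the mode's prevalence, placing the partner atom at U(2.6, 3.3) Å when on
and U(4.5, 8) Å when off — straddling any sane hydrogen-bond cutoff; the
site-II ion sits at a mixture-distributed distance from the lactone
oxygen (bound component at 2.8 Å by default, unbound at 6–8 Å); and a
sugar-marker atom falls in planted per-mode 2-D Gaussian sites (4 Å
apart, sd 0.5 Å, major-site occupancy 0.65–0.7 so the X/Y ordering is
well defined). Contacts sharing a residue get separate partner atoms so
their states stay independent. One global seed fans out to fixed
per-stream sub-seeds, so adding a stream never perturbs existing ones and
equal seeds give byte-identical output.

Assay generators invert the fitted models: inhibition datasets come from
the equilibrium solver with, by default, multiplicative Gaussian noise (a
constant CV, as activity readings typically show; additive noise is
available), and competition readings from the exact two-ligand solver
with `F = baseline + span × bound-AO fraction`. The competition generator
needs an absolute \(K_\mathrm{AO}\) scale (default 1e-4 µM = 0.1 nM, the
reported order of AO's affinity for the phosphoenzyme); the 50%-decrease
identity is exact only in the strict tight-binding limit, and holds to
about 0.1 percentage points at that default. Torsion-profile generation
evaluates a known term set plus offset and Gaussian noise.

**What the generator does not emulate:** there is no force field and no
integrator; frames are statistical emulations. Protein atoms beyond the
helices do not move; hydrogens are absent (so detection runs
distance-only); periodic-boundary artifacts, solvent, membrane and
conformational coupling between observables do not exist. Passing the
recovery suites therefore demonstrates correctness of the *analysis*
under known truth — not that real MD data are this clean. On real
trajectories, mode jitter is state-dependent, contacts correlate with
rotation, and alignment quality varies; the configurable criteria and the
unassigned/min_cos machinery exist for exactly those cases.

# Validation suite and problem sizes

The test suite ties every recovery claim to ground truth at stated
tolerances, with problem sizes chosen to keep the full suite in the
minutes range on one core:

- Kabsch: exact transform recovery (RMSD < 1e-9 Å, det +1) on noiseless
  rigid copies; independent cross-check against `bio3d::fit.xyz`.
- Morrison closed form vs an independent bisection mass-balance solver:
  max |Δ| ≤ 1e-9 over a 1000-point (E, L, Kd) log grid.
- Mode recovery: 5000-frame sticky chain (diagonal 0.9), 15° jitter —
  ≥ 98% per-frame label agreement and prevalences within 2 points of the
  generator's true-label fractions; a 4%-stationary-prevalence mode is
  dropped by the 5% filter (at a seed where its realized occupancy is
  below 5%; chain autocorrelation gives realized occupancies a spread of
  roughly ±1 point at this length).
- Interaction prevalences within 3 points of the planted values at 5000
  frames.
- Mixture/BIC: planted 2.8/6.0 Å (sd 0.2/0.5) two-component sample at
  n = 2000 selects k = 2 with means within 0.1 Å; one-component data
  select k = 1; selection accuracy grows from n = 200 to n = 2000;
  `mclust` (same parameter count for its "V" model, hence the same
  selection rule) is the independent reference.
- Inhibition recovery: 100 replicates at 5% CV and 12 concentrations
  recover \(K_d\) within 10% in ≥ 90% of runs. The study sits in the
  identifiable regime (E = 0.02 µM below \(K_d\) = 0.1 µM) with
  inverse-variance weights — under strong depletion (E ≫ \(K_d\)) the
  curve is a stoichiometric titration and no estimator can constrain
  \(K_d\), which is a property of the design, not the fitter. AIC prefers
  two species when the truth has a 100-fold \(K_d\) split.
- Dihedrals: noiseless five-scan recovery to RMSE < 1e-6 with exact term
  recovery; fitted RMSE within [0.1, 0.3] across 20 seeds at noise 0.2
  kcal/mol.
- Competition: equal affinities give a 50% AO-signal decrease; the
  estimator algebra is exact to machine precision.

`scripts/acceptance.R --seed S --out results/acceptance.json` recomputes
all of these quantities from scratch at a given seed.

# Numerical choices and known limitations

- Tolerances live in `cts_tolerances`: 1e-9 for orthonormality and unit
  norms, 1e-6 for geometric recovery, 0.1 Å for degenerate in-plane
  directions, EM tolerance 1e-8 with sd floor 1e-3 Å, dihedral pruning at
  1e-3 kcal/mol, sugar-site merging at 1.5 Å.
- Frames are assumed pre-imaged: **no periodic-boundary unwrapping is
  performed anywhere**. Coordinates are Å, times ns, concentrations µM,
  energies kcal/mol.
- Multi-model PDB is the canonical trajectory interchange format so the
  whole pipeline runs without binary-format dependencies; PDB precision
  (1e-3 Å) bounds round-trip fidelity. Insertion codes are rejected;
  first altlocs win with a warning.
- BM3 stays in every data structure even when never observed — ligands
  with occupied cation sites may simply not visit it.
- The headline per-ligand prevalence numbers of a real study (e.g. a
  dominant BM1 for β-bufalin) depend on hundreds of ns of MD sampling and
  are not reproduced here; this package validates the analysis operators
  against synthetic ground truth and applies them to whatever
  trajectories the user supplies.

# Pipeline orchestration

`run_pipeline()` drives everything from one config (YAML or list):
inputs (or a synthetic spec), stage toggles, criteria, thresholds and
seeds. Outputs are deterministic given config + seeds; a manifest records
the config, package version and collected warnings; a failing stage
aborts with its name and removes that run's partial outputs. The
`analysis/` scripts in the repository are thin numbered drivers over the
same functions and double as usage examples.
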