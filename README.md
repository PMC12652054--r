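# ctsbind

Analysis toolkit for studies of cardiotonic-steroid (CTS) binding to
Na⁺,K⁺-ATPase that combine molecular-dynamics trajectories with
equilibrium biochemistry. Bufadienolides (bufalin and its glycosides) and
cardenolides (the digoxin series) occupy a site between the transmembrane
helices of the E2P phosphoenzyme; which way the steroid core faces, which
hydrogen bonds it holds, and whether its lactone coordinates the
transport-site cation together rationalize the measured affinities. This
package provides the quantitative layer of that reasoning, for
computational biochemists who have trajectories and assay readings and
need reproducible numbers out of them.

## What it computes

- **Rotational binding modes BM0–BM3.** Each frame's steroid core is
  reduced to one angle: the in-plane direction of its β-surface
  (methyl-bearing face) relative to helix αM2, measured about the core's
  long principal axis. The β-surface facing αM2/αM1/αM4/αM6 defines
  BM0/BM1/BM2/BM3. Nearest-direction and wrapped-Gaussian-mixture
  clustering classifiers, prevalences, transition counts, dwell times.
- **Interaction-prevalence matrices.** Hydrogen-bond occupancy per
  (ligand group, residue) pair *within each binding mode*, with modes
  under 5% of total simulation time filtered out.
- **Lactone–ion distances.** Per-frame distance to the site-II cation,
  fitted per mode with 1-D Gaussian mixtures; component count by
  BIC = p·ln n − 2·lnL, p = 3k − 1.
- **Stability and sugar sites.** Core tilt and vertical displacement
  after Kabsch alignment on the αM1–6 Cα atoms; k-means clustering of the
  sugar para-hydroxyl position into X/Y sites.
- **Tight-binding affinity models.** The Morrison ("square-root") bound
  fraction ((E+L+K_d) − √((E+L+K_d)² − 4EL)) / (2E), one- and two-species
  (heterogeneous) inhibition fits with AIC comparison and bootstrap CIs,
  an exact two-ligand competition solver, and the anthroylouabain (AO)
  displacement estimator K_X/K_AO = (X/AO)·f/(1−f) from the residual
  AO-specific fluorescence fraction f.
- **Dihedral parameterization.** CHARMM cosine-series terms
  k(1 + cos(nφ − δ)) fitted jointly to ±180°/10° torsion energy scans,
  with per-scan offsets, nonnegative force constants, phases {0°, 180°},
  and CHARMM parameter-stream output.
- **Synthetic systems with ground truth.** A generator producing
  pseudo-protein trajectories with Markov-switching binding modes,
  Bernoulli contacts at set prevalences, mixture-distributed ion
  distances, planted sugar sites, and noisy assay/torsion datasets — the
  backbone of the validation suite.

## Worked example

Generate a synthetic complex with known ground truth, classify its
binding modes, and recover the planted interaction pattern:

```r
library(ctsbind)
spec  <- trajectory_spec(n_frames = 2000, seed = 42)
sys   <- generate_system(spec)
ref   <- build_reference_frame(sys$structure, sys$helix_ranges, sys$site_atoms)
trace <- classify_binding_modes(sys$trajectory, sys$groups, ref)
trace
#> binding_mode_trace: 2000 frames
#>   prevalence: BM0 27.7%, BM1 20.6%, BM2 30.8%, BM3 20.9%
mean(trace$frames$label == sys$truth$modes)
#> [1] 0.9925
```

99.25% of frames match the generator's true labels despite 15° rotational
jitter. The per-mode hydrogen-bond matrix recovers the planted
prevalences (e.g. the core hydroxyl–T797 bond at 95%/91% in BM0/BM1, the
C3-substituent contacts only in BM2):

```r
interaction_prevalence(sys$trajectory, trace, sys$pairs)
#> prevalence_matrix: 4 pairs x 4 modes (> 5% of 2000 frames)
#>                    BM0  BM1  BM2 BM3
#> hydroxyl_C14:T797 95.5 91.0  0.7 0.0
#> hydroxyl_C14:N122  0.0  7.3  3.3 0.2
#> hydroxyl_C3:Q111   9.2  0.0 35.6 0.0
#> hydroxyl_C3:N122   0.0  0.0 35.4 0.0
```

The BM1 lactone–ion distances split into a bound component at the K⁺
coordination distance and a minor unbound one, with the component count
chosen by BIC:

```r
ds <- ion_distance_series(sys$trajectory, sys$groups, trace)
mixture_fit_bic(ds$distance[ds$mode == "BM1"])
#> mixture_fit: k = 2 (BIC 150.2, n = 413)
#>   component 1: weight 0.915, mean 2.810 A, sd 0.192 A
#>   component 2: weight 0.085, mean 6.014 A, sd 0.520 A
```

On the biochemistry side: a competitor that halves the AO-specific
fluorescence at equal totals has equal affinity, and tight binding with
ligand depletion follows the Morrison closed form:

```r
relative_affinity_ratio(F_AO = 200, F_mix = 150, F_ref = 100)
#> K_X/K_AO = 1 (residual AO fraction f = 0.500)
bound_fraction_single(0.1, 0.2, 0.01)   # E, L, Kd in uM
#> [1] 0.916
```

## Analysis workflow

`analysis/` holds numbered drivers that run the full study on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # inputs + ground truth (PDB/YAML/CSV/TSV)
Rscript analysis/02_binding_modes.R  # classification vs truth
Rscript analysis/03_observables.R    # interactions, mixtures, stability, sugar sites
Rscript analysis/04_affinity.R       # inhibition + competition fits
Rscript analysis/05_dihedrals.R      # torsion-term fitting + CHARMM stream
```

`run_pipeline()` performs the same stages from a single YAML/list config
with a manifest for reproducibility. Real trajectories enter as
multi-model PDB (plus topology PDB, group YAML, and helix-range YAML);
see the vignette in `vignettes/cts-binding-analysis.Rmd` for the model
descriptions, parameter meanings and validation design.

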