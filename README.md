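# hepnmr

Solution-NMR tools for characterizing protein–glycosaminoglycan (GAG)
interactions, built around the study design used for GAG-binding cytokines
titrated with structurally defined heparin oligosaccharides. The package is
aimed at NMR spectroscopists and structural biologists who have
chemical-shift-perturbation titrations and intermolecular NOE contact lists
and want to go from those tables to apparent affinities, binding
stoichiometry signatures, and NOE-consistent 3D models of the
protein–oligosaccharide complex — without a forcefield or any deposited
structure.

## What it computes

**Titration analysis.** Normalized chemical shift perturbations
Δδ = √(ΔH² + (0.2 ΔN)²) from ¹⁵N-HSQC peak tracks; apparent dissociation
constants by least-squares fitting of the quadratic one-to-one fast-exchange
isotherm

  Δδ = Δδ_max [(P_t + L_t + K_d) − √((P_t + L_t + K_d)² − 4 P_t L_t)] / (2 P_t)

with noise-floor flagging of non-binders; and detection of nonlinear peak
migration (direction changes of the trajectory in (ΔH, 0.2 ΔN) space), the
signature of two sequential binding events.

**Two-site equilibria.** A simulator for a protein with two independent
sites (θᵢ = L/(L+K_dᵢ), mass conservation solved to 1e-12) that synthesizes
fast-exchange peak tracks and reproduces the direction change at a
ligand:protein ratio of 1:1 when a tight site fills before a weak one.

**Glycan building.** 3D models of 1,4-linked heparin-family
oligosaccharides with controlled ring puckers (⁴C₁ glucosamines, ¹C₄
iduronates, half-chair unsaturated uronate), explicit protons, exact
glycosidic torsion placement (φ = O5–C1–O1–C4′, ψ = C1–O1–C4′–C3′),
selective desulfation variants (2-O, 6-O, N→NAc), sulfate-cluster
distance analysis and Cremer–Pople pucker measurement. `dp6c()` builds the
hexasaccharide ΔUA2S-(GlcNS6S-IdoA2S)₂-GlcNS6S at the minimum-energy
torsions (80/−170 and −80/−140).

**Restraints, docking, scoring.** Ambiguous NOE-derived distance restraints
with r⁻⁶ averaging (d_eff = (Σ dᵢ⁻⁶)^(−1/6)) and a 4–7 Å flat-bottom well;
two-stage restrained simulated-annealing docking from the 64-orientation
start grid (90° increments about X, Y, Z) at ~30 Å standoff, with fixed
backbone and harmonically restrained glycosidic torsions; NOE-consistency
scoring (mean distance from probe protons to the nearest 2-O-sulfated
uronate proton), top-10% selection re-ranked by a surrogate binding energy,
and Kabsch backbone-deviation checks. Everything stochastic is seeded and
bit-reproducible.

**Synthetic data.** Titration fixtures with embedded ground truth,
schematic basic-patch mini-receptors, and bound-pose fixtures whose contact
tables are derived from the true pose — enabling closed-loop
parameter-recovery and pose-recovery experiments with no external data.

See `vignette source in vignettes/hepnmr-methods.Rmd` for the models,
parameter defaults and design decisions.

## Worked example

```r
library(hepnmr)

# --- apparent Kd from a noisy 7-point titration (plus apo reference)
peaks <- make_titration_fixture("one_site", kd = 0.05, noise_sd = 0.002,
                                seed = 7, include_apo = TRUE)
fit <- fit_one_site(peaks, protein_conc = 0.1)
fit
#> One-site titration fit - residue 1 (HN)
#>   Kd = 0.05575 mM, ddmax = 0.1777 ppm, SSE = 6.1e-06, converged: TRUE
```

The fitted Kd (0.056 mM) recovers the generating value (0.05 mM) to ~11%
from a single noisy replicate, and Δδ_max (0.178 ppm) the true saturation
shift (0.180 ppm); `autoplot(fit)` draws the binding curve.

```r
# --- sequential two-site binding reverses the peak trajectory at 1:1
trk <- make_titration_fixture("two_site", include_apo = TRUE)  # Kd 0.001 / 0.15 mM
detect_migration(trk, protein_conc = 0.1)
#> # A tibble: 1 x 7
#>   residue_id atom_label max_turn_deg turn_ratio is_nonlinear ...
#> 1          1 HN                 152.          1 TRUE
```

A 152° turn at ligand:protein = 1.0: the tight (CTD-like) site saturates at
one equivalent and further ligand moves the peak along the weak-site vector.

```r
# --- build the hexasaccharide and dock it onto a basic patch
dp6 <- dp6c()
dp6
#> Glycan chain: dUA2S-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S
#>   150 atoms, 6 residues, formal charge -12
measure_torsions(dp6)        # phi/psi reproduce 80/-170 and -80/-140 exactly

receptor <- make_mini_receptor()                    # CTD-like basic patch
fx  <- make_bound_pose_fixture(receptor, dp6)       # ground-truth complex
rst <- compile_restraints(fx$contacts, receptor, dp6)
run <- dock(receptor, dp6, rst, seed = 1,
            config = dock_config(prescreen_top = 10))
scores <- rank_models(score_poses(run))             # NOE score + energy ranking
ligand_rmsd(best_pose(run)$pose[[1]]$xyz, fx$manifest$true_xyz)
```

On this fixture the best-ranked pose typically lands within ~1–2.5 Å
ligand-RMSD of the generating pose, with every compiled restraint satisfied.

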