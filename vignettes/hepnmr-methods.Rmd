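---
title: "Methods: NMR-guided modelling of protein-heparin oligosaccharide interactions"
author: "hepnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR-guided modelling of protein-heparin interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hepnmr` implements the computational chain used to characterize the
interaction of a glycosaminoglycan (GAG)-binding protein with a structurally
defined heparin hexasaccharide by solution NMR: chemical-shift-perturbation
(CSP) titration analysis with one-site Kd fitting and nonlinear-migration
detection, a sequential two-site binding simulator, a conformation-controlled
heparin oligosaccharide builder with selective-desulfation variants,
ambiguous NOE-derived distance restraints with r^-6 averaging, a two-stage
restrained docking protocol, and NOE-consistency model ranking. This vignette
records the models, the tunable parameters, and the design decisions behind
each step.

## Titration analysis

Under fast exchange a 15N-HSQC peak moves continuously between its free and
bound positions. The normalized shift change combines both dimensions as

$$\Delta\delta = \sqrt{\Delta H^2 + (0.2\,\Delta N)^2},$$

the 0.2 factor compensating the wider 15N range. Apparent dissociation
constants come from the quadratic one-to-one isotherm

$$\Delta\delta = \Delta\delta_{max}\,
 \frac{(P_t+L_t+K_d) - \sqrt{(P_t+L_t+K_d)^2 - 4P_tL_t}}{2P_t},$$

with $P_t$, $L_t$ the total protein and ligand concentrations (mM). The
discriminant is clamped at zero so stoichiometric points cannot produce NaN
by round-off. `fit_one_site()` minimizes the SSE over $(\log K_d,
\Delta\delta_{max})$ with L-BFGS-B, $K_d$ bounded in $[10^{-6}, 100]$ mM,
initialized from the ligand-excess (Langmuir) approximation with two
additional bracketing starts. Shifts are measured relative to the first
point of the track: a track may start at the 0 mM apo point or at the first
titration point (the model then subtracts the reference offset), which keeps
the fit well-posed for data recorded without an explicit apo spectrum.
Tracks whose maximal normalized shift stays below a noise floor (default
0.005 ppm; no experimental cutoff is published, and 0.005 ppm is about twice
a typical peak-picking precision) are flagged non-binding rather than fitted.

Nonlinear peak migration — the signature of two sequential binding events —
is quantified as the turn angle between successive step vectors in
$(\Delta H,\ 0.2\,\Delta N)$ space; the 0.2 scaling is applied here too, for
consistency with the CSP. A track is called nonlinear when any interior turn
angle exceeds a threshold (default 60 degrees; the phenomenon is reported
visually in the source experiments, so a vector-angle criterion is the
minimal testable formalization). The ligand:protein ratio at the maximal
turn localizes the stoichiometry of the switch. Zero-length steps make the
angle undefined; they are skipped and counted. Note that the turn angle is
a per-step statistic: on a densely sampled schedule the same trajectory
curvature is spread over many small angles, so threshold-based calls are
meaningful on experimental-resolution schedules while the *location* of the
maximal turn is robust at any sampling density.

## Two-site equilibria

The two structured domains bind short heparin oligosaccharides
independently, so the protein is modelled with two thermodynamically
independent sites (no coupling term): occupancies $\theta_i = L/(L+K_{d,i})$
and mass conservation $L_t = L + P_t(\theta_1+\theta_2)$. The conservation
function is strictly increasing in $L$, so the free-ligand root is unique
and bracketed in $[0, L_t]$; `solve_two_site()` finds it with `uniroot` to
1e-12 relative tolerance (verified against a plain bisection oracle in the
tests). Observed shifts are population-weighted:
$\delta = \delta_{apo} + \theta_1 v_1 + \theta_2 v_2$ with per-site
saturation shift vectors $v_1, v_2$. Intermediate-exchange broadening is not
modelled. With a tight first site ($K_{d,1} \ll P_t$), site 1 fills
stoichiometrically until $L_t \approx P_t$ and the trajectory then rotates
toward $v_2$: the direction change at a 1:1 ratio.

The per-site shift vectors are free parameters of the generator (no
published per-residue values exist). The defaults, $v_1 = (0.15, 0.5)$ and
$v_2 = (-0.15, -0.25)$ ppm, are typical saturation CSP magnitudes for a
strongly perturbed amide and point in directions separated by well over 90
degrees in migration space, reproducing the observed near-reversal.

## Glycan builder

`build_glycan()` constructs 1,4-linked heparin-family chains
(non-reducing to reducing) from idealized monosaccharide templates:

* ring geometry: ideal chairs with Cremer-Pople $\theta \approx 0^\circ$
  (4C1, glucosamines) or $\approx 180^\circ$ (1C4, iduronates), and a
  half-chair for the 4,5-unsaturated uronate formed by lyase cleavage;
* idealized internal coordinates (C-C 1.52 A, C-O 1.43 A, S-O ester 1.58 A,
  S=O 1.45 A, tetrahedral angles); the templates are *not* a forcefield
  geometry;
* explicit hydrogens, because restraints and NOE scores address named
  protons (IdoA2S.H2, dUA2S.H3/H4, GlcNS6S.H2/H3/H5);
* fully ionized sulfates and carboxylates (formal charge -1 each, no
  counterions), so the DP6-C hexasaccharide
  dUA2S-(GlcNS6S-IdoA2S)2-GlcNS6S carries -12.

Glycosidic torsions follow the heavy-atom convention
$\phi =$ O5-C1-O1-C4', $\psi =$ C1-O1-C4'-C3', shared by the builder and
the measurer and recorded in PDB output headers (the literature
minimum-energy values are quoted without a stated convention; the
convention ambiguity is recorded here rather than resolved). Each linkage is
placed exactly: the acceptor C4' is positioned from $\phi$ by internal
coordinates, a virtual C3' from $\psi$, and the acceptor template is
rigid-fitted with its old C4-O4 bond direction mapped onto the glycosidic
oxygen. Measured-back torsions therefore reproduce the requested values to
machine precision (the contract is 0.5 degrees). Default linkage torsions
are the minimum-energy geometries 80/-170 (glucosamine to iduronate) and
-80/-140 (uronate to glucosamine).

Axial/equatorial substituent slots are fixed per residue family. They were
chosen once so that (a) the 1C4 iduronate presents its 2-O-sulfate on the
linkage face next to the glucosamine N-sulfate — the high-density sulfate
cluster that makes the GlcNS6S-IdoA2S disaccharide the preferred binding
motif — and (b) the hexasaccharide at the default torsions is extended
(about 29 A end-to-end) and free of heavy-atom overlap. One exocyclic
rotamer per rotatable group is fixed at template level; no conformational
ensembles are generated (the 2S0/1C4 iduronate equilibrium is acknowledged
but one pucker is used per build). Steric screening uses a 1.8 A heavy-atom
criterion; idealized hydrogen positions are not screened.

`desulfate()` produces the selectively desulfated variants (2-O, 6-O,
N-desulfation/N-acetylation) by group surgery that leaves ring coordinates
untouched and raises the formal charge by exactly the number of sulfates
removed.

## Ambiguous restraints

An ambiguous restraint pools protein-proton/ligand-atom pairs into one
effective distance $d_{eff} = (\sum_i d_i^{-6})^{-1/6}$, which is always
bounded by the shortest pair — the restraint is satisfied if *any* listed
contact is close. The restraint energy is a flat-bottom quadratic on
$d_{eff}$: zero in $[4, 7]$ A, $k\,w\,(d_{eff}-\text{bound})^2$ outside.
The 4 A lower bound encodes the weak-NOE calibration (the intermolecular
NOEs represent distances greater than 4 A); no calibrated upper bound
exists, and 7 A keeps restrained groups in contact range without
over-constraining sparse data. The default force constant is 10
energy/A^2 with uniform weights. An analytic gradient is provided and
verified against central finite differences.

Selectors are globs over residue and atom names: `"*"`/`"O2S*"` expands the
"2-O-sulfate terminal oxygens" across every 2-O-sulfated residue;
protein-side ambiguity groups (`"68/91"`) expand across both residues into a
single restraint. The packaged CTD and NTD contact tables
(`example_contacts()`) transcribe the published binding-site contacts and
can be applied to any user-supplied coordinates with matching residue
numbering.

## Docking

The published protocol (placement about 30 A from the binding face at 64
orientations, 1 ns restrained implicit-solvent MD with fixed backbone, then
2 ns free MD with only the glycan dihedral restraints active) is replaced by
a two-stage seeded simulated-annealing protocol with the same inputs,
stage structure and outputs. The substitution trades thermodynamic realism
for desk-scale determinism and independence from a forcefield: identical
seeds give bit-identical poses, and the acceptance surface (restraint
satisfaction, pose recovery, NOE-consistency ranking) is preserved.

* Start grid: all rotations by 0/90/180/270 degrees about X, then Y, then Z
  — 64 starts in lexicographic order (24 unique matrices, the proper
  octahedral group; the full 64 are enumerated as in the printed protocol).
* Placement: ligand centroid on the binding-face axis (centroid of
  restrained atoms displaced outward from the protein centroid) with the
  closest protein-ligand approach within standoff +/- 2 A.
* Stage 1 minimizes restraint energy + surrogate nonbonded energy over
  rigid pose and glycosidic torsions, with the torsions harmonically
  restrained to their built targets and the entire protein fixed.
* Stage 2 drops the distance restraints, keeps the torsion restraints, and
  additionally frees the side-chain chi1 rotations of the restrained
  residues ("all atoms free" is narrowed to the ligand plus those side
  chains; backbone rigidity is itself a quality criterion of the original
  protocol, and backbone atoms move exactly 0 A here).

The surrogate nonbonded energy is a Coulomb term with distance-dependent
dielectric $\epsilon(r) = 4r$ over formal-charge centers (Lys NZ +1, Arg CZ
+1, sulfate S -1, carboxylate C -1), soft-floored at the contact radius so
the attraction between opposite charges stays bounded, plus a capped
soft-sphere repulsion $(\sigma/r)^{12}$ over heavy-atom pairs
($\sigma = 2.8$ A, cap 100 per pair). Its absolute scale is arbitrary: it
replaces an end-point forcefield energy and only comparisons between poses
of one system are meaningful.

Annealing defaults (all overridable via `dock_config()`): 40 temperature
levels for stage 1 and 20 for stage 2, geometric cooling 0.93 from T0 = 10,
200 proposals per level; proposal widths 0.15 rad rotation, 1.0 A
translation, 10 degrees torsion; torsion restraint constant 0.2
energy/deg^2 (stiff, because the study kept the glycan dihedrals
constrained in both stages; the harmonic keeps refined torsions within 25
degrees of target). A restraint-driven prescreen of all starts followed by
full refinement of the best N (`prescreen_top`) mirrors the rigid-body-then-
refine structure of data-driven docking and is how the larger recovery
experiments are run. Non-finite proposal energies are rejected and counted;
a stage aborts only if every proposal rejects. Refined poses are ranked
restraint-consistency first (highest satisfied fraction, then lowest total
score, ties by start index) — the same primary/secondary logic as the model
ranking below.

## Scoring and ranking

The primary NOE-consistency score of a pose is the mean, over the probe
protons of the binding site (CTD: W59/W74 He1, the K68/91 Hz ambiguity
group, K111 backbone HN; NTD: W18/W20 He1, R52 He, K54 Hz), of the distance
from each probe to its nearest 2-O-sulfated uronate proton (IdoA2S.H2 /
dUA2S.H3). Probe ambiguity groups contribute one value (the group minimum);
all terms carry equal weight. "K68/91.Heta" in the source material is read
as Hz — lysines have no eta protons, so this is treated as a typographical
slip. For the NTD site the unambiguous K45.Hz-dUA2S.H4 distance is averaged
into the primary score. A secondary score against the glucosamine H3/H5
protons is reported as the consistency flag (uronate score < glucosamine
score for NOE-consistent models), not used for selection.

`rank_models()` retains the top fraction (default 10%, ceiling rounding —
the rounding rule is unpublished) by primary score and orders the retained
set by surrogate binding energy, ties broken by pose id so the ranking is
stable under input shuffling. Backbone deviation from the starting
structure is computed by Kabsch superposition (SVD with reflection
correction).

## Synthetic data

No deposited structures or spectra are required; every input is generated:

* **Titration fixtures** use the experimental schedule (0.1, 0.2, 0.3, 0.4,
  0.6, 0.8, 1.0 mM ligand at 0.05-0.1 mM protein) with optional Gaussian
  shift noise and embed their ground truth in `#` header comments.
  `include_apo` prepends the 0 mM reference point, which is required to see
  the 1:1 direction change on the experimental-resolution schedule (the
  first scheduled point is already at one protein equivalent).
* **Mini-receptors** are schematic, rigid poly-alanine scaffolds (CA
  spacing 3.8 A) presenting Lys/Arg/Trp side chains on one face, arranged
  as one or two basic patches (the CTD-like default places W59/K68/K91 and
  W74/K111 about 15 A apart). They stand in for the real domains, whose
  coordinates are not redistributed here; the packaged contact tables apply
  unchanged to user-supplied real coordinates.
* **Bound-pose fixtures** hand-dock the ligand onto the patch (principal
  axis along the scaffold, exhaustive search over axial rotations, offsets
  and heights subject to sulfate-cation contact range 3.5-5 A), then settle
  the pose into the nearest local minimum of the surrogate energy with a
  deterministic rigid-body Nelder-Mead relaxation, so the recorded true pose
  is a stationary point of the docking objective. Contacts are derived from
  the actual pose geometry (probe protons and sulfate/ring-proton targets
  within 6 A, a cutoff chosen inside the 4-7 A well), filtered so every
  compiled restraint is satisfied by the true pose, and given calibrated
  per-contact upper bounds ($d_{eff}$ + 1 A, capped at 7 A) — the generator
  knows its own geometry, and the calibrated bounds make the recovery
  experiment register-sensitive despite the internal repeat symmetry of the
  hexasaccharide. The manifest stores the exact pose for RMSD checks.

What the generator does *not* emulate: relaxation and exchange broadening,
peak overlap and assignment ambiguity, spectral noise structure,
conformational ensembles of the ligand, and real protein topology. Passing
the closed-loop tests therefore demonstrates correctness of the computational
chain under its own assumptions, not performance on experimental spectra.

## Numerical choices and problem sizes

* Isotherm discriminant clamped at zero; Kd fitted in log space with
  bounded L-BFGS-B; grid-search SSE oracle cross-checks the optimizer in
  the tests.
* Free-ligand root to 1e-12 relative tolerance; bisection oracle agreement
  to 1e-9 mM over a 20 x 20 x 10 parameter grid.
* Torsion placement is exact by construction; round-trip tolerance stated
  as 0.5 degrees.
* Degenerate dihedrals (collinear atoms) and zero-length migration steps
  yield NA with a message, never silent values.
* Tie-breaks are always deterministic (pose id / start index).
* Test and example docking runs use reduced annealing schedules (about 20-26
  levels, 60-90 proposals per level, prescreen to 6-10 refined starts) on
  mini-receptors of ~10 residues and the 150-atom hexasaccharide; these
  sizes make the closed-loop recovery experiment (64 starts x 10 seeds)
  run in a couple of minutes while leaving the default configuration at the
  full published schedule. The parameter-recovery suite uses 200 noisy
  replicates of the 7-point titration.

## Known limitations

* The glycan templates are idealized diastereomer models, adequate for
  torsion bookkeeping, pucker control, sulfate-cluster geometry and proton
  naming, but not a substitute for forcefield-quality carbohydrate
  geometry; the half-chair used for the unsaturated uronate is an
  approximation whose exact reference geometry is unpublished.
* The surrogate energy has no solvation, polarization or entropy; energies
  are not comparable in kcal/mol with end-point forcefield methods, and no
  thermodynamic-ensemble claims attach to the annealing trajectories.
* Only fast exchange is modelled in titration simulation; intermediate
  exchange (observed experimentally as broadening) is out of scope.
* One ligand conformation per build: flexibility enters only through the
  restrained glycosidic torsions during docking.
* Protein backbone flexibility is out of scope by design.
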