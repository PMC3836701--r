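---
title: "Coarse-grained models of coupled binding and folding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained models of coupled binding and folding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Intrinsically disordered proteins (IDPs) often fold only upon binding their
partners.  Because specific recognition then requires both encounter and
folding, IDP association could in principle be slow; experimentally, many
IDPs nonetheless bind at near diffusion-limited rates.  One proposed
resolution is that long-range electrostatic forces between the enriched
charges of IDPs and complementary charges near their binding sites
accelerate both the encounter step and the folding step that follows it.

`bindfold` implements the simulation and analysis machinery needed to test
that hypothesis with topology-based (Gō-like) coarse-grained models: a
C&alpha;-bead force field derived from a complex structure, Langevin and
temperature replica-exchange samplers, WHAM thermodynamics, a two-stage
calibration protocol, a three-state kinetic decomposition of binding
trajectories, and an interface charge census.  A synthetic-fixture module
generates small two-chain complexes, multi-temperature energy samples with
closed-form thermodynamics, and Markov state trajectories with known rates,
so every stage is testable without external data.

# The model

Each residue is one bead of mass 110 Da at the C&alpha; position.  The
potential has:

* **Virtual bonds** between consecutive residues, fixed at their native
  lengths by SHAKE (a harmonic term with `k_bond` is used only when
  constraints are disabled).
* **Angles**: `U = k_theta (theta - theta0)^2` with `k_theta = 20`
  kcal/mol/rad&sup2;, referenced to native geometry.
* **Dihedrals**: a two-term cosine series
  `k1 [1 - cos(phi - phi0)] + k3 [1 - cos 3(phi - phi0)]` with
  `k1 = 0.4`, `k3 = 0.2` kcal/mol.
* **Native contacts**: 12-10 wells
  `eps_ij [5 (r0/r)^12 - 6 (r0/r)^10]`, minimum `-eps_ij` at the native
  separation.  A pair is a native contact when any heavy-atom pair of the
  two residues is within 4.5 &Aring; in the native structure (C&alpha;
  fallback when no all-atom records exist), with sequence separation
  &ge; 3 for intramolecular pairs.  Both criteria are configurable; they
  follow the standard structure-based-model convention because the
  original model builder is external to this package.
* **Sequence flavoring**: well depths are modulated by a 20&times;20
  statistical matrix shipped in `inst/extdata`, built as the geometric-mean
  factorization `w_ij = sqrt(e_i e_j)` of per-residue contact-energy
  magnitudes (a standard one-parameter approximation of statistical
  contact potentials).  Under the default normalization the mean weight
  over the model's own contacts is exactly 1, so the mean well depth equals
  the base epsilon and the flavoring only redistributes depth among
  contacts.  A uniform matrix is available and is what the test suite
  uses.
* **Excluded volume**: `(sigma/r)^12` with `sigma = 4.0` &Aring; on all
  non-native nonbonded pairs.
* **Electrostatics** (optional): Debye–Hückel,
  `U = k_C q_i q_j exp(-r/lambda_D) / (eps_r r)` with `eps_r = 80` and
  `lambda_D` from the ionic strength (`I = 0` gives unscreened Coulomb).
  In explicit-charge mode Lys/Arg carry +1, Asp/Glu −1, zinc +2, and all
  other residues — including histidine — are neutral.
* **Zinc ions** are explicit particles restrained harmonically
  (`k = 50` kcal/mol/&Aring;&sup2;) to their coordinating residues at the
  native distances.

All nonbonded terms (contacts, excluded volume, electrostatics) are
truncated at 25 &Aring; and shifted so the energy is continuous at the
cutoff; shifting was chosen over switching to avoid energy drift, as the
original truncation scheme is not recorded.  The minimum-image convention
applies in cubic periodic boxes.  Units are kcal/mol, &Aring;, ps, K
throughout, with `k_B = 0.0019872` kcal/mol/K.

# Sampling

`run_langevin()` integrates Langevin dynamics with a BAOAB splitting
(half-kick, half-drift, exact Ornstein–Uhlenbeck velocity update,
half-drift, half-kick) and applies SHAKE after the position update, with
the constraint displacement fed back into the velocities.  BAOAB was
chosen over simpler leapfrog discretizations because it remains accurate
in configuration space at the 15 fs production time step with stiff
contact wells.  The default friction is 0.1 ps&sup1;&#8315;, as in the
production protocol.  The integrator is deterministic per seed:
identical seed, configuration and topology give bit-identical
trajectories.  Nonbonded interactions are evaluated by a precomputed
pair-list scan with a cutoff early exit rather than a cell list: for the
system sizes this package targets (tens to a few hundred beads) the scan
is faster than list maintenance and the physics is identical.

`run_rex()` is a temperature replica-exchange driver over the Langevin
kernel.  Neighbor swaps alternate between even and odd pairs every
`exchange_interval` steps (default 1000) and use the Metropolis criterion
`min(1, exp[(beta_i - beta_j)(U_i - U_j)])`; configurations swap and
velocities are rescaled by `sqrt(T_new/T_old)` (rescaling, not redrawing,
is the conventional choice).  The default ladder is geometric with eight
rungs from 270 to 400 K.

# Thermodynamics

`wham()` implements binless temperature WHAM: per-temperature offsets
`f_k` are iterated to self-consistency (tolerance `1e-8` on
`max |df|`), after which any per-sample observable can be reweighted to
any temperature in the sampled range.  The binless formulation was chosen
so downstream observables need not be decided before the analysis.
Derived quantities:

* `heat_capacity()`: `C_V(T) = (<U^2> - <U>^2) / (k_B T^2)`.
* `melting_temperature()`: the C_V peak, and the temperature where the
  reweighted bound probability crosses 0.5.
* `effective_concentration()`: `1/(N_A V)`; 1.66 mM for a 100 &Aring;
  box, 1.43 mM for 105 &Aring;.
* `dissociation_constant()`: `K_D = C_eff P_U^2 / (1 - P_U)` for one
  pair per box, with the unbound state defined by the absence of any
  native intermolecular contact; a complement rule
  (`P_U = 1 - P_bound`) is provided for complexes whose 1D free-energy
  profile lacks a barrier between the unbound and partially bound states.
* `free_energy_surface()`: `F = -k_B T ln P`, anchored so the minimum
  over occupied bins is 0; empty bins are masked, not zeroed.

Uncertainties follow the half-split convention: the difference between
values computed from the first and second halves of the data.

# Reaction coordinates and states

A native contact is *formed* in a frame when its C&alpha; distance is
within 1.0 &Aring; of the native value.  Nonspecific intermolecular
contacts use a 10 &Aring; C&alpha; cutoff; for state assignment they
*exclude* native pairs, so the collision-complex definition ("at least
one nonspecific but no specific contact") is disjoint from native-contact
formation — the original analysis does not say whether native pairs were
excluded, and the disjoint convention is declared here because it makes
the three states well defined.

Contact-count series are smoothed with a centered 15 ps running average
*before* labeling (smoothing labels instead would be a different, less
faithful operation), then frames are labeled: bound (B) when the native
intermolecular count reaches the per-model threshold; unbound (U) when
both smoothed counts are below 0.5; collision complex (CC) when only
nonspecific contacts are present.  Partially bound frames
(`0.5 <= N_inter < threshold`) inherit the previous unambiguous label —
intermediates are not a fourth state.  Direct U&harr;B label changes
(possible after smoothing) insert a zero-length CC visit so the
three-state bookkeeping stays closed.

Kinetic definitions, fixed by consistency with the published summary
tables: `k_TS = N_TS / t_tot` where `N_TS` counts completed U&rarr;B plus
B&rarr;U passages; `k_cap = 1 / MFPT(U->CC)`;
`k_esc = N_esc / T_CC` and `k_evo = N_evo / T_CC` over the total
residence time of complete CC episodes.  MFPT(X&rarr;Y) is the mean
residence time in X per visit, over visits whose next state is Y; because
real transitions pass through unmodeled intermediates, the CC lifetime
may depend on the destination, and this convention is reproduced rather
than corrected.  Wall-clock first-passage times are reported separately
(`fpt`).  Episodes truncated by the trajectory ends are excluded from all
episode statistics.  On/off rates come from the mean residence times of
the unbound (U+CC) and bound macro-states.

# Calibration

Calibration is two-stage, re-run from scratch for charged models:

1. `calibrate_intra()` bisects the uniform intramolecular scale
   `lambda_intra` in [0.1, 1.5] so that the mean residual helicity of the
   unbound IDP over fixed-length 300 K Langevin runs matches a target
   (tolerance 0.05).  Helicity of residue i is operationalized as: the
   native (i, i+4) contact is formed *and* the C&alpha; pseudo-dihedral
   (i−1…i+2) is within 40° of native — the analysis must define helicity
   from C&alpha; geometry alone, and this contact-plus-dihedral rule is
   the declared choice.  Both per-residue profiles and the mean are
   supported as targets; the mean is the default summary because the
   synthetic fixtures carry no per-residue experimental profile.
2. `calibrate_inter()` bisects `log lambda_inter` so the REX + WHAM
   dissociation constant at 300 K matches the target to one order of
   magnitude.  The computed K_D is very sensitive to small changes of the
   intermolecular scale, which is why the acceptance criterion is an
   order of magnitude, not a percentage.

Evaluation-run lengths during calibration are configurable and default far
below production scale; reproducing experiment-calibrated models requires
correspondingly longer sampling.

# The synthetic study system

`make_toy_complex()` emits a two-chain ideal-geometry complex: chain A
(20 residues, the "substrate") and chain B (12 residues, the "IDP") are
alpha helices packed at 10 &Aring; axis separation, each residue carrying
a C&alpha; and a dummy outward CB bead so heavy-atom contact criteria and
SASA are exercisable.  The default sequences place lysines on chain A and
aspartates/glutamates on chain B (net −6, matching the charge scale of
real acidic IDP domains), giving the complementary interface electrostatics
whose kinetic consequences the analysis probes.  The ground-truth contact
table is computed by a brute-force all-pairs scan inside the generator at
a 6.5 &Aring; heavy-atom cutoff — looser than the all-atom 4.5 &Aring;
because the CA/CB toy geometry is coarser than a real side chain — and
every emitted structure satisfies its own criterion by construction.

The miniature end-to-end study (`mini_binding_study()`) uses a 50 &Aring;
box (effective concentration 13.3 mM), `lambda_inter = 1.6`, a bound
threshold of 6 of the 8 intermolecular contacts, a 6-rung 300–460 K
ladder with 120k steps per replica, and 3.5M production steps (52.5 ns).
These sizes were chosen once so that the full pipeline — build, REX,
WHAM, melting-temperature location, production, kinetics — completes in
minutes on one CPU while still observing tens of reversible transitions
for the uncharged model and several for the charged one.  T_m is located
from the C_V peak and then fine-tuned with short probe runs until bound
and unbound states are sampled with comparable probability, mirroring the
two-step protocol used for the real complexes; the probe uses the same
smoothed three-state labels as the production analysis, because raw
instantaneous contact counts and smoothed labels can disagree
substantially near the melting point.

What the toy complex emulates: charge-complementary interfaces, reversible
binding with a folding-coupled bound state, collision-complex
stabilization by nonspecific electrostatics.  What it does not: real IDP
sequences and helicities, many-helix topologies, zinc-stabilized folds
(zinc handling is exercised separately), experimental affinities.
Passing tests on the toy therefore validate the machinery and the
direction of electrostatic effects, not the published per-complex
numbers, which require the experimental structures and tens of
microseconds of sampling.

# Numerical choices and degenerate inputs

* WHAM: log-sum-exp throughout; non-convergence is an error with
  diagnostics; a single temperature yields uniform weights.
* `K_D` with `P_U` of 0 or 1 is an error (unresolvable), not a clamped
  value.
* Free-energy surfaces with all samples in one bin warn rather than fail.
* SHAKE: relative tolerance `1e-8`, 500-iteration cap, error with the
  step index on non-convergence; every saved frame satisfies the
  constraints to well below 1e-6 &Aring;.
* Zero transition counts give rate 0 with a flag, never NaN.
* Particle overlaps (r < 1e-6 &Aring;) and non-finite coordinates are
  hard errors.
* Bisection tie-breaks: `calibrate_intra` evaluates the unscaled model
  first and reports it alongside the calibrated result.

# Known limitations

* The C&alpha;-only charge model overestimates salt screening, so the
  attenuation of electrostatic acceleration with ionic strength is
  qualitative.
* Conditional MFPTs inherit the intermediate-state bias discussed above.
* The pair-list evaluator scales as O(N&sup2;) per step; it is the right
  trade-off below a few hundred beads but would need a cell list for
  larger systems.
* Short replica-exchange runs give rough melting temperatures; the
  production fine-tuning step absorbs most, not all, of that error.

# Reproducing the analysis

The numbered scripts under `analysis/` run the full workflow on the
synthetic complex: `01_build_models.R` (models and charge census),
`02_calibrate.R` (two-stage calibration), `03_thermodynamics.R`
(REX/WHAM, C_V, K_D, free-energy surfaces), `04_kinetics.R` (production
kinetics with and without explicit charges, collision-complex contact
maps).  `scripts/acceptance.R` recomputes the package's headline
quantities from scratch and writes them to JSON.  With locally available
experimental complex structures, the same functions accept their PDB
paths and chain selections in place of the toy generator; multi-microsecond
sampling lengths are then required for quantitative comparisons.
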