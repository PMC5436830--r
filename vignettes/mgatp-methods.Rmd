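---
title: "Hydrogen-bond energetics and free-energy estimation for MgATP binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond energetics and free-energy estimation for MgATP binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgatp)
library(dplyr)
```

## The scientific problem

The ε subunit of bacterial F₁Fₒ-ATP synthase senses cellular ATP levels: it
binds MgATP in a "down" conformation and releases it when its second
C-terminal α-helix swings "up". Point mutations in the binding site (such as
the double arginine-to-alanine substitution R103A/R115A studied in the
thermophilic *Bacillus* PS3 subunit) can change the ATP affinity by orders of
magnitude. Because binding strength in such sites is dominated by a dense
hydrogen-bond network between the protein, the nucleotide, and the Mg²⁺
counter-ion, differences between variants can be interrogated by analysing
molecular-dynamics trajectories of each variant:

1. **Hydrogen-bond detection** under geometric criteria, split into a
   protein–ATP component and a helix-anchoring component (the network tying
   the second C-terminal helix, residues 112–133, to the rest of the
   protein).
2. **Energy scoring** of the detected network with an empirical exponential
   distance relation (an Espinosa-type fit), giving per-variant totals whose
   difference is an *energy penalty* ΔE_HB = E_HB(mutant) − E_HB(wild type).
3. **Repulsive-contact counting** between binding-site cations (Arg/Lys side
   chains) and Mg²⁺.
4. **Mg²⁺ coordination classification** — whether the ion chelates the
   non-bridging Oα/Oβ or Oβ/Oγ phosphate oxygens directly (first sphere),
   binds through its hydration shell (second sphere), or is unbound.
5. **Free-energy estimation** from alchemical simulations via the Bennett
   acceptance ratio (BAR) and thermodynamic integration (TI), with
   equilibration discards and time-slice convergence checks.

This package implements stages 1–5 as composable functions over tidy data
frames, together with a synthetic binding-site generator that plants known
geometry so every stage can be validated against exact ground truth.

## Data model

A *trajectory* is a tibble with one row per atom per frame (`frame`,
`time_ps`, `serial`, `name`, `element`, `resname`, `resid`, `chain`, `x`,
`y`, `z`; coordinates in Å). Multi-model PDB files map onto it directly
(`read_pdb()` / `write_pdb()`), and all analysis functions take the tibble
first so they chain with the pipe. Frames are numbered from 1, residue
numbers follow the PDB field verbatim.

Composite atom labels common in binding-site work are resolved by an alias
table (`atom_aliases()`): `NHx` → {NH1, NH2}, `OEx` → {OE1, OE2},
`N3/7/9` → {N3, N7, N9}, and `Oalpha`/`Obeta`/`Ogamma` → the *non-bridging*
phosphate oxygens {O1A, O2A}, {O1B, O2B}, {O1G, O2G, O3G}. The bridging
O3A/O3B are excluded deliberately: chelation and arginine contacts involve
the non-bridging oxygens, and distances over an alias are minima over the
set. The PDB chemical-component naming is a convention choice — the analysis
literature writes Oα/Oβ/Oγ without fixing atom names — so the table is an
exported, replaceable object.

## Hydrogen-bond model

A bond is a donor–hydrogen–acceptor triple D–H···A accepted when

* d(H, A) ≤ 2.7 Å, and
* the D–H···A angle deviates from linearity by ≤ 30° (i.e. the angle at the
  hydrogen is ≥ 150°).

The angular criterion is stated in the literature simply as "a 30° cut-off
between donor hydrogen and acceptor", which is ambiguous; the deviation-from-
linearity reading is the standard geometric criterion corresponding to a 30°
acceptance cone and is what `hbond_criteria()` implements (both numbers are
parameters). Hydrogens are paired to their donor heavy atom by residue
identity and a 1.2 Å covalent cut-off; the package never synthesises missing
hydrogens, because an unvalidated geometry-building step would contaminate
every downstream energy. One hydrogen may satisfy the criteria with several
acceptors; every qualifying triple is counted (counts are triple counts).

Which atoms *may* donate or accept is a chemistry table
(`default_hbond_chemistry()`): N–H and O–H groups donate (backbone N, Arg
NE/NH1/NH2, Lys NZ, Ser/Thr/Tyr hydroxyls, amide and ring NH, plus ATP's N6
and ribose O2′/O3′); carbonyl/carboxylate oxygens, phosphate and ribose
oxygens, and ring nitrogens with lone pairs accept. The source analyses never
enumerate this chemistry, so the table ships as an editable default rather
than hard-coded truth.

`helix_network_hbonds()` counts bonds with *exactly one* heavy partner in
the helix residue range — intra-helix bonds say nothing about how the helix
is anchored to the protein body, so they are excluded.

No periodic-boundary minimum-image correction is applied anywhere: inputs
are assumed unwrapped, which holds for the synthetic generator and for
typical post-processed binding-site extracts.

## Energy scoring

Each detected bond contributes

$$E_{HB}(d) = -A\,e^{-b\,d(H,A)} \quad\text{kJ/mol},$$

with A = 502×10³ kJ/mol and b = 3.6 Å⁻¹ by default (`espinosa_params()`).
Sums are converted at 4.184 kJ/kcal and reported as magnitudes in kcal/mol,
matching the sign convention of published tables; internally energies stay
negative. The prefactor is configurable: published fits of exponential
H-bond energy relations differ, per-bond energies from this constant are
large at typical H···O distances, and fidelity to the printed constant was
preferred over silently substituting another fit. Consequently the package
validates energy totals against synthetic closed-form ground truth and the
printed component/total arithmetic — not against re-derived per-structure
values, which would require the original (undeposited) trajectories.

The relation is applied to every detected bond regardless of acceptor
element, as the source analysis applies one formula to the whole network; a
restriction is one `dplyr::filter()` on the record tibble away.

### Replicate statistics

Independent replicas are summarised by *mean of run means*: each run is
averaged over its retained frames, then the mean and the sample (n−1)
standard deviation are taken across run means (`replica_summary()`). Pooling
frames would weight long runs more; with three replicas the n−1 convention
treats them as a sample of possible runs. A single run reports `NA` spread,
never a misleading 0. Per-run totals are formed *before* summarising, so the
component/total identity holds run by run and survives averaging.

## Repulsive contacts and Mg²⁺ coordination

A repulsive contact is a positively charged binding-site residue whose
cationic side-chain atom (Arg NE/NH1/NH2, Lys NZ) lies within 4.5 Å of the
Mg²⁺ ion. Whether published per-structure values count residues or atoms is
not stated, so `contact_criteria()` exposes both modes; `per_residue` is the
default and both are cheap to report.

`classify_mg_state()` computes minimal Mg–Oα/Oβ/Oγ distances and assigns
exactly one of four states: bidentate first-sphere Oα/Oβ or Oβ/Oγ (both
partner distances ≤ 2.6 Å), second sphere (minimal distance ≤ 5.0 Å), or
unbound. The two thresholds are not available from the source distributions
alone; 2.6 Å sits in the gap between the direct Mg–O coordination peak
(≈2.1 Å) and the water-bridged peak (≈4 Å) of typical Mg–O radial
distributions, and 5.0 Å closes the second-sphere shell. Both are explicit
parameters of `mg_thresholds()` because a reproducible classification needs
printed cut-offs. If both bidentate patterns hold simultaneously, the pair
whose two distances have the smaller maximum wins — a deterministic
tie-break. Second-sphere assignment is distance-based only; verifying an
explicit Mg–water–phosphate bridge would require waters that many inputs do
not contain.

## Free-energy estimators

`bar_estimate()` solves the Bennett self-consistency equation

$$\sum_F \frac{1}{1+e^{\beta(M + W_F - \Delta F)}} \;=\;
  \sum_R \frac{1}{1+e^{\beta(-M + W_R + \Delta F)}},
  \qquad M = \tfrac{1}{\beta}\ln(n_F/n_R),$$

where backward samples carry the work of the *reverse* perturbation. The
residual is monotone in ΔF, so the root is found by bisection on a bracket
expanded geometrically from the mean-work midpoint — deterministic and
robust for poorly overlapping data — to a residual below 10⁻¹⁰ per sample.
Disjoint forward / negated-backward supports are refused with an overlap
diagnostic before solving: the equation still has a root there, but a
statistically meaningless one. The reported uncertainty is Bennett's
asymptotic variance evaluated at the solution. Correctness is anchored two
independent ways: the Gaussian/Crooks closed form (forward work
N(ΔF + βσ²/2, σ²) implies ΔF = μ − βσ²/2) and a separate fixed-point
iteration of the same equation, which the test suite requires to agree with
the bisection solver to 10⁻⁶.

One caveat worth stating: the familiar claim that BAR lies between the
forward and reverse exponential-averaging estimates is a population-level
(Jensen) inequality. On finite samples all three estimators share noise and
the ordering is violated in a substantial fraction of draws; the test suite
therefore checks it on seed averages in a strongly dissipative regime
rather than per sample.

`ti_integrate()` discards a per-window equilibration time (100 ps of a
500 ps window by default in the protocols this mirrors), averages ∂H/∂λ per
window, and integrates over λ with the trapezoidal rule — exact for affine
profiles on any grid, and within 10⁻⁴ relative of the analytic integral for
a cubic profile on an 85-window grid. The TI uncertainty convention is the
two-point sample standard deviation of forward and backward estimates
(`forward_backward_sd()`, |Δ|/√2). `slice_convergence()` re-runs the
estimator on sub-intervals of the sampling time (full production window and
its halves by default) — agreeing slices indicate stationarity; a planted
drift shows up as excess spread. `subsample_snapshots()` implements the
stride-grid thinning used for snapshot post-processing: a 100 ns trajectory
stored every 100 ps, skipped for 10 ns and strided at 100 ps, yields exactly
900 production snapshots. Temperature defaults to 300 K wherever β must be
derived from an energy unit.

## The synthetic generator: what it emulates and what it does not

`build_site_trajectory()` constructs a minimal binding site: an ATP-like
ligand with canonically named phosphate/nucleoside atoms, an optional Mg²⁺
planted in a chosen coordination state, cationic residues at chosen
distances from the ion, and donor–hydrogen–acceptor triples realising
requested (d, deviation) geometries exactly. Design choices that matter:

* **Each planted bond lives in its own spatial cell** (non-ATP acceptors on
  a 15 Å grid; ATP acceptors keep their scaffold position with the donor
  approaching from outside the ligand), and nucleoside scaffold atoms are
  ≥ 6 Å apart. A construction-time guard rejects any geometry in which a
  planted hydrogen comes within 3 Å of a foreign acceptor or violates the
  1.2 Å covalent pairing constraint. Together these make the noiseless
  detected set *equal* the planted set, so ground truth is exact by
  construction, not by circular measurement.
* **Planted bonds are validated against the chemistry table** — a planted
  "donor" that detection chemistry would never accept (say a Glu
  carboxylate oxygen) is refused rather than silently diverging from the
  analysis.
* **Noise is isotropic Gaussian jitter, i.i.d. per atom and frame, except
  that a planted hydrogen shares its donor's displacement.** Fully
  independent jitter would stretch the covalent D–H pair past the 1.2 Å
  pairing cut-off in roughly 0.4% of frames per bond at σ = 0.05 Å, making
  high-fidelity recovery impossible for networks of more than a couple of
  bonds — and in the simulations being emulated, bond-length constraints
  move the X–H unit rigidly anyway. Jitter therefore perturbs bond
  *geometry* (distances, angles, classifications), which is what the
  analyses measure, and never the bookkeeping of which hydrogen belongs to
  which donor.
* **No kinetic realism.** Frames are uncorrelated; there is no force field,
  no water, no conformational sampling. Passing recovery tests shows the
  *analysis* operations are correct and noise-tolerant; it says nothing
  about whether a real trajectory was converged or its force field
  adequate.

`gaussian_work_samples()` draws Crooks-consistent forward/backward work
(the unique Gaussian pair with equal variances satisfying the fluctuation
theorem), and `synthetic_dhdl()` emits per-window series following
closed-form λ-profiles — the oracles for BAR and TI.

One visible consequence of jitter worth knowing when reading outputs: the
exponential energy relation is convex, so positional noise biases mean E_HB
slightly *upward* (≈ +3% at σ = 0.05 Å) relative to the noiseless planted
value. This is a property of the estimator under noise, not a bug, and it
cancels to first order in wild-type/mutant differences.

## The comparison pipeline

`run_config()` + `run_compare()` assemble the full wild-type-versus-mutant
table: per-variant protein–ATP and helix-network bond counts, repulsive
contacts, and energy components/totals with replica mean ± sd, plus the
energy penalty at the shared coordination state. Defaults are the
literature values: 2.7 Å / 30°, 4.5 Å contacts, 10 ns equilibration skip,
helix 112–133, A = 502×10³ kJ/mol, b = 3.6 Å⁻¹. Each input trajectory set
is treated as one coordination state (the experimental design of the
three-setup study this mirrors); per-frame stratification by classified
state is available through `mg_state_series()` for the more general
analysis. Machine outputs are written with 6 significant digits, and a run
log echoes every parameter. A thin command-line front end
(`inst/scripts/mdhb.R`) exposes each stage as a subcommand over YAML
configs; the R functions remain the primary interface.

## Problem sizes and numerical choices

The validation suite uses deliberately small, fully synthetic problems:
2–5-frame noiseless trajectories for exactness checks, 200-frame jittered
trajectories (σ = 0.05 Å) for recovery rates, 10⁵ work samples per direction
across 20 seeds for BAR calibration, and 85-window TI grids. These sizes
were chosen so each property is measured well inside its statistical
resolution. Ties, degenerate inputs, and error contracts (empty series,
missing ions, non-overlapping work, inverted ranges) are exercised
explicitly. All generators are deterministic under a fixed seed; identical
configurations produce byte-identical outputs.

## Known limitations

* Energies are network sums of an empirical two-body relation: no
  electrostatics, van der Waals, entropy, or cooperativity. The penalty is
  a *hydrogen-bond-network* difference, not a binding free energy.
* Detection requires explicit hydrogens; structures without them must be
  protonated upstream.
* Distance-based coordination classification cannot distinguish a true
  water-bridged second sphere from a transiently departing ion at the same
  distance.
* Only PDB/XVG text inputs are supported; binary trajectory formats are out
  of scope.
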