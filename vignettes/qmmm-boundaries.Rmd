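---
title: "QM/MM boundaries: link atoms, charge redistribution and energy assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QM/MM boundaries: link atoms, charge redistribution and energy assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmmmtools)
```

## The problem

Hybrid QM/MM calculations treat a small reactive region of an enzyme
(system 1, the QM region) quantum-mechanically and the bulk (system 2, the
MM region) with a force field. When the region boundary cuts a covalent
bond — say the CA–CB bond of an active-site residue — three pieces of
machinery decide what the QM calculation actually sees:

1. **Link atoms.** The dangling QM valence is capped with a hydrogen link
   atom (HL) placed on the axis from the boundary QM atom (Q1) to the
   replaced MM atom (M1, also called the carbon link atom, CL).
2. **Charge redistribution.** The MM point charges closest to the cut
   would sit essentially on top of the HL atom; every QM/MM code
   deletes, shifts or compensates them differently. These choices are the
   Z0–Z3, DZ1–DZ3, ZZ2, RCD and CS schemes implemented here.
3. **Energy bookkeeping.** The total energy is assembled either
   *additively* (QM energy + MM energy + explicit interaction term) or
   *subtractively* (QM energy + MM energy of everything − MM energy of the
   QM region), with mechanical (ME) or electrostatic (EE) embedding.

Published comparisons of mature QM/MM codes show that these three choices —
not the QM method — dominate the spread of computed reaction energies.
This package implements the machinery itself as a small, fully tested
library: every scheme, both bookkeeping formulations, and the "big-QM"
region-selection procedure used to converge energies with respect to the
QM-region size. All electronic-structure work is delegated to a pluggable
backend; the shipped backend is a *classical surrogate* so that every
algebraic identity the formulations must satisfy can be verified exactly,
at desk scale, in seconds.

## Boundary nomenclature and link atoms

For each bond crossing the partition, atoms are classified into shells by
graph distance from the cut: Q1 (the QM atom of the cut bond), Q2 (QM
neighbors of Q1), Q3 (their neighbors), and symmetrically M1, M2, M3 on
the MM side. Shells are made disjoint by priority (M1 > M2 > M3), so a
ring closing back onto the boundary never classifies an atom twice; the
`ring_adjacent` fixture exercises exactly this.

The HL position is linearly related to Q1 and M1:
r_HL = r_Q1 + g·(r_M1 − r_Q1). The scale g is not standardized across
codes; our default derives it from standard bond lengths,
g = d0(Q1–H)/d0(Q1–M1), giving g = 1.090/1.526 ≈ 0.714 for a C–C cut. A
fixed-length mode (default 1.09 Å) is also provided. Cutting a bond to
hydrogen, or an MM atom bonded to two QM atoms ("double junction"), is
rejected rather than silently patched.

## The ten charge-redistribution schemes

With q0 the M1 charge and n = |M2|:

| scheme | rule |
|---|---|
| Z0 | keep all MM charges, including M1 (the CL atom — note this lets an atom interact with its own HL alter ego) |
| Z1 / Z2 / Z3 | delete shells M1 / M1+M2 / M1+M2+M3 |
| DZ1–DZ3 | as Zk, then spread the deleted charge of the junction residue evenly over its remaining MM atoms |
| ZZ2 | as Z2, then shift the junction residue's retained charges uniformly so they sum to zero |
| RCD | delete M1; add −q0/n to each M2 and a site of +2q0/n at each M1–M2 bond midpoint |
| CS | delete M1; add +q0/n to each M2 and a pair ±δ at r_M2 ± d·û along M1→M2, δ = −q0·|r_M2 − r_M1|/(2nd) |

RCD and CS conserve both the total charge and the local {M1 ∪ M2} dipole
exactly — the property tests verify this to 1e-12 e and 1e-10 e·Å on 200
randomized junction fixtures. The consequence is measurable: the error of
each scheme's electrostatic potential relative to Z0, sampled on spheres
10–80 Å from the junction, decays with log–log slope ≈ −1 for Z1 (a
monopole defect), ≈ −2 for DZ1 (charge restored, dipole not) and ≈ −3 for
RCD and CS (charge and dipole restored). This is why dipole-preserving
schemes converge fastest with distance.

The CS construction is implemented from its verbal description, which is
known to be under-specified in the literature; the pair half-distance d is
therefore an exposed parameter (default 0.25 Å, must be smaller than the
shortest M2 bond) and is recorded in the model's provenance attributes.

Edge-case policy: exclusions are unioned across junctions *before* the
DZ/ZZ2 compensations, and an atom excluded by one junction is never
re-adjusted by another (exclusion wins). DZk redistribution is confined to
the junction residue (the residue holding M1); if an excluded shell spills
into a neighboring residue its charge is not recovered — with the backbone
C–N and CA–CB cuts this package recommends (and its fixtures use), shells
up to M3 stay inside the junction residue, so DZk conserves total charge
exactly there.

## Energy assembly and the surrogate backend

Four assemblies are provided, with components labeled exactly as they
enter the totals:

* ME additive: E = E_QM¹ + E_MM² + E_QM/MM¹⁻², the interaction evaluated
  classically with force-field charges (MEA) or supplied ESP charges (MEE)
  on the QM side, plus cross-boundary bonded and Lennard-Jones terms.
* ME subtractive: E = E_QM¹ + E_MM¹² − E_MM¹.
* EE subtractive: E = E_QM1+ptch2^HL + E_MM12,q1=0^CL − E_MM1,q1=0^HL.
  The "12" term keeps the real CL atoms while the "1" term uses HL atoms —
  that asymmetry is what carries the van der Waals link-atom correction.
* EE additive: E = E_QM1+ptch2^HL + E_MM² + cross LJ, with optional DLB
  (Q1–M1 bonds) and DLAD (Q2–Q1–M1 angles, Q3–Q2–Q1–M1 torsions) terms.

The big-QM assembly is the EE-subtractive expression with an enlarged
region, by the same code path, so `bigqm(region = base QM)` is identical
to the ordinary EE energy and `bigqm(region = everything)` is the bare
backend energy — both reductions are tested to 1e-9 kJ/mol.

The surrogate backend evaluates an HL-capped geometry as its internal MM
energy (link hydrogens get hydrogen Lennard-Jones parameters and zero
charge) plus the analytic Coulomb energy with the external point-charge
model, excluding the model's self-energy, as the backend contract
requires. Because the surrogate and the MM engine share one pairwise
evaluator with no cutoffs, two identities hold *exactly* rather than
approximately: additive and subtractive ME coincide (the classical analogue
of the sub-0.1 kJ/mol agreement real codes show), and EE totals under two
schemes differ by precisely the Coulomb interaction of the QM charges with
the difference of the two point-charge models. A real electronic-structure
backend would satisfy these only approximately; the contract
(geometry + external charges in, energy ± ESP charges out, deterministic,
kJ/mol) is documented on `surrogate_backend()` so one can be wired in.

## The MM engine

Harmonic bonds k(r−r0)² and angles k(θ−θ0)², torsions V(1+cos(nφ−γ)),
Lennard-Jones with Lorentz–Berthelot combining, Coulomb with
1389.35458 kJ mol⁻¹ Å e⁻², AMBER-style 1-2/1-3 exclusions and 1-4 scaling
(elec 1/1.2, LJ 1/2, configurable). No distance cutoff is applied to any
term, which is what makes the energy exactly pairwise-additive and the
subtractive/additive identity exact. Exclusions are classified on the full
covalent graph, so they are unchanged by subsetting or link substitution.
The engine is validated against an independently written double-loop
oracle on 50 randomized ≤25-atom systems to 1e-10 kJ/mol.

## Big-QM selection and neutralization

`select_bigqm()` applies, in order: (i) whole-residue inclusion of every
residue (water molecules included whole, likewise) with an atom within
radius r of the base region; (ii) backbone atoms (N, H, CA, HA, C, O) of
user-listed span residues; (iii) buried charged residues, whole, when
requested; (iv) junction relocation — any peptide-bond cut closer than two
residues in sequence to a base residue is pushed outward residue by
residue. Cuts are accepted only at backbone C–N or CA–CB bonds. On a
nine-residue chain with base residue 5 and a small radius this yields
residues {3,4,5,6,7}, the canonical relocation trace. Two interpretation
points were genuinely open and are resolved as follows: the radius rule
completes whole residues by default (an atom-level mode is provided for
comparison but skips relocation, which is only well-posed on whole
residues); and the r → 0 limit returns the base residues *plus* whatever
relocation then demands, since rule (iv) is unconditional.

Solvent exposure uses Shrake–Rupley SASA with a deterministic
Fibonacci-spiral sampling (960 points/atom, probe 1.4 Å). The per-residue
reference maximum is the SASA of the same residue computed in isolation at
the same coordinates rather than a tabulated Gly-X-Gly value — exact for
any residue palette, including synthetic ones, and it makes "an isolated
residue has relative SASA 1" true by construction. Because the sampling
grid is fixed in space, rotation invariance holds only to sampling
tolerance (tested at 0.02); translation invariance is exact. No numeric
buried/exposed criterion exists in the literature for this procedure, so
the defaults — buried: relative SASA < 0.05; exposed charged: ≥ 0.20 on
the residue — are documented, configurable choices.

`neutralize_exposed_charges()` applies the standard structural edits:
arginine loses HH22, lysine loses HZ3, aspartate gains a proton on OD1 and
glutamate on OE2, the added proton 0.97 Å from the oxygen along the
in-plane bisector of the O–C and O–O′ directions (away from both the
carboxylate carbon and the sibling oxygen). Residues in an ion pair —
opposite formal charges with a *side-chain* heavy-atom contact under
4.0 Å; the backbone peptide bond between sequence neighbors deliberately
does not count — are exempt. After an edit the residue's formal charge is
zero and its partial charges are renormalized to sum to exactly zero (the
residual is spread over the residue after a deletion, or assigned to the
added proton). Plain deletion would leave non-integer residue sums; the
renormalization keeps the package-wide closure invariant and changes no
geometry.

## The synthetic-data generator

All tests run on generated peptide-like systems: a toy helical chain
(~1.5 Å backbone spacing, 40°/residue side-chain twist, chosen so that no
non-excluded atom pair comes closer than ~1.5 Å) with residue kinds ALA,
ARG, LYS, ASP, GLU, a cyclic RING side chain and free waters. Partial
charges are plausible template values plus a seeded uniform perturbation
(±0.05 e), renormalized per residue so they sum exactly to the formal
charge; force constants are generic (bonds 1000 kJ mol⁻¹ Å⁻², angles
300 kJ mol⁻¹ rad⁻², torsions 2 kJ/mol threefold) with bond and angle
equilibria taken from the as-built geometry. Identical spec + seed
reproduces a fixture bit for bit.

What passing tests on these fixtures shows — and does not show: the graph,
charge, conservation and bookkeeping logic is exercised fully, on harder
topologies (double cuts into one residue, rings at the boundary, waters
inside the QM region) than a typical protein boundary presents. What the
fixtures do not emulate is real conformational strain, real charge
distributions, or electronic polarization; no claim about the *numerical
size* of scheme-to-scheme energy differences in a real protein follows
from them, only the exact laws those differences must obey.

## Numerical choices and problem sizes

Units are fixed internally (Å, e, kJ/mol; Coulomb constant
1389.35458 kJ mol⁻¹ Å e⁻²). Degenerate junction geometry (|Q1−M1| <
0.1 Å) is an error, as is a CS shift reaching the nearest M2 neighbor.
Hydrogen bond inference assigns each H to its closest heavy atom, ties
broken toward the smaller index. The property suites use 200 random
junction fixtures for the conservation laws, 8 probe distances × 32
directions for the decay slopes, 50 random systems for the MM oracle and
a 9-residue chain for big-QM — sizes at which the full suite runs in well
under a minute per suite on one core.

## Limitations

No electronic structure, no polarizable or Gaussian-blurred embedding, no
continuum solvation, no geometry optimization: the package builds and
audits the boundary machinery, not the chemistry on top of it. The prmtop
reader covers only charges/bonds/residues/names; angles and torsions for
real systems must come through the JSON topology dialect. Supported cuts
are single covalent bonds between heavy atoms; frozen-orbital boundaries
are out of scope by design.
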