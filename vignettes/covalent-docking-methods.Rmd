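---
title: "Modelling cysteine-acrylamide adducts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cysteine-acrylamide adducts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind `acrydock`, the assumptions they
make, the tunable parameters that matter, and the design decisions taken
where several defensible choices existed. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The chemical picture

Acrylamide's α,β-unsaturated carbonyl is a soft electrophile. Its β-carbon
reacts with soft nucleophiles — above all the thiolate of a deprotonated
cysteine — in a Michael addition that leaves a propionamide group
covalently bound to the sulfur. Three properties of a cysteine govern its
reactivity: solvent accessibility (the electrophile must reach the
sulfur), acidity (only the thiolate is nucleophilic; the intrinsic thiol
pKa is about 8.6, but hydrogen bonding and nearby positive charges can
lower it), and the microenvironment (His/Asp/Glu can accept the thiol
proton; Lys/Arg stabilise the thiolate and the negatively charged
enolate-type intermediate, and later hydrogen-bond the adduct's carbonyl
oxygen). The package profiles candidate cysteines along these axes and
then models the adduct itself by restraint-based covalent docking.

The docking models the *product* state: the reactive cysteine is prepared
deprotonated (no thiol hydrogen, thiolate charge set), and the free-energy
cost of that deprotonation, ln(10)·kT·(pKa − pH), is reported alongside
docking scores but never added to them — mixing a site-preparation
penalty into a pose-ranking score would conflate two different questions.

## Cysteine profiling

**SASA.** Shrake–Rupley sphere sampling with a deterministic Fibonacci
point set; probe radius 1.4 Å (water), 960 points per atom by default,
which keeps the isolated-sphere error under 1% (the acceptance suite
verifies this against the closed form and against Monte-Carlo surface
integration). Both the whole-residue sum and the Sγ-only value are
reported, since either may be the relevant exposure measure; comparisons
in this package use the whole-residue value. SASA is accumulated per atom,
so the per-residue value is exactly the sum over its atoms.

**Relative acidity.** Absolute cysteine pKa prediction is famously
unreliable, so ranking is the only supported semantics. With an annotation
table (TSV: chain, resnum, pka, flags) candidates are ordered by ascending
annotated pKa. Without one, an internal heuristic preserves the ordering
logic: score = (positive side chains within 5 Å of Sγ) + (hydrogen-bond
donors to Sγ) − 0.05·max(0, 10 − SASA). The two count terms reflect the
two classic pKa-lowering mechanisms; the burial term is a mild penalty
(0.05 per Å² of missing exposure below 10 Å², so full burial costs 0.5 —
half the weight of one positive neighbour). The coefficients are fixed and
deliberately simple; the heuristic is a declared stand-in for external
predictors and carries only ordering meaning.

**Microenvironment.** Residues with any side-chain heavy atom within 5 Å
of Sγ, classified as proton acceptors (His/Asp/Glu) or positive residues
(Lys/Arg), plus hydrogen-bond donors to the sulfur found with the same
geometric criterion as the interaction module. The 5 Å radius and the
Sγ-to-side-chain measurement convention are fixed choices.

## The covalent docking model

**Covalent emulation.** The S–C bond is emulated, not formed: the Sγ
Lennard-Jones radius is divided by ten (so the ligand's reactive carbon
can approach to bond distance) and two flat-bottom quadratic restraints
hold the geometry — Sγ to the reactive carbon at 1.8 ± 0.1 Å (a C–S single
bond) and cysteine Cβ to the adjacent carbon at 2.8 ± 0.1 Å (the
Met Cγ–Cε distance, which enforces a realistic bond angle). The default
force constant is 50 kcal/mol/Å². Because the restrained pair is a
*bonded* moiety in all but name, the scaled Sγ and the Cβ are excluded
from nonbonded terms with their ligand copy, exactly as 1-2/1-3 bonded
pairs are excluded in molecular force fields. Without this exclusion the
vdW-deleted sulfur creates spurious short-range electrostatics with the
ligand's polar hydrogens deep inside what would normally be repulsive
territory.

**Energy terms.** The functional forms are standard and config-overridable:
12-6 Lennard-Jones (additive rmin, geometric-mean well depths, per-pair cap
of 1000 kcal/mol below 0.1 Å overlap), Coulomb electrostatics in a
distance-dependent dielectric ε(r) = r with an 8.5 Å cutoff, desolvation as
Σ σᵢ·(SASA_bound − SASA_unbound) with per-element atomic solvation
parameters (positive for C and S, so burying apolar surface is
favourable), and the restraint energy Σ k·max(0, |d − target| − tol)².
The composite weighs them 1.0/0.1/1.0/0.1 — the weighting recommended for
protein–small-molecule scoring — and holds exactly by construction (the
acceptance suite checks bit-exactness on random tuples). During docking
the desolvation term recomputes SASA only for the ligand and protein atoms
within 8 Å of it (all other contributions cancel), with a 120-point sphere
sampling; this keeps scoring cheap at a per-call accuracy well below the
score differences that matter.

**Parameter table.** The packaged charge set is a minimal additive,
polar-hydrogen force-field subset written for this package: aliphatic
hydrogen charges are absorbed into their carbons, each residue sums to its
formal charge, and the polarity split used by the hydrophobic-contact
definition is preserved (backbone carbonyl carbons ≥ 0.15 e, aliphatic
side-chain carbons < 0.15 e). Cysteine has thiol, disulfide and thiolate
charge states; the thiolate state is applied automatically to reactive
cysteines. LJ radii/depths and solvation parameters are per-element. The
table is self-consistent rather than a reproduction of any published
force field; scores are therefore only meaningful relative to other scores
from this package.

**Search.** Stage 1 places the reactive carbon on the restraint shell
around Sγ (directions biased towards solvent), applies a uniform random
orientation, optionally a 180° flip about the S–C axis (the symmetry-flip
class), and optionally a spin that points the carbonyl oxygen at a nearby
polar hydrogen (a hydrogen-bond-biased orientation class, applied to
whatever donors the pocket offers); each placement is rigid-body minimised
(Nelder-Mead) against the cheap objective (LJ + weighted Coulomb +
full-strength restraints). The best-scored poses (200 of 1000 by default)
enter stage 2: Metropolis Monte-Carlo annealing over ligand rigid-body
motion, the two ligand torsions, and side-chain torsions (χ1/χ2 rotations)
of protein residues within 5 Å of the ligand, under a hot (500→50 K) and a
cool (300→50 K) linear temperature ramp, followed by local minimisation.
The protein backbone never moves, and a soft steric guard keeps moved side
chains from clashing with the rest of the protein. The full composite
(including desolvation) is evaluated at stage boundaries and the
best-scored configuration is kept, so refinement never worsens a pose's
composite score. An explicit-solvent refinement stage is deliberately not
modelled; its role is approximated by the restrained minimisation in the
distance-dependent dielectric.

**Clustering and cluster scores.** Pairwise interface-ligand RMSD (ligand
heavy atoms after least-squares superposition on the interface backbone —
backbone atoms within 10 Å of the ligand in the reference pose; since the
backbone is rigid here the superposition is the identity, but it is
computed explicitly for generality), greedy clustering at a 1.0 Å cutoff:
the pose with the most neighbours seeds a cluster, members are removed,
repeat — so clusters partition the pose set. A cluster's score is the mean
composite of its four best members (fewer if smaller), and "the standard
deviation of the top cluster" — the analysed-cluster rule — is interpreted
as the standard deviation of those top-four member scores (zero for a
singleton). Ties anywhere break by ascending pose index, which together
with the single seeded RNG stream per run makes every docking
bit-reproducible for a fixed seed and configuration.

**Multibody mode.** Two ligand copies, one per cysteine, each with its own
restraint pair; the interaction matrix spans protein–ligand-1,
protein–ligand-2 and ligand-1–ligand-2, so steric competition between the
adducts appears as positive ligand–ligand vdW energy. With one site the
code path is identical to single-site docking. Scores are additive for
non-interacting sites by construction.

## Interaction analysis

Hydrogen bonds: every donor-H⋯acceptor triple with donor–acceptor
distance ≤ 4.1 Å and donor-H-acceptor angle ≥ 100° measured at the
hydrogen; acceptors are O and S plus nitrogens that carry no hydrogen and
are not backbone amides; no acceptor-angle criterion is applied. Water is
excluded throughout — the analysis covers direct interactions only.
Hydrophobic contacts: the adduct's two aliphatic carbons against protein
carbons with |q| < 0.15 e within 4.0 Å. Both detectors are verified
against brute-force enumeration on random fixtures.

Frequencies are per analysed cluster (percent of member poses exhibiting
the interaction) and pooled as a cluster-size-weighted average. The
residue-type summary pools side-chain hydrogen bonds above a 60% frequency
threshold across dockings — applied per docking before pooling, which
matches reporting interactions a docking displays — counts them by residue
type separately for the carbonyl and amino adduct groups, and reports
percentage shares plus grouped shares (positive = Lys + Arg, negative =
Asp + Glu, polar = Ser/Thr/Asn/Gln/Tyr/His/Trp/Cys). Percentages are
rounded to one decimal.

## Site ranking

Analysed-cluster scores order the candidate cysteines of one protein;
scores are never compared across proteins or configurations (the scale is
not normalised). A site whose top-cluster representative violates either
covalent restraint by more than three times its tolerance is flagged
"no covalent bond formed" and excluded from primary designation — the
numeric form of the qualitative failure mode in which poses sit outside
the covalent-bond range. Secondary sites are the remaining covalent sites
within a 5 a.u. window of the primary; the window is a declared
convention, motivated by treating a ~1 a.u. gap as a plausible secondary
and a ~10 a.u. gap as not, and is configurable.

## The synthetic pocket generator

The generator exists so that every stage of the pipeline can be exercised
with no external downloads, on systems whose ground truth is known by
construction. It emulates the statistical structure the analysis assumes:
reactive cysteines sit in shallow grooves whose microenvironment can be
enriched in positive residues, and those residues are positioned to
stabilise the adduct's carbonyl.

A 38-residue helix–loop–helix hairpin is built from ideal internal
coordinates (φ/ψ = −57°/−47°, trans peptide bonds; the six loop torsions
were optimised once, offline, so the helices run antiparallel at an 8.3 Å
axis separation, and are frozen constants). The groove is deliberately
snug for the small adduct: in a loose groove, truncating a wall residue to
alanine *adds* usable contact volume and the vdW term rewards the
truncated pocket, drowning the electrostatic signal the generator is
supposed to plant; in a snug groove truncation loses contacts, as in real
tightly packed sites. One cysteine sits at the groove floor (residue 29),
its side chain aimed into the groove by a deterministic χ-grid search.

Flank placement is coordinated with the adduct the site will host: the
generator first derives a planned adduct pose from the covalent-restraint
geometry (reactive carbon 1.8 Å from Sγ, chain extending towards solvent),
keeps that volume clear of *all* side chains in every pocket variant, and
then aims the flank side chains by fine χ-grid search. For positive
pockets the first donor targets the shell between the planned carbonyl
oxygen and the sulfur (hydrogen-bond distance to the former, inside the
5 Å microenvironment of the latter), and further donors take
thiolate-stabilising positions beside the sulfur; proton-acceptor flanks
(His, Asp/Glu) always target the thiol region, where they act in the
reaction; alanine flanks simply line the wall at the same slots. Remaining
positions carry a seed-dependent apolar filler (Leu/Val/Ala) bulky enough
that the helix faces present side chains rather than bare backbone, as
real helix surfaces do. Side-chain placement is sequential with explicit
clash avoidance (2.6 Å clearance against everything already placed,
bonded neighbours excluded), so generated structures satisfy the
hydrogen-placement valence invariant.

`generate_known_complex()` additionally builds the adduct pose itself,
solving the second restraint exactly by bisection and optimising the
remaining torsions so a requested donor–acceptor distance and angle are
met while other polar contacts are penalised — giving fixtures whose
complete interaction list is known. `make_paired_site_fixture()` rebuilds
the scaffold position whose Cα lies closest to 7.1 Å from the cysteine's
Cα as a second free cysteine, for multibody tests.

**What the generator does not emulate:** real folds and packing
heterogeneity, backbone flexibility, buried waters, long-range
electrostatics of a full-size protein, and crystallographic artefacts.
Passing the planted-site discrimination experiment therefore shows that
the scoring recovers a planted microenvironment signal under controlled
conditions — not that it ranks sites correctly in arbitrary real
structures, where score differences also reflect pocket shape, state
choice and preparation details.

## Problem sizes and numerical choices

The test suite and the acceptance script run dockings at 150 initial /
40 selected poses with 70 + 70 annealing steps — a configuration chosen so
a docking pair completes in about a minute on one CPU while the
discrimination experiment (ten seeds, twenty dockings) stays stable; the
package default of 1000/200 with 100 + 100 steps is the recommended
production setting. Degenerate inputs are handled explicitly: overlapping
atom pairs cap the LJ term and set a flag; a sterically inaccessible
sulfur yields a warning rather than an error; an empty candidate list
after filtering warns; clusters of size one get a zero standard deviation.
Sphere sampling below 20 points is refused as meaningless.

## Known limitations

Scores are internally consistent but not transferable: the parameter
table is minimal, the dielectric model is crude, and no entropy or
explicit solvent enters the score, so absolute values carry no
thermodynamic meaning. Only polar hydrogens are modelled; His is fixed to
the Nε2 tautomer unless annotations say otherwise; N-terminal amines and
C-terminal carboxylates are left bare. Backbone rigidity means sites that
require conformational change to react can only be studied by docking
each state separately and comparing.
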