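---
title: "Methods: interface contact and stability analysis for two-domain complexes"
author: "ifacemd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface contact and stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifacemd)
```

## The problem

ADAMTS13, the plasma metalloprotease that cleaves von Willebrand Factor,
circulates in an auto-inhibited "closed" conformation in which its distal
domains fold back onto the Spacer domain.  The contact between the eighth
thrombospondin type-1 repeat (TSP8, residues 1072--1131) and the Spacer
domain (residues 556--682, carrying exosite-3 at R568/F592/R660/Y661/Y665
and exosite-4 at E634/D635/R636/R639) is one piece of that auto-inhibition.
Which residues hold this interface together can be asked of molecular
dynamics trajectories: a hydrogen bond or salt bridge that persists across a
large fraction of simulation frames, in several independent replicates,
marks a load-bearing contact; one that flickers does not.

`ifacemd` implements that analysis as a reusable, testable pipeline:
geometric bond detection, per-pair survival ratios with replicate
aggregation, thermal-stability classification, key-residue prediction,
structural stability metrics, and the triage step that selects a docked
starting complex.  It deliberately does **not** run molecular dynamics:
trajectories come in as multi-model PDB files, or from the package's own
synthetic generator, which exists so that every stage can be validated
against programmed ground truth at desk scale.

## Bond definitions and survival ratios

A hydrogen bond is called in a frame when the donor--acceptor distance is
strictly below 3.5 Å and the donor--hydrogen--acceptor angle strictly
above 150°.  The angle is measured at the explicit hydrogen -- the standard
geometric convention -- which is why the package requires structures with
hydrogens present and links each hydrogen to its nearest heavy atom within
1.2 Å at read time rather than building missing ones (building hydrogens
would smuggle in a forcefield; structures without them are rejected with a
clear error).  A salt bridge is called when a side-chain carboxylate oxygen
of Asp/Glu lies strictly within 4 Å of a side-chain nitrogen of
Arg/Lys/His; backbone O/N never participate.  Both thresholds are
parameters (`d_cut`, `a_cut`, `sb_cut`) with these defaults.

The donor/acceptor chemistry table is the conventional one (backbone N--H
donates, backbone O accepts; Ser/Thr/Tyr hydroxyls donate and accept;
Asn/Gln/Arg/Lys/Trp/His side-chain N--H donate; Asp/Glu/Asn/Gln side-chain
O accept) and is user-replaceable.  His is listed as both donor and
acceptor on both ring nitrogens, so any protonation variant (HSD/HSE/HSP
naming included) is covered without choosing one.

Atom-level hits are pooled to residue pairs: a pair is *present* in a frame
when at least one atom-level hit links its two residues.  The **survival
ratio** of a pair is its presence fraction -- bond dwell time over the
analysed duration.  The per-frame interface hydrogen-bond count
N~HB~ counts distinct present residue pairs by default (an
atom-level variant is available via `nhb_level = "atom"`); residue-level
counting is the natural companion of residue-level survival tables.

Detection is evaluated over precomputed cross-domain candidate lists with
vectorised distance and angle arithmetic.  This is exact -- the test suite
holds it to set equality against a brute-force all-pairs evaluator on
randomised conformations -- and fast enough at the package's scale that no
spatial decomposition (cell lists) is needed.

## Replicate aggregation and classification

Replicate survival ratios aggregate to mean ± SEM, where the SEM convention
is the **population** standard deviation (divide by *n*) over √*n*.  This
choice is empirical: it is the convention under which the package's shipped
reference tables (WT and gain-of-function complexes) reproduce exactly
after 3-decimal rounding, whereas the sample-SD convention does not.  The
convention is switchable (`sem_type = "sample"`).  Two caveats are recorded
with the data: the mutant-complex table's printed SEMs follow yet another
convention (consistent with population SD divided by 2) and are excluded
from arithmetic checks; and because the reference replicate columns are
themselves rounded to 3 decimals, five of the 64 WT/GoF cells recompute one
unit of the last decimal away from their printed aggregate -- agreement to
±0.001 is the strongest statement the printed inputs support.

Average survival ratios classify into thermal-stability bands
low [0, 0.3), medium [0.3, 0.55), high [0.55, 1].  The band edges follow
the 0.3/0.55 convention; membership at the boundaries is left-closed so
that the bands partition [0, 1] and a ratio of 0.313 is medium, matching
the reference classification of the Arg660--Asp1090 bond.  Reporting uses
a strict mean > 0.10 filter (a pair at exactly 0.105 is kept, 0.100 is
dropped) ranked by descending mean with lexicographic tie-breaks; **key
residues** are those appearing in at least one record with mean strictly
above 0.30.  Rounding for report tables is 3 decimals, round-half-even.
Survival ratios use every saved frame by default; the analysis stride is a
parameter.

## Structural metrics

*RMSD.*  Superposition is the closed-form Kabsch solution (SVD of the
covariance matrix with the determinant correction that excludes
reflections); the fit and the deviation use the same atom selection
(Cα by default).  The test suite cross-checks it against an independent
quaternion-method implementation to 10⁻⁹ and against rigid-motion
invariance.

*SASA.*  Shrake--Rupley with a deterministic golden-section spiral point
set (default 960 points/atom, probe 1.4 Å, Bondi-type radii, hydrogens
excluded by default).  Determinism matters more here than marginal
accuracy: results are reproducible without seeds, and the expected
resolution error is ≤ 1/√n_points (an isolated sphere reproduces
4π(r + probe)² to machine precision).  Interface burial is reported two
ways, because "interface SASA" is ambiguous in the literature: the buried
area (SASA(TSP8) + SASA(Spacer) − SASA(complex))/2, and the summed
complex-state SASA of interface residues (heavy-atom contact within 5 Å).
Both are labelled; users pick the one matching their convention.

*Interaction energy.*  A minimal cross-domain nonbonded evaluator:
CHARMM-style Lennard-Jones (ε~ij~ = √(ε~i~ε~j~), r~min,ij~ = r~min/2,i~ +
r~min/2,j~) plus Coulomb (332.0636 kcal·Å/(mol·e²), constant dielectric,
default 1.0), both multiplied by the CHARMM quadratic-cubic switching
function between 10 and 12 Å (the 12 Å cutoff is the stated simulation
convention; 10 Å is its common companion switch-on) and zero beyond.
Parameters are a user-supplied table (atom name, residue, charge, ε,
r~min~/2); the package ships only toy parameters, because reproducing a
real forcefield's topology assignment is out of scope.  Absolute energies
are therefore not comparable to engine-computed values -- the metric is for
relative, within-study comparisons.

## The interface definition and docking triage

"On the interface" is nowhere given a numeric definition in the source
literature; the package uses a 5.0 Å minimum heavy-atom distance between
residues of opposite domains, configurable, which is a common contact
cutoff.  The triage gate for docked models is: (1) at least one exosite-3
residue on the interface, and (2) none of Spacer residues 621--623 (the
β6--β7 loop that must remain free for the neighbouring Cys domain) on the
interface.  Eligible models rank by static salt-bridge count, then H-bond
count -- salt bridges weigh more because they distinguish the stabler of
the two historical candidate models -- with deterministic id tie-breaks.
Democratic docking-score ranking is excluded: the scoring method is not
defined by the available sources, so the gate plus contact inventory is the
whole triage.

## The synthetic generator

The generator emulates the *statistical* structure of an interface
trajectory, not its physics: two rigid mini-chains 10 Å apart (numbered in
the standard TSP8/Spacer ranges so every domain rule applies unchanged),
glycine filler residues with explicit backbone amide hydrogens, and one
"slot" per scheduled residue pair where side chains reach across the
interface.  An H-bond pair is an Asn donor facing an Asp acceptor at
donor--acceptor 2.9 Å with a linear donor--H--acceptor geometry; a
salt-bridge pair is a Lys facing an Asp at O--N 3.2 Å, with the Lys
hydrogen oriented perpendicular so the pair never doubles as a geometric
H-bond.  Each frame, each pair is bonded or broken by a Bernoulli(p_occ)
draw (or a stationary two-state Markov chain when frame-to-frame
correlation is requested); the broken pose displaces the acceptor-bearing
side chain 2 Å along the donor→acceptor axis (to 4.9 Å, safely past every
criterion) while the backbone stays fixed, so breaking one pair cannot
disturb another.  Gaussian jitter (default sd 0.05 Å) is added to every
atom; at that level the bonded geometry margins (0.6 Å in distance, 30° in
angle) make detection errors negligible, and the generator warns if a
larger jitter breaks programmed-present poses in more than 1% of frames.
Replicate *r* uses seed, seed+1, seed+2, recorded in the output metadata;
identical inputs give byte-identical trajectories.

What the generator does **not** emulate: solvent, correlated collective
motions, side-chain rotamer exchange, partial occupancy geometries near
the thresholds, or competition between overlapping bonds.  Passing the
recovery tests therefore demonstrates that the *analysis* is correct --
detection, pooling, survival arithmetic, classification and selection
recover programmed truth -- not that any particular MD force field or
sampling protocol is adequate.  Gain-of-function-like and mutant-like
conditions are realised as re-programmed occupancy schedules (exosite-3
pairs attenuated, exosite-4 retained, or all pairs silenced) rather than
physical remodelling; alanine truncation of real side chains is supported
directly, and non-alanine substitutions rebuild side chains from the
template library (generator-built structures only, which record the local
geometry needed for placement).

## Numerical choices and degenerate inputs

* Gaussian fits of N~HB~ distributions are least-squares fits of
  A·exp(−(x−μ)²/2σ²) to unit-bin frequencies (Levenberg--Marquardt,
  moment-based starts).  A rounded-Gaussian series of sd σ fits with
  σ' ≈ √(σ² + 1/12) -- discretisation broadening of about 0.02 at σ = 2,
  well inside the recovery tolerance.  Series with fewer than three
  distinct values raise a fit error suggesting a moment summary instead.
* One-way ANOVA across conditions uses the classical decomposition with
  Bonferroni-adjusted pooled-SD pairwise t-tests, significance at
  p < 0.05; the all-values-identical case short-circuits to F = 0, p = 1.
* The expected RMSD between two independently jittered copies of the same
  frame is σ√6 (the per-atom displacement has variance 2σ² in each of
  three coordinates); the jitter-plateau test asserts this value within
  10%, which superposition barely perturbs at realistic atom counts.
* Problem sizes in tests and the acceptance script -- 30 residues per
  domain and 100 random frames for detector equivalence, 2000 frames × 3
  replicates for occupancy recovery, 10⁵ frames for the Gaussian fit --
  are chosen so every stochastic bound is comfortably resolved while the
  whole suite runs in about a minute.
* PDB inputs: alternate location 'A' or blank only, insertion codes
  rejected, author numbering authoritative (no renumbering); trajectory
  models are validated per MODEL (atom counts and identities) with errors
  naming the offending model.

## Known limitations

Hydrogens are required, never built.  The energy metric is not a binding
free energy and omits solvation, long-range electrostatics and bonded
terms.  SASA point sets trade accuracy for determinism; for publication-
grade absolute areas increase `n_points`.  The generator's two-chain
geometry cannot represent a residue participating in several scheduled
pairs at once (one slot per residue), which the real tables do contain --
survival arithmetic on such tables is unaffected, only synthetic emulation
of that exact topology is.  The package analyses whatever trajectories it
is given; the question of whether 40 ns of sampling, a particular water
model, or a particular force field suffices for the biology is outside its
scope.
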