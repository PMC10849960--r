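---
title: "Groove scaffolds and sequence-space annealing: models and methods"
author: "HelixGroove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Groove scaffolds and sequence-space annealing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HelixGroove)
```

## The design problem

Peptide hormones such as parathyroid hormone, glucagon and neuropeptide Y
are short, often disordered in solution, and fold into an α-helix on
binding. Binding them tightly requires a protein whose interaction surface
cradles the full length of that helix. A helical bundle with an open
*groove* — three helices forming a channel, flanked by two buttressing
helices — is a natural topology for this: the groove buries the target
helix along its whole length, while the flanking helices limit
self-association of the exposed hydrophobic channel.

HelixGroove implements the non-neural computational core of this design
approach: parametric generation of groove-shaped scaffold backbones,
threading of target sequences onto a bound helix, the interface and
compactness metrics used for scoring and filtering, and a simulated
annealing optimizer in sequence space driven by a pluggable
structure-prediction oracle.

## Crick-parameterized backbones

A single helix is generated from the Crick coiled-coil parameterization: a
superhelical circle of radius $R_0$ traversed at $\omega_0$ degrees per
residue carries a minor helix of radius $R_1$ winding at $\omega_1$ degrees
per residue; phases $\phi_0$ and $\phi_1$ set the position on each circle.
The axial rise follows from the fixed per-residue rise $d$ along the
minor-helix axis through the pitch angle $\alpha = \arcsin(R_0
\omega_0 / d)$, which also yields the domain constraint
$|R_0\,\omega_0| < d$.

The defaults — $d = 1.51$ Å/residue, $R_1 = 2.26$ Å, $\omega_1 =
102.85^\circ$/residue for supercoiled helices and $100^\circ$/residue for
straight ones — are canonical coiled-coil values from the parameterization
literature, and every one of them is an explicit argument of
`CrickParams()` rather than an asserted constant.

Only CA positions come from the generating equations. N, C and O atoms are
placed by replaying ideal α-helix peptide-plane offsets in a local frame
built at each CA–CA junction; the along-chain components scale with the
local CA step, so bond lengths stay inside chemically sane windows
(C–N in [1.2, 1.5] Å) even on non-helical loop traces. This is a
backbone-level model by design: side chains, hydrogens and any energy
model are out of scope, because all downstream consumers (threading,
docking, surface metrics) operate at backbone + C$\beta$-proxy resolution.

An antiparallel helix (`sense = -1`) is the *same* spatial helix traversed
C-to-N. An earlier design that mirrored the helix about an axis was
rejected because mirroring also flips the superhelical winding, which
systematically collapses the bundle geometry.

## Sampling groove scaffolds

`sampleCandidate()` draws one five-helix arrangement per call:

* **Helix lengths** uniform on 15–19 residues.
* **Supercoil** $|\omega_0|$ from a truncated exponential on
  $[0, 6]^\circ$/residue with density $\propto e^{0.4 x}$, sign negative
  (left-handed). The bias favours strongly supercoiled scaffolds to
  compensate for their higher attrition at the loop-closure stage; the law
  itself is a configuration knob, since only the *direction* of the bias is
  a stated design condition.
* **Helix spacing**: a per-candidate average neighbour distance from
  N(9.5, 0.7) Å — typical of native helical-bundle packing — then per-helix
  distances from a much tighter Gaussian (sd 0.2 Å) centred on that
  average, so each scaffold has slightly heterogeneous grooves.
* **Placement**: groove helices at superhelical phases 90/180/270°, leaving
  the face at 0° open for the target; buttresses at 135/225°, 4 Å further
  out radially, with an extra uniform tilt on $[-15, 15]^\circ$ about their
  radial direction. The central slot is an imaginary straight helix on the
  z axis where the target is later docked.

Clashes (inter-helix CA–CA below 4 Å, or scaffold atoms intruding into the
slot cylinder) cause *rejection*, not repair: rejection sampling keeps the
acceptance statistics auditable, and every candidate records its full draw
vector for replay. Under the defaults the acceptance rate is roughly 15%;
rejections are dominated by buttress–groove contacts at high supercoil
(where winding drift between helices of unequal length narrows the angular
gaps), which is also why the sampler slightly depletes the extreme
supercoil tail.

## Loop closure

`enumeratePlans()` scores every visit order × traversal direction
(5! × 2⁵ = 3840 combinations) by total end-to-start gap and keeps plans
whose every junction gap is bridgeable by a loop of at most 5 residues
(gap ≤ 3.8 L + 2 Å). `closeLoops()` then builds each loop geometrically:
first a family of cubic Hermite arcs respecting the helix end tangents,
sampled by equal-chord walking; if no curve in that family meets the CA
step window [3.6, 4.0] Å, a circular arc with exactly equal chords is
solved for directly (such an arc exists whenever $(L+1)c > \mathrm{gap}$).
Helix coordinates are never moved — loops only add residues — and the
closed chain is rejected if any non-local CA pair comes below 3.5 Å.

The choice of a geometric builder over fragment- or kinematics-based
closure is deliberate: it is deterministic, dependency-free and sufficient
for backbone-level library generation. It reproduces the qualitative
behaviour that strongly supercoiled bundles fail closure more often
(their termini splay apart), which the test suite checks as a monotone
trend over a seeded supercoil grid (failure rates 0.33 → 0.67 over
$|\omega_0| = 0.5 \ldots 5^\circ$/residue at the default conditions).

## Threading and hydrophobic-interface filtering

Given a scaffold–helix complex, `enumerateThreadings()` places a peptide
sequence at every register offset in both orientations.
`hydrophobicContactCount()` counts peptide positions that are hydrophobic
(A, V, L, I, M, F, W, Y) *and* whose side-chain proxy — an ideal C$\beta$
built from backbone geometry, CA for glycine — lies within 8 Å of any
scaffold proxy. Both the residue set and the cutoff are configuration, not
constants, since neither is a stated condition of the approach; the values
chosen are the field's usual conventions at backbone resolution.
`filterThreadings()` ranks by count (ties: lower offset first, then
parallel before antiparallel) and drops entries below a floor.

## Interface and compactness metrics

* **Radius of gyration** is the root-mean-square distance of CA atoms from
  their centroid; the normalized form divides by the radius of a sphere of
  volume $n \times 110$ Å$^3$ (a documented default for per-residue
  volume), making the loss roughly length-independent. Its analytic
  gradient (used as a guiding potential) sums to zero by translation
  invariance, and the potential's weight decays cubically,
  $w_0 (t/T)^3$ with $t$ counting down — strongest early in a denoising
  trajectory when the quaternary arrangement is still forming.
* **Distogram contact probability**: for each target residue, the
  probability mass below 8 Å against the most-contacting binder residue
  (max over binder residues — the per-pair aggregation is not dictated by
  the loss definition, so the optimistic max is used and documented),
  averaged over target residues. A bin straddling 8 Å contributes
  fractionally by linear interpolation.
* **Interface pAE** is the mean of the two off-diagonal blocks of the
  predicted-aligned-error matrix.
* **Shape complementarity (Sc)** follows the Lawrence–Colman statistic
  with the standard published constants ($w = 0.5$ Å$^{-2}$, 5 points/Å²,
  interface patch = points within 1.5 Å of the opposing surface): nearest
  opposing point, score $e^{-w d^2}(\hat n_a \cdot -\hat n_b)$, median per
  side, mean of the two medians. Surfaces are dot lattices on atom spheres
  with occluded dots removed; this surface is bumpier than a true solvent-
  excluded surface, so Sc on atom-level toys runs somewhat lower than on
  ideal smooth surfaces (which score ≥ 0.95 in the tests).
* **Contact molecular surface** is the distance-weighted area of one
  partner's dot surface in contact with the other
  ($w(d) = e^{-(d/1.5)^2}$, zero beyond 3 Å) — doubling a contact patch
  doubles it.
* A Shrake–Rupley SASA utility with the classic 92-point lattice supports
  surface bookkeeping.

## Sequence-space simulated annealing

`runHallucination()` optimizes a binder sequence against any *oracle* — a
function of (binder sequence, target sequence, residue index) returning
per-residue confidence (pLDDT), complex confidence (pTM), a pAE matrix, a
distogram and CA coordinates. The chain break between binder and target is
encoded as a +32 offset in the residue index vector, applied inside the
oracle adapter only.

The mechanics follow the published recipe exactly where stated:

* seed sequence drawn i.i.d. from BLOSUM62 background frequencies;
* proposals mutate positions drawn from the lowest-50%-pLDDT binder
  positions (at-or-below-median, so ties include everything under a
  uniform profile), substitutes drawn by background frequency excluding
  the current letter;
* phase plan 1250×3, 2500×2, 1250×1 (5,000 steps total) with the number of
  simultaneous changes decaying across phases;
* Metropolis acceptance with temperature $0.01 \cdot 2^{-s/500}$;
* total loss $1\cdot(1-\mathrm{pLDDT}/100) + 1\cdot(1-\mathrm{pTM}) +
  0.1\cdot r_g^{\mathrm{norm}} + 3\cdot(1-p_{\mathrm{contact}}) +
  5\cdot \mathrm{pAE_{iface}}/31$.

The loss *orientation* deserves a note: the published account lists the
quantities and their relative weights (1:1:0.1:3:5) but not their signs or
normalizations. Maximized quantities are folded as $(1-x)$ with pLDDT
scaled by 100 and pAE by 31 Å (the conventional maximum of the pAE output
head). Relative weights are preserved; absolute loss values therefore have
a package-specific offset. The eligible-position profile is refreshed only
after accepted steps, avoiding churn during rejection streaks.

The shipped toy oracle is a deterministic pure function of the sequences
with a planted optimal binder: per-position confidence is high where the
binder matches the optimum (with a fixed per-position spread, as a real
predictor would produce), and pTM, contact mass and interface pAE
interpolate with overall similarity. It exists so the optimizer mechanics
are testable without any neural network: the suite verifies that 20 seeded
runs of a 1,500-step schedule recover a planted 12-mer in ≥ 95% of runs,
that trajectories are bitwise reproducible, and that stored loss
components reproduce stored totals to 1e-12. What passing these tests
shows is that the search machinery is correct; it says nothing about
binder quality under a real structure predictor, which is exactly the
pluggable-oracle boundary.

```{r toy-run}
oracle <- makeToyOracle("LEIKKALEQAIK")
run <- runHallucination(oracle, targetSeq = "GSHLVEAL", binderLength = 12,
                        schedule = AnnealSchedule(data.frame(steps = c(50, 150),
                                                             mutations = c(2, 1))),
                        seed = 1)
run
head(trajectorySteps(run)[, c("step", "temperature", "accepted", "total")])
```

## Filtering

`applyGates()` applies threshold gates (for example interface pAE < 10,
mean pLDDT > 92, pTM > 0.8, RMSD < 1.75 Å — or the looser pAE < 10,
pLDDT > 80, ddG < −40 used for final selection) with *strict* comparisons:
a record exactly on a "<" boundary fails, matching the printed
inequalities. Failed records list every violated gate. `rankAndTake()`
implements the "reduce to the orderable set" step (stable sort, ties by
design id, e.g. top 96).

## What the synthetic data do and do not emulate

The fixture generator (`makeFixture()`) produces ideal poly-alanine
helices, sampled toy complexes, oracle tensors of consistent shape, and
complementary sphere/pocket surfaces. These exercise every module
deterministically and offline. They do not emulate: real side-chain
packing (everything is backbone + C$\beta$ proxy), solvent-excluded
surface topology (dot surfaces omit reentrant patches), real predictor
confidence landscapes (the toy oracle's landscape is unimodal by
construction), or crystallographic disorder. Consequently the two
crystal-structure interface numbers the package can reproduce
(shape complementarity and contact molecular surface of the refined
glucagon binders) require the actual PDB entries 8GJG/8GJI placed under
`inst/extdata/`; the corresponding tests state this requirement explicitly
when the files are absent.

## Numerical choices and problem sizes

Tolerances: backbone bond windows are enforced at 1e-9 slack; distogram
rows must sum to 1 within 1e-6; annealing bookkeeping is checked to 1e-12;
Sc is compared across argument order within 0.02 (surface sampling noise)
and across rigid motions within a wider band, since dot lattices are only
approximately rotation invariant. Statistical checks (Metropolis rate,
background frequencies, supercoil-bias dominance) run at fixed seeds with
3-4σ bands.

The test suite and the acceptance script use deliberately desk-scale
problem sizes — libraries of tens of scaffolds, 12-mer planted optima,
1,500-step annealing runs, 10–12 candidates per supercoil level — chosen
so the full suite completes in minutes on a single core while still
exercising every code path; the published-scale library (200,000
arrangements) is a linear multiple of the same sampler.

## Known limitations

* Loop closure is geometric; it makes no claim of matching any particular
  fragment-based or kinematic closure implementation, only of producing
  chemically sane single chains.
* Sc and contact molecular surface are computed on dot surfaces at vdW
  radii; values on crystal structures may differ from implementations
  built on true molecular (solvent-excluded) surfaces, which is why the
  crystal-structure checks carry ±0.03 (Sc) and ±10% (area) bands.
* The scaffold library is backbone-only: sequence design, ddG estimation
  and structure prediction are consumed through interfaces (metric tables,
  the oracle contract), never reimplemented.
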