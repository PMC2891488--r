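---
title: "Coarse-grained co-translational folding in a crowded cell: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained co-translational folding in a crowded cell: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdfold)
```

## The model

`crowdfold` simulates protein folding with a two-particle-per-residue
representation: one particle at each C-alpha position and one at the
side-chain centroid (glycine, whose centroid coincides with its C-alpha,
carries no second particle).  Motion follows the Langevin equation

$$ a = \frac{F - \gamma_{\mathrm{eff}}\, v + R}{m}, $$

solved iteratively with a semi-implicit (velocity-then-position) update.
$F$ is a sum of pairwise force terms:

* **cov** — stiff springs along covalent connectivity: consecutive
  backbone particles (rest length 3.8 Å) and each backbone to its own
  side-chain centroid (per-residue rest length).
* **bb** — backbone-geometry springs at sequence separations 2 and 3 whose
  rest lengths encode the assigned secondary structure.  Helix-pair values
  are computed from ideal helix geometry (1.5 Å rise, 100° twist), strand
  pairs from an ideal extended strand (3.32 Å axial rise); mixed or coil
  pairs use intermediate coil values (6.0 and 7.5 Å).  This is how a
  three-state secondary-structure string enters the model; there are no
  torsional potentials.
* **sc** — springs from each side-chain centroid to the neighbouring
  backbone particles, orienting side chains relative to the backbone.
* **vdw** — a purely repulsive soft-core term standing in for steric
  clash: a linear ramp from `max_repulsion` at zero separation to zero at
  the pair's contact distance (sum of type contact radii).  A tabulated
  profile derived from clash statistics can be substituted through the
  pair-table interface.
* **hb** — backbone hydrogen bonding.  Virtual O/H sites are placed at
  ±1.9 Å along the local chain bisector at each non-terminal backbone
  particle; pairs at sequence separation ≥ 3 whose opposite-sense sites
  approach within 3 Å are pulled together with a constant force.  Because
  the attraction is gated and of fixed magnitude it is not the gradient of
  a smooth potential; energy-based checks in the tests therefore disable
  this term, and its contract (gating, antisymmetry, direction) is tested
  directly.
* **boundary** — the container wall (inward spring once a particle's
  solvent sphere crosses the wall), the ribosome sphere (outward push once
  a particle's surface penetrates), and the exit-point anchor.

The model is deliberately *native-blind*: no term knows the target
structure, so the same machinery can predict structure and study folding
dynamics.

## Hybrid implicit–explicit solvent

Drag and solvent kicks act only on solvent-exposed surface.  Exposure is
estimated by casting a fixed, quasi-uniform set of rays (a Fibonacci
sphere, default 32 directions) from each particle and testing occlusion
against neighbouring solvent spheres within 12 Å.  The ray set is fixed,
so exposure is deterministic and whole trajectories are reproducible from
a single RNG seed.

Drag is $-\gamma \cdot A \cdot v$ with $A$ the accessible area
(fraction × $4\pi r^2$); a buried particle feels no solvent at all.
Kicks arrive as a Poisson process with mean `kick_rate` × $A$ per
iteration; each kick has fixed speed and a uniformly random direction, and
kicks arriving from directions blocked by other particles are discarded
rather than resampled, so crowded particles are genuinely quieter.
Hydrophobic side-chain particles receive `hydrophobic_multiplier` times
more kicks — the *only* effect of hydrophobicity in the model — which
biases them toward buried positions where kicks cannot reach, producing
hydrophobic collapse without any attractive hydrophobic potential.

## Parameters and calibration

The published description of this model family does not include numeric
constants, so every default here is a package choice, declared in
`default_ff_params()` / `default_langevin_params()` and overridable via
the YAML configuration.  Units: lengths in Å, time in iterations, mass in
base-particle units, `dt = 1`.

The solvent constants were calibrated once, on the package's own toy
systems, to put the model in the physically sensible regime that the
design requires, and then frozen:

* `kick_rate` and `kick_speed` are set so that a free chain sits just
  above its "melting" point: kicks of speed 1.0 Å/iteration at rate
  0.002 per Å² keep a free 40-mer partially unfolding and re-collapsing
  throughout a $10^5$-iteration window instead of freezing into the first
  collapsed blob.  In a dense cell the same chain quietens: exposure
  drops roughly four-fold at the highest crowding level (blocked kick
  directions are discarded) and the static crowder walls leave no room
  for large rearrangements, so the crowded chain arrests while the free
  one stays mobile — the regime the model is meant to probe.
* `hydrophobic_multiplier = 3` gives reliable hydrophobic burial on an
  alternating hydrophobic/hydrophilic 20-mer within $5\times10^4$
  iterations.
* crowder–crowder repulsion is much stiffer than the protein soft-core
  (crowders stand in for the *hard* excluded volume of folded proteins and
  must jam into static walls), while crowder–protein contacts are kept
  moderate so that wall contact does not inject unphysical agitation into
  the chain.
* `speed_cap = 1` Å/iteration is a stability device, not physics; the
  documented conservation properties (momentum, energy drift) hold in the
  regime where the cap never engages, and the tests check them there.

## The simulated cell

The cell is a container sphere of diameter 100 Å.  The ribosome is a
sphere of radius 100 Å whose exit point sits on its surface at the
container centre, anchored there by a spring; all particles are excluded
from the ribosome.  Synthesis adds one residue per 1000 iterations (a
deliberately fast rate; the growing C-terminal backbone particle is
tethered to the exit point and the previous tether released), after which
the chain is untethered and evolves freely.

Crowders are spheres of diameter 30 Å and mass 150 — the approximate
excluded volume and mass of a previously synthesized 75-residue protein.
Their count for a target excluded-volume fraction is
`round(fraction × available volume / crowder volume)`, where the
available volume is the container minus the container–ribosome lens
(closed form; the whole-container denominator is available by
configuration).  The realised fraction after rounding is reported and
logged.

**A geometric caveat discovered during implementation:** with the exit
point at the container centre, the ribosome lens occupies ~41% of the
container, and the region in which whole 30 Å crowders may legally sit is
a thin crescent.  Sequential rejection sampling jams near ~27% excluded
volume, and even optimal packing of non-overlapping crowders cannot reach
50% in this geometry.  `place_crowders()` therefore rejection-samples as
far as it can, completes dense targets with an overlap-relaxation pass,
and — when geometry makes strict placement impossible — returns a
*compressed* start (flagged and warned) whose residual overlaps the stiff
crowder–crowder repulsion resolves into a jammed packing during the run.
Measured crowder displacements in such runs are ~1–2 Å per $10^4$
iterations: the walls are effectively static.  The nominal "50%" level
should therefore be read as "the densest realisable packing", slightly
below 50% in effective terms.

## Observables

* **TM score** — mean of $1/(1+(d_i/d_0)^2)$ over residues under the best
  rigid superposition, $d_0 = 1.24(L-15)^{1/3} - 1.8$ floored at 0.5 Å.
  The search seeds superpositions from contiguous fragments (lengths $L$,
  $L/2$, 4), iterates inclusion of residues within a ladder of cutoffs,
  and polishes the best candidates directly against the TM objective with
  a derivative-free optimiser (the least-squares fit is not optimal for
  the distance-weighted objective).  On 8-residue toys the result matches
  an independent dense rotation-grid oracle to 0.01.
* **Alignable fraction** — largest fraction of residues simultaneously
  within 5 Å of their counterparts under some superposition, by greedy
  seed-and-extend.
* **Relative radius of gyration** — Rg over backbone particles divided by
  the native Rg.
* **Fixation time** — the earliest sample whose mean absolute internal
  pairwise-distance difference to *every* later sample stays below 4 Å
  (superposition-free, all residue pairs).
* **Native-like time** — percentage of samples with TM score above 0.3.
* **Contact maps** — backbone traces smoothed with a nine-residue moving
  average (truncated symmetrically at the termini), contacts below 8 Å for
  strand–strand pairs and 11 Å otherwise, pairs within the same
  secondary-structure unit (maximal run of identical non-coil assignment)
  ineligible.

## Structure prediction

`generate_pool()` runs many co-translational trajectories differing only
in seed (full protocol: 150 trajectories of $6000l + 400{,}000$
iterations, 40 samples each from iteration $6000l$ on, pool of 6000).
Members are ranked by similarity to the pool's mean contact map (+mean
for a contact present where the pool tends to have one, −mean for its
absence); the top 20 are rescored by a pluggable scorer (the default
keeps the consensus score; a learned model-quality assessor can be
plugged in through the same interface); and the final five are made
diverse by dropping the lower-scoring member of any pair in which ≥ 90%
of residues superpose within 7 Å — interpreted here as per-residue
deviation after whole-structure superposition — promoting the next
candidate until the list is diverse or exhausted.

## What the synthetic fixtures do and do not show

All tests run on generated fixtures: ideal helices and strands, beta
hairpins, self-avoiding random coils, alternating-pattern toy sequences,
and perturbed decoy pools.  These exercise every contract of the
machinery — force laws, solvent gating, determinism, metric definitions,
protocol bookkeeping — and the qualitative physics (hydrophobic burial,
crowding-induced extension).  They do not demonstrate predictive accuracy
on real proteins: fixture "natives" are idealised geometries, not
experimental structures, and desk-scale budgets are orders of magnitude
below the full protocol.  Conclusions about real-protein accuracy require
running the full-scale protocol against experimental structures.

## Numerical choices and degenerate inputs

* Coincident particles give a zero spring/repulsion force (direction
  undefined) and are logged once.
* The smoothing window truncates symmetrically at chain termini, drawing
  terminal smoothed positions slightly inward.
* Percentiles use linear interpolation between order statistics.
* Selection ties break toward earlier pool provenance, so ranking is
  deterministic given pool order.
* Selection thresholds are boundary-inclusive (a protein native-like
  exactly 10% of the time is "foldable").
* Trajectory sampling records iterations $k \times$ interval,
  $k = 1..\lfloor n/\text{interval} \rfloor$; the initial state is stored
  separately.

## Problem sizes used in the shipped analyses

The packaged tests and the acceptance script run desk-scale versions of
the study: a 20-mer hydrophobic-collapse toy ($5\times10^4$ iterations,
10 seeds), a 40-mer crowding comparison at 0% vs 50% excluded volume
(10 seeds per level, $10^5$ post-synthesis iterations, exposure
recomputed every 4 steps), and a 16-mer prediction demonstration with a
6-trajectory pool.  The full-scale protocol numbers (100 replicates,
$10^6$ iterations, 150-trajectory pools) are exposed as configuration
defaults and verified as bookkeeping, not re-run.

## Known limitations

* The fixation-time contrast between crowded and uncrowded conditions is
  the least robust observable at desk scale: the chain can still slither
  through the static corridor network, so conformational arrest is
  gradual, the per-seed fixation times overlap between conditions, and
  only the medians over seeds separate cleanly (see the geometric caveat
  above).
* Heterogeneous crowder sizes and attractive crowder chemistry are out of
  scope; crowders act by volume exclusion only.
* The geometric secondary-structure assigner is a coarse surrogate for a
  proper assignment program and is only used when no assignment is
  supplied.
* All-atom detail (explicit side chains, electrostatics, solvation free
  energies) is outside the model by design.
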