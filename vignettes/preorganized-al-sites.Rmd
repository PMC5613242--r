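---
title: "Detecting pre-organized Al(III) binding sites in peptide ensembles"
author: "alsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pre-organized Al(III) binding sites in peptide ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

No experimental structure of Al(III) bound to the amyloid-beta peptide
exists, and none can be borrowed from other metals: Al(III) is a hard
Lewis acid that seeks anionic oxygen donors (above all carboxylates),
whereas the Cu(II)/Zn(II) amyloid complexes that are structurally
characterized are nitrogen-coordinated. `alsite` implements a
template-free alternative built on the pre-organization (conformational
selection) hypothesis: a flexible apo peptide transiently samples
conformations close to its metal-bound geometry, so binding-competent
arrangements can be found inside experimental NMR ensembles of the
*metal-free* peptide and then refined in place.

The pipeline has three stages:

1. **Coordination rules.** A curated table of quantum-cluster
   interaction enthalpies over candidate first-shell motifs (ligand
   classes: `C` carboxylate, `T` phenol, `A` backbone carbonyl, `W`
   water, `H` imidazole, `N` N-terminal amine) defines what a good
   Al(III) shell looks like: at least two carboxylates among at least
   two non-water ligands, coordination number 4-6, hexacoordination
   preferred. The package ships this table (`load_reference_table()`)
   and the first-shell descriptors and interaction energies of the 13
   refined Al-amyloid complex models (`load_complex_reference()`); it
   performs no quantum chemistry itself.
2. **Grid scan** (`detect_sites()`). A 1 A lattice over each conformer
   is filtered for points where at least three donor-bearing residues
   (at least two of them Asp/Glu) could plausibly coordinate a cation,
   and passing points are merged into candidate sites.
3. **Multi-objective genetic algorithm** (`evolve()`). Per site, an
   NSGA-II-style GA optimizes the metal position (a bounded offset from
   the site centroid) and the chi angles of the supporting side chains
   against three objectives; survivors are filtered
   (`filter_solutions()`) and completed to octahedral coordination with
   explicit waters (`build_complex()`).

## The objectives

For a genome (metal offset + chi angles) the evaluator returns:

* `clash` (A^3): summed analytic sphere-sphere overlap between the
  moved atoms (metal + re-posed side chains) and all other heavy atoms,
  with Bondi radii (C 1.70, N 1.55, O 1.52, S 1.80; Al uses its ionic
  radius 0.60 because the cation is far smaller than the neutral atom).
  Two exclusion groups apply. First, a moved atom is never checked
  against atoms of its own residue: 1-3, 1-4 and rotamer self-contacts
  are bonded-geometry energetics, not placement clashes, and with Bondi
  radii an ideally built carboxylate side chain would otherwise carry a
  constant ~1 A^3 of self-overlap. Second, the first coordination
  sphere (N/O atoms within the cutoff), its bonded parent atoms and the
  metal are mutually excluded: a donor 1.9 A from Al(III) and two shell
  oxygens 2.7 A apart are dative-bond geometry, 1-2 and 1-3 through the
  metal.
* `donor_score` (A-equivalent, lower better): the sum of
  |d - ideal_bond| over taxonomy donors inside the 2.5 A coordination
  cutoff, plus a hard penalty of 10 per donor missing below
  `min_donors` = 3, plus a mild penalty of 0.5 per vacant place below
  `target_cn` = 6. The vacancy term is a deliberate addition: without
  it, shedding a donor from the shell always lowers the score (one
  fewer deviation term), and the optimizer systematically abandons
  planted 4-6-donor cages for trivial 3-donor poses. A 0.5 A-equivalent
  cost per vacancy encodes the observation that the refined complexes
  are hexacoordinate almost without exception, while staying far below
  the hard shortfall penalty.
* `octa_dev` (degrees): RMS deviation of all shell-pair angles at the
  metal from the nearest octahedral ideal (90 or 180 degrees). Zero for
  any subset of ideal octahedron vertices; a chelating bidentate
  carboxylate (bite angle ~72 degrees) contributes an irreducible
  ~7-10 degrees, which is physical, not an artifact.

The ideal Al-donor bond length (1.90 A) brackets the 1.81-2.01 A range
of the refined complex shells; the water completion bond (1.95 A) is
the midpoint of that range. Tyr phenol is classified as a donor but
excluded from coordination counts by default: its binding requires
prior deprotonation, which makes it energetically inferior to a
carboxylate, and the deprotonation energetics are outside this
package's scope (`count_phenol`/`include_phenol` re-enable it).

## Grid-protocol choices

The published description fixes the intent (find "suitable
arrangements" around lattice points, referencing residues by their
C-alpha to keep flexibility) but none of the numerical knobs, so the
defaults here are the package's own, chosen once from geometry:

* `spacing` 1.0 A and `padding` 4.0 A: a true site can fall at most
  ~0.87 A from a lattice point.
* `calpha_radius` 7.0 A: a Glu C-alpha-to-carboxylate-oxygen reach of
  ~4.9 A plus a 2 A bond plus slack.
* `min_donor_residues` 3 with `min_carboxylate_residues` 2: three
  distinct donor side chains, at least two of them Asp/Glu, merging the
  screening rule with the cluster-model admissibility rule. Backbone
  carbonyls do not count here (the rule is about side chains) but
  remain available to the GA and the water-completion stage.
* `donor_atom_radius` 3.5 A (`use_donor_atoms = TRUE`): each supporting
  residue must also have a side-chain donor *atom* within 3.5 A of the
  point (the 2.5 A shell plus the worst-case lattice offset). This is
  the package's one substantive tightening of the published rule. With
  C-alpha referencing alone, the passing region around even a perfectly
  pre-organized octahedral cage is the intersection of 7 A balls -- a
  blob several Angstrom across whose centroid lies ~3 A from the true
  site, outside the GA's +-2 A offset box, so the pipeline could never
  refine its way back. Requiring the donor atoms themselves to be
  nearby is precisely the pre-organization condition, and localizes the
  centroid to ~1 A. The permissive C-alpha-only mode remains available
  behind the flag.
* `clash_floor` 1.5 A against carbon and sulfur, `donor_floor` 0.9 A
  against nitrogen and oxygen: lattice points buried in the peptide core
  are discarded, but a viable metal point is *necessarily* within
  bonding range (~1.9 A) of several oxygens, so holding N/O to the full
  1.5 A floor would reject the interior of any dense donor cage and
  leave only off-centre fringe points.
* `merge_radius` 3.0 A, single linkage: the clash floor around a donor
  cage carves the passing region into pockets that can be separated by
  one rejected lattice plane (~2-3 A), which a 2 A radius fails to
  bridge; 3 A reunites pockets of one cage while still separating
  genuinely distinct sites several Angstrom apart. How the original
  work aggregated grid points into its reported site count was never
  specified, so this is a documented, configurable choice -- and the
  package makes no attempt to reproduce that count, which depends on an
  unpublished structure list.

## Genetic-algorithm choices

The source describes only "a multi-objective genetic algorithm"; the
machinery here is standard NSGA-II: fast non-dominated sorting,
crowding distance, binary tournament on (rank, crowding), uniform
crossover (probability 0.8), per-gene Gaussian mutation (probability
0.25; sigma 0.3 A for the offset, 20 degrees for chi), elitist
environmental selection, everything tie-broken deterministically
(lexicographic genome order) so a seed fixes the run bit-for-bit.
Population 200 and 100 generations are the defaults for production
runs; the validation experiments below use 100 x 50 and 60 x 30.

One founder individual carries the unperturbed input pose (zero offset,
measured chi angles): under the pre-organization hypothesis the apo
conformation is the natural first candidate, and seeding it turns the
GA into a refinement of that hypothesis rather than a blind search. The
backbone never moves -- induced-fit relaxation belongs to the MD/QM-MM
refinement stage that is outside this package's scope.

After the final generation a short memetic polish refines the metal
offset of the best shell-forming solutions (up to 30, side chains
fixed) by Nelder-Mead on the donor objective; a polished genome
replaces its parent only if it improves the donor score without
breaching the clash threshold. The GA is good at finding basins and
mediocre at the last few tenths of an Angstrom; the polish supplies
exactly that, deterministically.

Survivor filters follow the published criteria: clash volume at most
`clash_max` and at least three N/O atoms within 2.5 A of the metal.
The published clash bound of 30 nm^3 (30 000 A^3) is honoured
literally but flagged: a clash of even 100 A^3 is sterically
catastrophic, so the figure is most plausibly a units slip for 30 A^3
in the source. `filter_solutions()` warns whenever a survivor's clash
lies in (30 A^3, 30 000 A^3], and `clash_max` is an ordinary
configurable parameter.

## Water completion

Surviving poses are completed toward hexacoordination: the ideal
octahedron is fitted to the existing shell directions by exhaustive
assignment (ordered selections of vertices, at most 720, with one
Kabsch rotation each -- exact, no heuristics), and a water oxygen is
placed 1.95 A from the metal at every vacant vertex whose water would
not overlap peptide atoms outside the coordination framework. A vertex
blocked by a just-out-of-shell donor stays empty, which reproduces the
occasional pentacoordinate complex seen among the refined reference
structures. Carboxylate denticity is labelled per residue: bidentate
(B) when both oxygens are within the cutoff, monodentate (M) otherwise.

## The synthetic-fixture generator

`plant_spec()`/`build_planted_model()` construct peptide models with a
known, planted octahedral site: donor residues (Asp/Glu/His/Tyr) are
built from internal-coordinate templates (standard amino-acid bond
lengths and angles, shipped as package data) and rigidly posed so their
donor atoms sit on ideal octahedron vertices 1.90 A from the chosen
site point; a bidentate carboxylate straddles two adjacent vertices
with both oxygens at 1.90 A. Spacer residues form extended segments
routed at least 4 A from the site, and the generator verifies at least
2.4 A separation between all non-bonded heavy atoms before returning.
`perturb_ensemble()` expands a model into an NMR-ensemble stand-in:
Gaussian chi noise per rotatable side chain plus small rigid-body
jitter per 3-residue segment (translation sd = `backbone_sigma`;
rotation sd = 10 degrees per Angstrom of `backbone_sigma`), rigid
segmenting avoiding unphysical bond stretching.

What the fixtures deliberately do not emulate: covalent continuity
between the rigidly placed pieces, Ramachandran-realistic backbones,
solvent, and the conformational correlations of real NMR ensembles.
Tests passing on fixtures therefore demonstrate that the machinery
recovers geometric ground truth under controlled noise -- not that real
amyloid ensembles contain such sites; that question belongs to the
original study's structure set, which is not redistributed here.

## Validation experiments and sizes

The test suite and `scripts/acceptance.R` recompute, at fixed seeds:

* worked examples on the packaged reference tables (ranking, charges,
  relative energies) -- exact equality with the printed values;
* clash volumes against a Monte-Carlo volume oracle (50 random sphere
  pairs, 10^6 samples each, agreement within 1%); pair distances are
  capped at 0.75 of the radius sum so the Monte-Carlo estimator itself
  has ~0.3% standard error;
* octahedral deviation: exactly zero on ideal vertices and invariant
  under 100 random rigid motions;
* exhaustive Pareto-rank verification for a 200-member population;
* parameter recovery: on the canonical planted fixture (three
  bidentate carboxylates spanning all six octahedron vertices -- the
  one O6 arrangement whose simultaneous-chelation point is unique --
  with two Ala spacers between donors) the detect-and-evolve pipeline
  (population 100, 50 generations) places the metal within 1.0 A of
  the planted position with at least three O donors in the shell, in
  at least 90% of 20 GA seeds. Plants containing monodentate
  carboxylates are unsuitable as recovery ground truth: their free
  second oxygens admit alternative chelation sites a few Angstrom away
  that legitimately outscore the planted pose;
* noise robustness: the same experiment at chi-noise sigma 0, 8 and
  15 degrees (12 ensemble members per level, a shared perturbation seed
  so the noise levels scale a common set of Gaussian draws) shows a
  non-increasing recovery rate.

These sizes were chosen as the smallest at which the stochastic rates
are stable; they are the package's validation conditions, not tuning
targets.

## Known limitations

* Energetics are reference data only: the package ranks motifs by the
  packaged enthalpies and never predicts an energy for an unseen motif.
  A classical scoring proxy was considered and rejected -- a
  pseudo-quantum score with no defined provenance would be worse than
  none.
* Backbone rigidity during the GA means sites requiring induced fit are
  invisible by design.
* The site count of a scan depends on lattice alignment and the merge
  radius; compare counts only across runs with identical parameters.
* His nitrogen donors satisfy the N/O survivor filter but carry no
  special weight; whether the original grid stage accepted them is not
  stated in the source and none survived its own filters.
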