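---
title: "Sequential carbohydrate docking onto disordered linkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential carbohydrate docking onto disordered linkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkerdock)
```

## The problem this package addresses

GntR-family transcription factors pair a winged helix-turn-helix
DNA-binding domain with a C-terminal effector-binding domain, joined by an
intrinsically disordered inter-domain linker. Carbohydrate effectors can
engage not only the canonical C-terminal pocket but also the linker itself
— individually weak, hard-to-see contacts that nevertheless accumulate:
over repeated docking rounds the same linker region fills with multiple
sugar copies held together by ligand–ligand hydrogen bonds. Detecting that
signature needs three things done consistently: a reproducible multi-ligand
docking protocol, geometric profiling of the resulting crowded complexes,
and a statistical baseline that separates preferred sites from generic
surface stickiness. `linkerdock` packages those three stages with synthetic
generators for every input, so the full analysis runs and is tested with no
external structures.

## Scoring model

A pose is scored by an empirical pairwise function in the Vina family.
Every receptor–ligand heavy-atom pair within a surface-distance cutoff
contributes two attractive Gaussians (contact at `s = 0` and a solvation-
like shell at `s = 3` Å), a quadratic clash penalty for `s < 0`, a
hydrophobic term when both atoms are apolar carbons (linear ramp, full
strength below `s = 0.5` Å, zero above 1.5 Å), and a hydrogen-bond term
when the pair is donor/acceptor-complementary (full strength below
`s = −0.7` Å, zero above 0). The weighted sum `c_inter` becomes a binding
free energy through the rotatable-bond penalty
`ΔG = c_inter / (1 + w_rot · n_rot)`; more negative is stronger. The
default weights are the published Vina coefficients, which keeps toy-system
outputs on the familiar kcal/mol scale; all of them are overridable through
`scoring_weights()`.

Three numerical choices deserve note:

- **The cutoff applies to the surface distance `s`, not the raw distance.**
  The exposed single-pair profile `score_pair_profile(class_i, class_j, s)`
  takes `s` directly and must agree exactly with `score_pose()` on the
  equivalent two-atom system, which forces one convention for both; the
  `s`-based rule is the one that makes a bare `s = 10 > cutoff = 8` query
  return zero.
- **Heavy atoms only.** Docked poses carry no hydrogens, so donor/acceptor
  capability is encoded as per-atom interaction classes assigned from a
  residue/atom-name rule table for proteins (hydroxyls are
  `donor_acceptor`, backbone N donor except proline, backbone O acceptor,
  His ring nitrogens both) and from element plus bond topology for ligands
  (hydroxyl O `donor_acceptor`, ring and carbonyl O acceptor, apolar C
  hydrophobic). Working without explicit protonation is a stated default,
  not a guess about how any particular study prepared its models.
- **No ligand intramolecular term.** Poses are kept clash-free by the
  search itself; conformational strain of the ligand is not scored. This is
  a documented limitation, acceptable for small rigid-ring sugars.

The van der Waals radii are fixed in code (C 1.9, N 1.8, O 1.7, S 2.0,
P 2.1 Å). Metals are kept and classed `metal` (they contribute only steric
terms); waters are dropped at parse time because docking targets apo
models.

## Pose search

`dock()` runs `n_runs` independent Monte-Carlo searches over translation,
orientation (quaternions) and rotatable-torsion angles, with Metropolis
acceptance at `temperature_like` (default 1.2 kcal/mol), then polishes each
run's best state with derivative-free Nelder–Mead and keeps the better of
the two — local optimization can therefore never worsen a pose. Poses
clashing with the receptor (any heavy-atom pair below `clash_floor = 2 Å`)
are discarded, survivors are ranked by ΔG with ties (to 1e-6) broken by
lexicographic translation order, which makes ranking fully deterministic.

Blind whole-surface docking uses a box around the entire protein with a
6 Å margin. Each run starts at a randomly chosen receptor atom offset by
2–6 Å in a random direction: in a whole-protein box a uniformly random
start frequently never reaches the surface within a desk-scale step budget,
whereas a surface-biased start always samples contact geometry and the
Metropolis walk then explores along the surface. The ligand centroid must
stay inside the box and atoms may protrude at most 2 Å, which avoids edge
artifacts. Run `r` seeds its RNG with `seed + r`, so serial and parallel
execution agree and two calls with one seed agree bitwise.

## Sequential protocol

`run_sequential()` executes the iterative multi-ligand protocol: round `k`
docks a fresh ligand copy against the protein plus the frozen poses of all
earlier rounds. Frozen copies are scored exactly like receptor atoms and
contribute no rotatable-bond penalty (the penalty is entropic and applies
only to the mobile ligand). Ten rounds is the default — enough to populate
preferred sites without accumulating rounds of pure noise. Three contracts
are enforced and tested: placed poses never move, protein atoms are never
modified, and the box is derived once from the bare protein (whether to
re-derive it as the complex grows is genuinely open; a fixed box keeps
rounds comparable and is the documented choice). Round `k` uses seed
`seed + 1000·k`. New copies must keep their centroid more than 1.5 Å from
every placed copy on top of the ordinary clash rules.

`rerun_with_retained_subset()` implements the validation rerun: ligands of
dropped rounds are removed and a fresh full protocol starts from the
protein plus only the kept copies. With nothing kept and the same seed it
reduces exactly to a from-scratch run, which is the identity case the tests
pin down.

## Interaction profiling

Hydrogen bonds are detected geometrically on heavy atoms: donor–acceptor
pairs across distinct units at distance ≤ 3.6 Å. That threshold is
deliberately stricter than the ~4.1 Å donor–acceptor limits common in
profilers that see hydrogens, because without protonation the angle term is
unavailable and distance must carry the false-positive control alone (when
hydrogens are present near a donor, a D–H···A angle ≥ 120° is additionally
required). A pair of two `donor_acceptor` atoms is reported once, with the
lower-serial atom as donor — an arbitrary but deterministic convention.

Ligand clusters are connected components of the graph over ligand copies
with an edge wherever a ligand–ligand H-bond exists or any heavy-atom pair
is within 4 Å; components below `min_size = 3` are not called clusters.
Components come from igraph; the tests check the partition against a
brute-force transitive-closure oracle.

## Region statistics

Region annotations map names to residue spans ("A:61-94"). A pose touches a
region when any heavy atom is within 4 Å of a region residue. Categories
follow the four-way heat-map scheme: linker only → `linker`; linker plus
any other region → `bridging`; non-linker regions only → `pocket`; nothing
→ `nonspecific`. Where a complex annotates additional named regions beyond
"linker" and "pocket", they are treated as pocket-class (CTD-side) sites —
the four-way scheme leaves that case open and this is the package's
resolution.

The background pools the ΔG of all nonspecific records of one
protein–ligand pair across conformers (one record per model × round;
linker, pocket and bridging records are all excluded) into mean, sample SD
(n−1) and n. Significance is `ΔG ≤ mean − 3·SD`, boundary inclusive, on
the affinity-strength axis — "above the background" means stronger, i.e.
more negative. With a degenerate zero-SD background only strictly stronger
values flag. Occupancy summaries count region-labelled rounds per model
(bridging counts toward the linker, since a bridging ligand occupies it)
and report mean ± sample SD over models. No multiple-testing correction is
applied by default, matching the practice the analysis emulates; the exact
Mann–Whitney U (full enumeration up to n1+n2 = 12, midrank ties, two-sided
tail probability around n1·n2/2) and a Shapiro–Wilk wrapper support group
comparisons. Shapiro–Wilk is the one statistic backed by the standard
`stats` routine rather than re-derived — it is a textbook procedure, not
part of this package's contribution.

## Sequence homology

`needleman_wunsch()` is a three-state Gotoh dynamic program with affine
gaps: a run of L gap positions costs `gap_open + (L−1)·gap_extend`, with
defaults BLOSUM62 / 10 / 0.5 mirroring the EMBOSS needle setup. Traceback
ties resolve diagonal > up > left. Tests verify the DP against exhaustive
alignment enumeration for short sequences. Published alignment scores for
specific regulator domain pairs depend on domain boundaries that are not
restated here, so they are not an acceptance surface; the package
guarantees the algorithm, not those numbers.

## What the synthetic world does and does not establish

`make_toy_protein()` builds each snapshot from ideal backbone internal
coordinates (N–CA 1.458, CA–C 1.525, C–N 1.329 Å): two α-helical domains
(φ = −57°, ψ = −47°) joined by a serine coil linker whose dihedrals are
resampled per snapshot around extended-coil values (φ = −120°, ψ = 130°)
with a configurable SD (default 15°, a mid-range flexibility that produces
linker RMSDs of several Å between snapshots while both domains stay
internally rigid). Snapshots failing a CA–CA clash check (< 3 Å non-bonded)
are resampled, at most 1000 times. Side chains are reduced to CB, plus OG
on the serine linker so the linker carries hydroxyl donors. Snapshot labels
run 10, 20, 30 … ns, mirroring a 10-ns MD sampling grid. A small "pocket"
region is annotated in domain 2 in addition to the linker so every
heat-map category can occur.

`make_toy_ligand("pyranose_like")` is a hexagonal 5C+1O ring with four
hydroxyls and an exocyclic CH2OH arm — topologically a sugar (ring O
acceptor, five `donor_acceptor` hydroxyls, exactly one rotatable bond),
geometrically idealized. `make_dg_table()` draws a Normal background and
inserts planted binders verbatim; its defaults (−4.5 ± 0.25 kcal/mol) sit
in the regime typical of nonspecific carbohydrate surface binding.

A green test on this world establishes that the pipeline's *contracts*
hold — determinism, frozen history, exact fixture recovery, statistical
calibration — not that any real protein binds any real sugar. The toy
protein has no genuine binding pocket, its surface chemistry is far poorer
than a real CTD, and the absolute ΔG values it produces (≈ −2 to −3.5
kcal/mol with desk-scale search budgets) are weaker than blind-docking
values on real models. Reproducing published background means, occupancies
or cluster sizes would require the original MD conformers and is explicitly
out of scope.

## Tunable parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cutoff` | 8 | Å (surface distance) | pair terms negligible beyond it |
| `w_rot` | 0.05846 | — | published entropic penalty per rotatable bond |
| `temperature_like` | 1.2 | kcal/mol | Metropolis scale; accepts ~kT-size uphill moves |
| `n_runs` | 8 | — | restart count (exhaustiveness analog) |
| `clash_floor` | 2.0 | Å | minimum receptor–ligand heavy-atom distance |
| `n_rounds` | 10 | — | sequential protocol depth |
| `d_max` | 3.6 | Å | heavy-atom H-bond limit (no protonation) |
| `contact_max` | 4.0 | Å | region contact / cluster edge threshold |
| `min_size` | 3 | — | smallest reported cluster |
| `k` (significance) | 3 | SD | 3-SD criterion on the strength axis |
| `gap_open`/`gap_extend` | 10 / 0.5 | score | EMBOSS-style affine gaps |

## Known limitations

Rigid receptor; no ligand intramolecular strain; no protonation-state
prediction; heavy-atom H-bond detection cannot distinguish donor from
acceptor in hydroxyl–hydroxyl contacts; desk-scale Monte-Carlo budgets are
sized for the toy systems and should be raised (`n_runs`, `n_steps`) for
real models; the exact Mann–Whitney mode is limited to 12 observations by
its enumeration cost.
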