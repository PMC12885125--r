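---
title: "Ensemble docking enrichment and conformational analysis with ensdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble docking enrichment and conformational analysis with ensdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ensdock)
```

## The problem

When a kinase acquires a resistance mutation, the question a treatment
team needs answered quickly is whether the mutation changes the protein
enough to weaken drug binding, and whether any known compound still binds.
A practical computational route is: model the wild-type (WT) and mutant
structures, relax and sample them with molecular dynamics (MD), cluster
the trajectory into a small ensemble of representative receptor
conformations, dock a benchmark library with known actives against every
conformation and binding site, and judge each ensemble member by how well
it enriches the known actives over decoys. More expensive quantum-chemistry
single-point energies on a small binding pocket can then rank variants for
a specific drug.

`ensdock` implements the *analysis* layer of that workflow. Structure
prediction, MD, the docking engine and the quantum-chemistry engine are
all upstream tools whose outputs this package consumes as plain files
(PDB, multi-model PDB, CSV score tables, component-energy tables). A
synthetic-data module generates statistically controlled stand-ins for all
of those inputs, so every analysis here is exercised end-to-end, with
known ground truth, without running any simulation.

## Structures, trajectories and windows

Structures are deliberately Calpha-only (`structure3d`): all of the
comparative analyses here are Calpha RMSD/RMSF analyses, and a single
coordinate per residue keeps every operation unambiguous. The one
exception is ligand-pocket extraction, which re-reads the full-atom file.
Residue numbering is taken verbatim from the PDB file and is assumed
pre-harmonized across variants (e.g. UniProt numbering), so residue
correspondences (`map_shared_residues()`) are by residue *number*, never
by sequence alignment. A deletion variant simply leaves unmapped numbers;
the mapped count is reported so missing-loop effects are visible rather
than silent.

Mutation strings follow clinical notation: `"T790M"` is a substitution,
`"del746-750"` an explicit deletion range, and a named alias such as
`"del19"` is accepted only together with an alias table giving its range,
because the name itself carries no coordinates.

Local structure comparison uses a residue window around the mutation site.
Two window rules are provided: a sequence window (`|resnum - anchor| <= k`)
and a spatial window (Calpha within `r` Å of the anchor's Calpha,
threshold closed, `d <= r`). The spatial window is measured **once in a
designated reference structure** and the same residue numbers are applied
to every structure being compared; per-structure windows would make the
pairwise RMSDs incomparable. Whether the windowed RMSD should be
superposed on the window itself or on the whole domain is genuinely open;
both are provided (`superpose_scope = "selection"` or `"whole"`), and the
default is the local fit, which isolates local deformation around the
site rather than rigid-body motion of the window relative to the domain.

Superposition is a from-scratch Kabsch implementation with the reflection
corrected by sign-flipping the smallest singular vector, so chirality is
always preserved; the tests check it against an exhaustive SO(3)
grid-search oracle to 1e-3 Å.

```{r}
cfg <- synth_config(seed = 1, n_residues = 50)
wt  <- make_chain(cfg, id = "wt")
mut <- make_mutant(wt, "T25M", cfg)
win <- distance_window(wt, 25, r = 5)
c(site = ca_rmsd(wt, mut, win),
  far  = ca_rmsd(wt, mut, distance_window(wt, 45, r = 5)))
```

## Clustering model sets and trajectories

`pairwise_rmsd()` + `hierarchical_cluster()` reproduce the heatmap-style
comparison of predicted models against experimental structures: an RMSD
matrix over the common window, agglomerative clustering (default complete
linkage) cut at a user-chosen `k`, clusters numbered in dendrogram leaf
order — the order in which they appear along the diagonal of a clustered
heatmap. No objective `k`-selection rule is imposed because none is
defensible at these sample sizes; `silhouette_widths()` is provided as a
diagnostic, not a decision. `composition()` then summarises each cluster's
WT/mutant makeup as one-decimal percentages (raw fractions are kept
alongside, so the rounding is presentation, not data).

Trajectory clustering follows the classic GROMOS neighbour-count scheme:
all pairwise superposed RMSDs, then repeatedly take the frame with the
most neighbours within the cutoff as a cluster centre, emit centre +
neighbours, remove them, repeat. Ties in neighbour count break to the
lowest frame index, so the procedure is deterministic. Neighbour counting
excludes the frame itself; a centre with no neighbours forms a singleton
cluster. The centre is the representative exported for docking; the
member with the lowest mean RMSD to the rest is also recorded
(`min_avg_member`) because the two usually coincide but need not. The
tightness statistic for *both* clusterers is that same minimum mean RMSD
to the rest, with singletons scoring 0 — one definition, used everywhere.
Cluster sizes always sum to the number of input frames.

The RMSD cutoff has **no default**: it is meaningful only relative to the
fluctuation scale of the particular trajectory, so the user (or CLI flag)
must supply it. Frames are superposed per pair over the selection before
the RMSD is taken, which makes the tool robust to trajectories that were
not pre-aligned.

```{r}
tr <- make_trajectory(synth_config(seed = 2, n_frames = 60,
                                   conformer_separation = 2,
                                   jitter_sigma = 0.05))
gromos_cluster(tr, cutoff = 0.5)
```

`rmsf()` reports per-residue Calpha fluctuation about the mean position
after a whole-topology fit of every frame; with the default
`superpose_to = "mean"` the frames are fitted to frame 0, averaged, and
refitted to that mean before fluctuations are measured. A single-frame
trajectory is rejected rather than silently returning zeros. Note that a
whole-topology fit can absorb part of a large, localized displacement
when the rest of the molecule is small or degenerate (e.g. nearly
collinear); the analytic two-frame test therefore pins the fit with a
large globular anchor.

## Enrichment analysis

Docking results are long-format records `(compound_id, conformation,
site, energy)` in kcal/mol, lower = better (the docking engine reports
free energies of binding). The `conformation_site` labels follow the
"c_s" convention: conformation `c` indexes the receptor along the
trajectory, with 0 the starting (modelling) structure, and `s` the
predicted binding site within it. Site discovery and grid boxes are
upstream inputs; site ids are opaque integers here.

Aggregation and ranking rules are fixed and deterministic:

* duplicate `(compound, conformation, site)` rows keep the best (lowest)
  energy, with a warning;
* `"best"` aggregation is the minimum over available rows, `"average"`
  the mean over available rows only — docking failures are routine, and
  imputing a worst case for missing rows would bias enrichment;
* energy ties rank lexicographically by compound id;
* the top-`q` cutoff is `floor(q * N)` compounds — conservative and
  deterministic, since no rounding convention is universal;
* an active named in the actives list but absent from the scores stays in
  the denominator, so the enrichment curve tops out below 100% instead of
  hiding the loss.

`enrichment_curve()` emits the full step curve (fraction screened vs
percent of actives found) plus the random diagonal;
`top_fraction_recovery()` reports recovery and enrichment factor at a
fraction; `better_than_random()` flags every conformation_site whose
recovery at the evaluation fraction is strictly above the diagonal. That
flag is the marginal curve-above-random comparison itself, with no
significance margin: under a no-signal null it fires at the
hypergeometric rate P[X > floor(qN)·K/N] — about 42% for a screen of 120
actives among 2620 compounds at the top 10% — so per-variant flag
*counts* are comparative summaries, not detections. The tests calibrate
this null rate exactly and verify that genuinely shifted conformations
are flagged every time; a selection rule that controlled false positives
would need replicate docking runs or an explicit null model, which the
single-number-per-compound input cannot support.

Whether the "average" combination should average energies before ranking
or average ranks is ambiguous; energies are averaged here (matching the
aggregation used for "best"), and rank-averaging is deliberately not
offered to keep the surface unambiguous.

`select_hits()` is the tier-1 multi-conformation selection: a compound
qualifies when it is in the top `q` of at least `min_conformations`
per-conformation_site rankings (default 2 — "multiple" is not otherwise
quantified), ordered by rankings hit, then best energy. Tier-2 expert
review is out of scope by design.

```{r}
st <- make_score_table(synth_config(seed = 3, n_actives = 120,
                                    n_decoys = 2500, n_conformations = 5,
                                    signal_conformations = c(0, 1, 2)))
better_than_random(st, at = 0.1)
```

## Binding-energy assembly

The quantum-chemistry stage reduces, on this side of the interface, to
`E_binding = E_complex − (E_protein + E_ligand)` per complex (all
kcal/mol; unit conversion happens upstream). The printed form of this
equation is sometimes shown without parentheses; the parenthesised
interaction-energy reading is the only one for which favourable
complexes come out negative, and it is what `binding_energy()` computes.
`compare_variants()` sorts complexes most-favourable-first, flags
positive binding energies as unfavourable, and derives a variant
preference string from the most favourable row per variant. The engine
adapter contract is just a CSV of `label, variant, e_complex, e_protein,
e_ligand`; whether the apoprotein pocket was relaxed before its
single-point energy is an upstream decision the arithmetic is agnostic
to. `pocket_residues()` produces the matching input on the structure
side: every protein residue with any atom within `r` Å (closed) of any
ligand atom, optionally written out as a pocket+ligand PDB fragment.

## What the synthetic data does and does not emulate

The generators are pure functions of their configuration (seed included):
reruns are bit-identical, and ground truth (conformer assignments, signal
conformations, scripted pocket distances) is always returned with the
data, so tests never re-derive it.

* `make_chain()`: an idealized Calpha trace with exactly 3.8 Å
  consecutive spacing along a smooth random curve.
* `make_trajectory()`: frames drawn from a few base conformations with
  configurable occupancy weights, plus i.i.d. Gaussian jitter
  (`jitter_sigma` is the per-coordinate sd, so two frames of one
  conformer sit about `sigma * sqrt(6)` apart in RMSD). Conformers are
  separated by independent centred displacement fields scaled so pairwise
  RMSDs land near `conformer_separation`.
* `make_mutant()`: renames the site residue and displaces residues within
  the perturbation radius by a fixed magnitude in random directions.
* `make_score_table()`: decoy energies Normal(mu, sigma), actives shifted
  down by `active_shift` in the signal conformations only; independent
  across conformation/site, as separate docking runs are.
* `make_complex()`: a toy protein-ligand PDB whose residues sit at
  scripted nearest-atom distances from a single-atom ligand, so pockets
  are known by construction (the default set plants a 4.9/5.1 Å pair
  around the 5 Å threshold).

Defaults mirror the study conditions the package targets: screens of 120
actives against 2500 decoys, trajectories of 100 recorded frames, three
conformers with occupancies 0.6/0.3/0.1, 2 Å conformer separation,
0.05 Å jitter, a 2 kcal/mol active shift against unit-sd decoy energies.
Gaussian noise everywhere is the simplest model with a controllable
signal-to-noise ratio; real MD frames and docking scores are neither
Gaussian nor independent, and the toy conformers are well-separated
metastable states rather than a continuous conformational landscape. A
passing suite therefore demonstrates that the *analysis rules* are
implemented exactly (they agree with brute-force oracles and analytic
cases), not that the upstream physics would reproduce any particular
biological result.

Problem sizes in the test-suite and acceptance runs are chosen for
tightness of the checks, as the package's own choice: the exhaustive
clustering comparison uses 200 random trajectories of 2–12 frames (small
enough that the brute-force rule is literally enumerable), planted
conformer recovery uses 60-frame trajectories over 50 seeds, and the
enrichment calibration uses 1000 random rankings at the full 120/2620
screen size.

## Numerical choices and degenerate inputs

* Distance thresholds are closed (`d <= r`) everywhere; the convention is
  fixed once and boundary cases are tested on exact fixtures.
* Kabsch refuses fewer than 3 points or mismatched lengths; windowed RMSD
  refuses superposition scopes of fewer than 3 mapped residues and empty
  selections after mapping.
* Neighbour-count ties and energy ties always break deterministically
  (lowest frame index; lexicographic compound id).
* Insertion-coded residues are rejected with a clear error; multi-chain
  files default to the first chain unless one is named.
* PDB coordinates round-trip to the format's 1e-3 Å precision; topology
  (residue numbers and names) round-trips exactly.
* A file with no MODEL records is one model with index 0; model indices
  and frame indices are 0-based throughout, matching the
  conformation-numbering convention where 0 is the pre-MD structure.

## Known limitations

* Residue correspondence is strictly number-based; structures that are
  not pre-harmonized to a common numbering need external renumbering
  first.
* No mmCIF input, no sequence-alignment mapping, no structure
  preparation; the pocket PDB fragment is raw extraction, not a prepared
  quantum-chemistry input.
* The enrichment flag has no significance control (see above); use the
  per-variant counts comparatively.
* The matrix `plot()` method is a diagnostic shaded image, not a
  clustered heatmap with dendrograms.
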