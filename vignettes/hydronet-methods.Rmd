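---
title: "Water-mediated allosteric networks, ion occupancy and the two-state model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-mediated allosteric networks, ion occupancy and the two-state model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydronet)
```

hydronet quantifies how buried, structured water shapes the allosteric core
of seven-transmembrane-helix (7TM) receptors and their designed variants.
This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, the design choices made
where the design was genuinely open, and what the synthetic fixtures do
and do not demonstrate.

## The scientific setting

G protein-coupled receptors switch between inactive and active
conformations. Helices 1-5 keep essentially the same backbone in both
states ("static"), while helices 6-7 rearrange substantially
("switchable"). The buried core between these helices is wet: ordered
water molecules bridge polar side chains across the static-switchable
interfaces, and the density of such bridges correlates with how easily the
receptor switches. hydronet takes structures with explicit waters plus a
residue annotation (Ballesteros-Weinstein codes, helix index, helix class)
and computes the water-mediated interaction counts, an ion-site occupancy,
and activity predictions that drive design selection.

## Interaction graphs and counting rules

Hydrogen bonds are detected geometrically between polar heavy atoms:
donor/acceptor role compatibility from a built-in per-residue chemistry
table, a heavy-atom distance window (defaults 2.4-3.5 Å), and a
hydrogen-free angle proxy — the antecedent-donor-acceptor angle must be at
least 90° — evaluated at the donor and skipped when the donor is a water
(a water can always reorient its hydrogens). When explicit hydrogens are
present, detection tightens with an H-acceptor cutoff (2.5 Å). These
cutoffs are deliberately configurable: structure sets relaxed under other
force fields may need recalibration of the window to reproduce their
published counts, and `hbond_criteria()` exposes every constant.

Bonds are collapsed to a node-level graph: one node per residue, one per
water; bidentate atom contacts between the same two partners form a single
edge with a multiplicity attribute. Two counts summarize a structure:

* **Total water-mediated bonds** — edges with at least one water endpoint
  (residue-water and water-water).
* **Static-switchable water-mediated interactions** — every residue-water
  or water-water edge lying on a path
  static residue → water (→ water) → switchable residue, counted once.
  One single-water bridge contributes 2; one two-water chain contributes
  3. Chains of three or more waters do not mediate: the rule names exactly
  one intermediate water-water hop, and we enforce that reading.

A design with more static-switchable interactions than the reference
receptor is classed `Hyd_high`, fewer `Hyd_low`. The canonical reference
count is 20 (with a total of 25) for the wild-type template receptor, so
`reference_count = 20` is the default anchor for classification.

For model ensembles, water positions from the lowest-energy fraction of
models (default 10%, rounded up, never fewer than one model) are pooled
and clustered by complete-linkage at a 1.0 Å cut; clusters seen in at
least two distinct models become consensus solvent nodes. The 1.0 Å
radius and the 2-model support floor are our choices — "positions common
to multiple models" fixes neither number — and both are arguments of
`cluster_waters()`.

Interface matrices count, per helix pair, direct residue-residue edges
plus distinct residue pairs bridged through one or two waters; the
diagonal (intra-helix) is zeroed. Solvated-residue set comparisons report
the fraction of the query structure's water-bonded side chains that are
also solvated in a reference; the query denominator is the default and a
Jaccard variant is available, because the denominator convention is not
uniquely determined by the quantity's usual presentation.

## The two-stage ion-placement protocol

Buried sodium sites are scored by exhaustive voxel sampling. Stage 1
scores every position of a 0.5 Å grid spanning ±2.5 Å around the site
centre — exactly 1,331 states. Poses are clustered by average linkage on
a combined metric, ‖Δposition‖ + λ·‖Δdistance-vector‖/√L (λ = 1, L the
number of site residues), cut at 1.0 Å; the distance vector holds the
distances from the ion to the nearest polar heavy atom of each site
residue. The ten best-scoring clusters (by best member energy) seed stage
2: a 0.05 Å grid over ±0.2 Å around each seed — 7,290 evaluations — and
the ten best fine poses are reported.

Two open choices deserve a note. Cluster ranking uses the best member
score ("mean" is available): a cluster's reachable optimum, not its
average, is what refinement exploits. And fine grids are centred on each
cluster's *best-scoring member*, not its centroid. We began with centroid
centring, but with a rigid-receptor scorer the protocol's stages do not
move the ion between evaluations, and an average-linkage centroid can sit
farther from the basin optimum than the ±0.2 Å refinement reach: on
planted sites this produced multi-Ångström misses of the brute-force
optimum. Centred on the best member, the fine box always contains the
coarse optimum, and the protocol matches an exhaustive 0.01 Å scan to
grid precision. `fine_center = "centroid"` remains available.

### The default scorer

The package's scorer is a documented, deterministic stand-in for a full
hydration/repacking energy function (which is out of scope here):

* screened Coulomb over charged/polar atoms within 8 Å, with a
  distance-dependent dielectric ε(r) = 4r and a soft-core offset
  (δ = 0.8 Å) that keeps the term bounded at short range;
* soft-sphere repulsion below per-element ion contact distances
  (O 2.2, N 2.4, C 3.0, S 2.8 Å), r⁻⁸ growth capped at 10⁴ REU so
  clashes are large but finite;
* first-shell completion: up to six ideal octahedral waters at 2.35 Å
  from the ion, each allowed if no heavy atom lies within 2.4 Å,
  contributing −2.0 REU each plus a 0.35 REU crowding penalty per water
  pair.

All constants live in `scorer_config()`, and any object satisfying the
scorer contract (deterministic position → finite score) can replace it in
`run_two_stage()`. The scorer is rigid-receptor: no side-chain repacking
occurs between stages; the shell term absorbs the first-order hydration
effect.

The bulk reference state is an ion in a 5 Å cubic box (125 Å³):
coordination numbers n = 0..8 on ideal octahedral-derived directions are
enumerated and the minimum ion-water energy returned. With the default
constants the optimum is six waters (−6.75 REU) — the shell increments
were chosen so that the marginal water turns unfavourable between n = 6
and n = 7, reflecting the canonical sodium coordination number.

Occupancy follows the two-state Boltzmann form
occ = 1/(1 + exp(κ·ΔE/RT)) with ΔE the site-minus-bulk energy in REU,
RT = 0.593 kcal/mol (298 K) and κ the REU→kcal/mol scale. Because the
score scale is not calibrated thermodynamically, conclusions should be
drawn at the rank level: `scaling_sensitivity()` sweeps κ ∈ {1, 2, 3} and
reports whether the design ranking by occupancy survives the sweep.

## The allosteric two-state model

Without ligand, basal activity equals the active-state fraction of the
receptor: BA = K_R/(1 + K_R) with K_R = exp(−ΔG_apo/RT), i.e.
ΔG_apo = −RT·ln[BA/(1 − BA)]. `ba_from_dg()`/`dg_from_ba()` are exact
inverses; activities at 0 or 1 are rejected rather than clipped, since
they imply infinite free energies. Near half-activation the logistic is
quasi-linear — `quasilinearity_check()` quantifies this by dense sampling
and a least-squares line (R² > 0.999 over BA ∈ [0.4, 0.6]) — which is
what justifies fitting measured basal activities linearly against
computed ΔΔG_apo values and quoting a Pearson correlation
(`fit_activity_energy()`; Pearson, not Spearman, because the quantity of
interest is the best linear fit). The correlation is invariant to the
REU→kcal/mol scale.

## Design selection

Three criteria order designs for experimental validation, with thresholds
exposed in `selection_config()`:

1. designs destabilizing **both** states beyond 8 REU are discarded as
   likely unfolded (single-state destabilization is the design lever and
   is retained);
2. ΔΔG_apo above 5 REU flags a likely loss of signalling (`c1_loss`);
3. static-switchable hydration below 18 flags broken connectivity
   (`c2_fail`).

Ranking is lexicographic: unflagged first, by hydration count descending,
ties by ΔΔG_apo ascending, then by ion interaction energy ascending —
the ion term enters only as a tie-break because it is a second-order,
less discriminative effect. The final tie-break on design id makes the
order total and permutation-invariant. The thresholds are typical
observed values, not sharp physical constants; they are configuration,
not code.

## Conservation analysis

`map_columns()` walks a reference row of a pre-filtered class-A alignment
(gaps skipped) to map BW codes onto columns; `site_conservation()` reports
residue frequencies with gapped sequences excluded from the denominator
(the standard convention; `count_gaps = TRUE` switches it), and
`motif_cooccurrence()` counts sequences carrying at least k of a design's
substitutions simultaneously. The alignment's E-value pre-filter is input
provenance: the package computes no database statistics.

## Synthetic fixtures and what they show

`make_bundle()` builds ideal α-helices (1.5 Å rise, 100°/residue) on a
circle of radius 8.5 Å, alternating direction, with backbone N/CA/C/O
(carbonyls along the helix axis), Cβ, and idealized single-rotamer polar
side chains; serines populate inward-facing positions by default. The
annotation reuses the helix.position code convention so all downstream
reporting works unchanged, with helices 1-5 static and 6-7 switchable.

`plant_water_network()` places bridge waters at 2.8 Å from their anchors
(two-water chains 2.8 Å apart), verified by direct distance arithmetic
that is independent of the bond-detection code: intended contacts inside
the bond window, all unintended polar atoms and foreign waters beyond
3.6 Å, donor-only anchors approached at a workable angle. The expected
counts (2 per opposite-class single bridge, 3 per chain) are therefore
analytic ground truth, and `random_planted_fixture()` adds same-class
decoy bridges that increase the total count without touching the
static-switchable count.

`make_ion_site_model()` arranges three carboxylates on a cone below the
equator (C3-symmetric), locates the scorer's global minimum by dense
scanning, translates the cage so the minimum sits at the requested
centre — mirroring real inputs, where the grid anchors at the known ion
position — and fails on ambiguous (near-degenerate, spatially spread)
optima. `strip_ion_site()` removes the carboxylate oxygens but keeps the
carbon scaffold: a cage that occludes shell waters without attracting the
ion, making the site less favourable than bulk.

`make_activity_dataset()` draws ΔΔG_apo uniformly over [−4, 4] REU for
14 designs and sets BA = 0.25 − 0.05·ΔΔG + N(0, σ), clipped into
(0.01, 0.99) with clips counted. When σ is not given it is calibrated to
the realized design, σ = |slope|·sd(ΔΔG)·√(1/r² − 1) with target
|r| = 0.91, so the generating relation has exactly the intended
signal-to-noise for the sampled energies. The defaults mirror the study
conditions the package targets: fourteen designs, basal activities of a
few to a few tens of percent, and a strong negative activity-energy
relation.

These fixtures establish that the counting rules, the sampling protocol
and the fitting machinery are correct against analytic or brute-force
ground truth. They do not establish realism: ideal helices carry no
packing strain, single-rotamer side chains no conformational ambiguity,
the scorer no calibrated thermodynamics, and planted waters no occupancy
disorder. Reproducing published counts on real deposited models would
additionally require calibrating the hydrogen-bond window against the
force field that produced them, and crystallographic inputs bring
altlocs, missing side chains and hydrogen-free coordinates — handled, but
not exercised, by the fixture path.

## Numerical choices and degenerate inputs

* Altloc resolution keeps the highest-occupancy conformer (ties:
  alphabetical altloc); counting rules assume single-conformer input.
* The lowest-energy ensemble fraction rounds up and never selects zero
  models; energy ties keep input order.
* Hierarchical clustering (waters and poses) uses `stats::hclust`;
  single-observation inputs bypass clustering.
* Grid specifications require extent/spacing to be integral, so position
  counts are exact; positions are generated in lexicographic order and
  pose ties are broken by coordinates for bitwise-reproducible output.
* The two-stage protocol is deterministic end to end; every source of
  randomness in the package (fixtures, datasets) is an explicit seed
  argument.
* Problem sizes used in the shipped checks — 20 randomized network
  fixtures, a 0.01 Å oracle scan over ±0.3 Å (226,981 evaluations), a
  1,000-seed correlation Monte Carlo at n = 14 — were chosen to give
  stable statistics at interactive runtimes.

## Known limitations

* The hydrogen-bond criteria are geometric stand-ins, not an energy
  function; absolute counts on real structures depend on the calibration
  of the distance window.
* The ion scorer's energies are not thermodynamically calibrated;
  only relative (rank-level) statements are supported, which is why the
  κ sweep is part of the surface.
* Water chains longer than two are never counted as mediating, by rule;
  systems with longer ordered chains would need an extended definition.
* The conservation module assumes the reference row's ungapped positions
  map linearly onto author residue numbers (offset configurable);
  structures with internal numbering jumps need an explicit site table.
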