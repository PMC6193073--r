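---
title: "Water-inclusive residue interaction networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-inclusive residue interaction networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroRIN)
```

## The model

A residue interaction network (RIN) abstracts a protein structure into an
undirected graph: nodes are amino-acid residues, edges are spatial contacts.
hydroRIN extends this abstraction to the solvation state of the structure by
treating ordered (crystallographic) water molecules as first-class nodes.
Waters resolved by X-ray diffraction are the least mobile part of the
hydration network — they hydrogen-bond to surface residues and to each other
— so a contact graph over residues *and* waters captures communication
routes that a protein-only ("dry") graph misses.

Contacts are defined on heavy-atom distances:

* **residue–residue**: an edge when the minimum distance over all heavy-atom
  pairs of the two residues is strictly below `d_rr` = 5 Å;
* **water–residue and water–water**: strictly below `d_w` = 3.5 Å, the
  hydrogen-bond range for a water oxygen;
* **interface**: a residue is at the protein–protein interface when any of
  its heavy atoms lies within (inclusive) `d_int` = 7 Å of any heavy atom of
  the partner chain group; a *water* is interfacial when it is adjacent in
  the RIN to at least one interface residue.

Four network variants are built from one structure: `dry` (waters dropped
before edge detection), `wet` (waters as nodes), `interface_waters` (only
waters adjacent to an interface residue survive, with water–water contacts
among survivors retained), and `wet_uniform` (a control using a single
3.5 Å cutoff for *all* contacts, removing the threshold asymmetry between
residue and water edges). Because water-involving edges are detected
separately, a wet RIN restricted to its residue nodes is always identical to
the dry RIN — water inclusion can only ever add paths, not rewire
residue–residue contacts. This is asserted as a test invariant.

### Boundary conventions

The contact rules use strict `<` ("below 5 Å"), the interface rule inclusive
`≤` ("within 7 Å"). Exact-boundary geometries have measure zero in real
coordinates, but fixing the conventions makes the behavior testable; the
test suite pins 4.999/5.0, 3.499/3.5 and 6.9/7.0/7.1 Å cases.

## Centrality analyses

Two node-importance measures are computed per network, both based on
unweighted shortest paths:

* **RCA** (residue centrality analysis): `raw_i = L(G − i) − L(G)`, the
  change in average shortest path length when node *i* and its incident
  edges are removed. Nodes whose removal lengthens communication get
  positive values.
* **BCA** (betweenness centrality analysis): the unnormalized shortest-path
  betweenness of *i*, i.e. the sum over node pairs of the fraction of
  shortest paths crossing *i* (Brandes' algorithm via igraph).

Raw values are standardized into Z-scores, `z = (x − μ)/σ`, with μ and σ the
mean and **population** standard deviation over **all** nodes of the same
network. A node with `z ≥ 2` (inclusive) is *central*.

Three normalization choices deserve emphasis:

1. **Shared population.** In a wet RIN, residues and waters are standardized
   together. Waters are peripheral and score low, which pushes residue
   Z-scores up; this compensation is part of the phenomenon being measured,
   not a nuisance, so it is deliberately not removed by per-kind scaling.
   A side effect worth knowing: removing even an *isolated* water changes
   the population size, so Z-scores (never raw values) of all other nodes
   shift slightly; a node sitting exactly at Z = 2 can cross the cutoff.
2. **Population (not sample) SD**; zero spread maps all Z to 0 (cycles and
   complete graphs yield all-zero Z for both methods).
3. **Scale invariance.** Z-scores are invariant under `x → a·x + b` with
   `a > 0`, so the betweenness normalization convention cannot affect any
   reported Z — asserted as a property test.

### Disconnected graphs

The average shortest path length `L` is the mean over *connected* unordered
node pairs only; pairs in different components drop out of numerator and
denominator, and a graph with no connected pair has `L = 0`. Removal-induced
disconnection is thereby penalized or rewarded through the changed pair set
(removing a star hub, for instance, yields the unique minimum raw RCA
value). This is the simplest convention that is well defined for every
input; it is recorded in each result's metadata, and absolute Z values under
a different disconnection convention would differ slightly.

## The differential analysis

For a wet/dry pair the package reports, per method: **added** central nodes
(central wet, not dry — waters can appear here), **lost** central nodes, and
the per-residue shift `ΔZ = Z_wet − Z_dry` with `μ(ΔZ)` and population
`σ(ΔZ)` over residue nodes (waters have no dry counterpart) plus `μ` and `σ`
of the wet water Z-scores. The **added-residue shift**,
`(mean ΔZ of added central residues − μ(ΔZ)) / σ(ΔZ)`, asks whether newly
central residues rose *more* than the global water-driven shift — a positive
value means the additions are not a normalization artifact. Across methods,
the union and intersection of added sets are reported, and the union can be
restricted to interface residues.

An exclusion policy (e.g. `hisTagExclusion()` for affinity-tag histidines
whose centrality is a construct artifact) filters the *reported* label sets
only; a test asserts bit-identical statistics with and without exclusions.

The **water-removal experiment** removes waters by selector — the single
maximum-degree water (ties broken lexicographically), all waters of degree
≥ k, or an explicit list such as family-conserved waters — recomputes both
centralities, and compares central residue sets before and after. An empty
symmetric difference indicates the water network acts globally rather than
through specific molecules.

## The synthetic generator

`generateComplex()` exists so that every pipeline stage is testable without
structure downloads. It emulates what the contact rules see in a real
two-chain complex, not protein chemistry:

* each chain is a serpentine walk on a 3.8 Å grid (Cα-like spacing) through
  a near-cubic block, so consecutive residues are always in contact and the
  residue subgraph is dense and connected, like a folded domain (mean
  residue degree ≈ 12 at the defaults);
* residues are clusters of 3 pseudo-atoms within 1.5 Å of the center;
  residue names cycle through the 20 standard codes for labeling realism;
* the chains face each other across a 5 Å backbone gap, giving a nonempty
  7 Å interface and a realistic sprinkling of direct cross-chain contacts
  (a 30 Å gap gives an empty interface);
* waters are single oxygens rejection-sampled into a 2.8–3.4 Å shell from
  the nearest protein atom (guaranteeing ≥ 1 contact under the 3.5 Å rule)
  with ≥ 2.6 Å mutual spacing — hydrogen-bond-like geometry that leaves
  waters peripheral and low-degree, as in crystal structures. Sampling is
  deterministic given `seed`; the retry budget (default 5000 attempts per
  water) makes failure an explicit, diagnosable error rather than an
  infinite loop.

Default sizes (30 residues/chain, 120 waters) keep a full wet/dry/RCA/BCA
replicate under a second, so the 20-replicate property suite runs in well
under a minute.

What the generator does **not** emulate: side-chain packing and chemistry,
buried waters and cavities, B-factor/occupancy noise, crystal contacts, and
the ~10× larger node counts of real complexes. Passing the synthetic suite
therefore shows the *mechanisms* (wet networks denser; waters peripheral
with sub-2 Z-scores; water inclusion adding central residues with
above-average ΔZ) — it does not certify quantitative agreement with any
particular deposited structure, which is why the file-based workflow keeps
all thresholds and conventions in its run metadata for comparison against
independent analyses. At this small scale one mechanism visibly differs
from large complexes: removing all degree-≥5 waters can flip a few
borderline central residues, because each water carries a larger share of
the network.

```{r example}
s <- generateComplex(synthParams(seed = 7))
res <- runPipeline(s, waterRemoval = list(list(selector = "degree_ge", k = 5)))
res$report
```

## Numerical and degenerate-input choices

* Tolerances: Z normalization is checked to 1e−9; oracle agreement (BCA vs
  exhaustive path enumeration, RCA vs naive remove-and-recompute) to 1e−10.
* AltLoc conformers: highest occupancy wins, ties broken by altloc code
  order — deterministic parsing of disordered side chains.
* Hydrogens are removed by default (X-ray inputs generally lack them, and
  their inclusion would change contact counts); non-water heteroatoms (ions,
  cryoprotectants) are dropped by default with `keepHetero = TRUE` to retain
  them as residue-kind nodes.
* Water names `WAT`, `DOD`, `H2O`, … are aliased to `HOH`; waters of *any*
  chain label are kept under the default chain-selection policy, because
  deposited files assign waters to chains inconsistently (`waters =
  "matching"` restricts them, and the choice is recorded in metadata).
* Affinity-tag residues are **not** removed at parse time; their exclusion
  is a reporting-level policy, so every statistic is computed on the full
  network.
* `max_degree` ties and all set outputs are ordered deterministically;
  identical inputs give bit-identical outputs, asserted for the TSV/SIF
  artifacts.

## Known limitations

* Contact edges are unweighted distance cutoffs — no hydrogen-bond
  geometry, no interaction energies, no Voronoi/contact-surface variants.
* Only the first model of multi-model (NMR) files is read; mmCIF is not
  supported.
* RCA recomputes all-pairs shortest paths per node removal (O(n·m·n) per
  network); fine up to a few thousand nodes, not tuned beyond that.
* The disconnection and normalization conventions above are one defensible
  choice; absolute Z values from tools with different conventions can
  differ by small amounts even though central-set membership is robust away
  from the cutoff.
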