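# hydroRIN

Water-inclusive residue interaction network (RIN) centrality analysis for
protein complexes.

Crystallographic water molecules are usually discarded when a protein
structure is abstracted into a residue interaction network, yet ordered
surface and interface waters form a hydrogen-bonded extension of the
protein's contact graph. hydroRIN builds RINs from PDB structures **with**
and **without** waters as nodes and quantifies what their inclusion changes
in residue-importance rankings. It is aimed at structural bioinformaticians
studying protein–protein interfaces, hotspot residues and water-mediated
interactions.

## The method

Nodes are residues and (optionally) water oxygens; edges are heavy-atom
contacts — residue–residue below 5 Å, water-involving below 3.5 Å, with a
uniform-3.5 Å control variant. Interface residues have any atom within 7 Å
of the partner chain; interface waters are RIN-adjacent to at least one of
them. Two centralities are computed per network and standardized to
Z-scores over all nodes (population SD); `Z ≥ 2` defines a central node:

* **RCA** — node-removal centrality: `raw_i = L(G − i) − L(G)`, where `L`
  is the average shortest path length over connected node pairs;
* **BCA** — shortest-path betweenness (unnormalized; the normalization
  cancels in Z-scoring).

The differential report compares wet vs dry: added/lost central nodes per
method, their union and intersection, the per-residue shift
`ΔZ = Z_wet − Z_dry` with `μ`/`σ` summaries, the water-node Z distribution,
and the *added-residue shift* `(mean ΔZ_added − μ(ΔZ))/σ(ΔZ)` that separates
genuinely promoted residues from the global normalization shift. Water
removal experiments (max-degree water, degree ≥ k, explicit conserved list)
test whether individual waters or only the water network as a whole matters.

A deterministic synthetic-complex generator (two compact chains, clustered
pseudo-atoms, a hydrogen-bond-spaced water shell) makes the entire pipeline
testable without structure downloads.

## Worked example

```r
library(hydroRIN)

s   <- generateComplex(synthParams(seed = 7))   # or s <- readPDB("complex.pdb")
s
#> Structure 'synthetic-complex-seed7': 60 residues, 120 waters, 300 atoms, chains: A, B

wet <- buildRIN(s, "wet", chainGroups = list("A", "B"))
dry <- buildRIN(s, "dry", chainGroups = list("A", "B"))
wet
#> RIN [wet] on 'synthetic-complex-seed7': 60 residue + 120 water nodes, 582 edges, 32 interface-flagged nodes

rep <- differentialReport(rca(wet), rca(dry), bca(wet), bca(dry))
rep <- interfaceReport(rep, annotateInterface(s, "A", "B"))
rep
#> Differential wet-vs-dry report ('synthetic-complex-seed7', Z >= 2)
#>   RCA: +7 / -2 central nodes; mean deltaZ = 1.246 (sd 1.021)
#>   BCA: +5 / -0 central nodes; mean deltaZ = 1.295 (sd 0.5635)
#>   union: 9, intersection: 3
#>   interface members of union: 5
```

Reading: adding the 120 waters as network nodes makes 7 further residues
central under RCA and 5 under BCA while losing almost none; residue
Z-scores shift up by ~1.25 on average (compensated by low water Z-scores,
which share the normalization population); 5 of the 9 newly central
residues sit at the 7 Å interface.

`runPipeline()` does all of the above from a file or structure and writes
SIF edge lists, node tables, per-method centrality TSVs and the JSON
differential report; `inst/scripts/rin-pipeline.R` wraps it for the shell:

```sh
Rscript inst/scripts/rin-pipeline.R --input complex.pdb --chains A,B --out results/
```

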