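# ddinet — dual clustering of drug-drug interaction networks

`ddinet` analyses drug-drug interaction (DDI) networks — undirected graphs
whose nodes are drugs and whose edges are recorded pairwise interactions —
with a *dual-clustering* methodology aimed at pharmacologists and network
scientists interested in drug repurposing. The premise: drugs that interact
with the same partners tend to share pharmacological properties, so
community structure in the interaction graph predicts properties that no
database lists yet.

Two independent clusterings are cross-referenced:

1. **Modularity classes.** Communities maximising the modularity

   *Q* = Σ<sub>C</sub> [ |E<sub>C</sub>|/|E| − (k<sub>C</sub>/k)² ],

   where |E<sub>C</sub>| is the number of edges inside cluster *C*,
   |E| the total edge count, k<sub>C</sub> the total degree of the
   cluster's nodes and k = 2|E| — found by greedy multilevel (Louvain)
   optimisation.

2. **Topological communities.** Point groups in an attraction-repulsion
   (a-r) energy-model layout, in which adjacent nodes attract with force
   ∝ d<sup>a</sup> and all node pairs repulse with force ∝ d<sup>r</sup>
   (a > r). Presets: Fruchterman-Reingold (a = 2, r = −1), LinLog
   (a = 0, r = −1) and a ForceAtlas2-style member (a = 1, r = −1 with
   degree-scaled repulsion). For a, r > −1 the layout minima separate the
   same clusters that modularity finds, which is precisely what makes the
   dual reading meaningful. Communities are extracted from the layout by
   density-based spatial clustering; drugs sitting between two communities
   are flagged as *border* drugs.

Each cluster is labeled with the pharmacological property shared by the
largest majority of its members (with a *consistency* percentage), and every
drug is then classified against two annotation tiers — tier 1 from the
primary database the network was built from, tier 2 from later
cross-checking sources:

* **confirmed** — the community label is among the drug's tier-1 properties;
* **explained** — the label appears only in tier 2;
* **not explained** — neither; these drugs, and the border drugs, seed
  *repurposing hypotheses* (drug, predicted property, evidence).

The package also provides five node centralities with top-k ranking tables,
global small-world statistics, the statistical network fidelity score
φ ∈ [0, 1] (mean relative agreement of two networks' metric vectors), a
planted-partition generator with two-tier annotations for fully reproducible
in-silico experiments, and an end-to-end pipeline driver.

## Worked example

```r
library(ddinet)

# a 9-community planted interaction network of 1141 drugs where 63% of
# drugs carry their community's property in tier 1 and 59.5% of the
# remainder in tier 2
bundle <- run_pipeline(list(seed = 1, synthetic = list()))
bundle$report
#> Community concordance report
#>  community_id mod_classes   n pct_confirmed pct_explained pct_not_explained
#>             1           1  80            63            26                11
#>             2           2 271            63            19                18
#>             3           3 307            59            23                17
#>             4           4  81            63            21                16
#>             5           5  53            66            17                17
#>             6           6 125            70            19                10
#>             7           7  58            66            22                12
#>             8           8  69            61            29                10
#>             9           9  96            59            26                15
#>            10           5   1           100             0                 0
#> totals: n = 1141 | confirmed 63% | explained 22% | not explained 15% (overall confirmed 85%)

head(bundle$hypotheses, 3)
#>        drug predicted_property           evidence
#> 1 drug_0002        property_01 not_explained_topo
#> 2 drug_0005        property_01 not_explained_topo
#> 3 drug_0008        property_01 not_explained_topo
```

The report's totals are drug-count-weighted means of the per-community
percentages (community 10 is one drug the density-based extraction flagged
as noise, kept as a singleton cluster): here the pipeline recovers the
designed 63 / 22 / 15 split
(and an overall confirmation rate of 85%) from the raw interaction graph
alone, demonstrating that the dual-clustering chain — modularity classes,
LinLog layout, spatial extraction, majority labeling — reconstructs the
planted property structure.

The same analysis, broken into inspectable stages that write their tables
under `results/`, lives in `analysis/01_simulate.R` …
`analysis/05_fidelity.R`.

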