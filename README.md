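# comorbnet

Comorbidity network inference from hospital discharge records.

`comorbnet` is for epidemiologists and systems-biology researchers who have
ICD-10-coded discharge records (one diagnosis per row) and want to go from
raw records to an interpretable map of multimorbidity: which diseases
co-occur more often than chance, how the resulting network is organised into
modules, and what shared molecular mechanism — shared genes and enriched
pathways — might underlie the strongest comorbid pairs. Because real
electronic health records are rarely shareable, the package also ships a
synthetic-cohort generator with planted ground truth, so the whole pipeline
can be exercised and validated end to end without any sensitive data.

## The model

**Edges.** For diseases *A* and *B* in a cohort of *N* discharge records,
with *n<sub>A</sub>*, *n<sub>B</sub>* records carrying each and *k* carrying
both, the co-occurrence evidence is the upper tail of the hypergeometric
distribution,

> p = P(X ≥ k),  X ~ Hypergeom(N, n<sub>A</sub>, n<sub>B</sub>),

one-sided (enrichment only). All co-occurring pairs of a cohort form one
Benjamini–Hochberg family and an undirected edge is drawn when the adjusted
value satisfies q &lt; α (default α = 0.05, strict). Age-stratified networks
(ten decade brackets, the last open-ended) repeat the same construction per
bracket, each with its own FDR family.

**Topology.** Each network is summarised by density 2E/(n(n−1)), average
degree 2E/n, Freeman degree centralization Σ<sub>i</sub>(k<sub>max</sub> −
k<sub>i</sub>)/((n−1)(n−2)), and mean local clustering.

**Modules.** Flow modules minimise the two-level map equation
L(M) = q<sup>↷</sup>H(Q) + Σ<sub>m</sub> p<sub>m</sub><sup>⟲</sup>H(P<sub>m</sub>)
over PageRank visit rates (damping 0.85, unrecorded teleportation), searched
by greedy single-node moves alternated with module merges under seeded
random restarts. Each module is labelled with its highest-PageRank disease.

**Mechanism.** Disease-gene annotations (a curated ClinVar-style table) give
each comorbid pair a shared-gene set and a Jaccard index
JI = |A∩B|/|A∪B|; shared-gene lists are tested for pathway
over-representation against a GMT collection with the same hypergeometric +
BH machinery.

## Worked example

```r
library(comorbnet)

sim <- simulate_comorbidity_study(sim_config(n_records = 2000), seed = 42)
net <- build_comorbidity_network(sim$records, alpha = 0.05)
net
#> <comorbidity_network> 60 nodes, 453 edges (FDR < 0.05, k >= 1; N = 2000 records, 1327 pairs tested)
glance(net)
#>   n_nodes n_edges density average_degree centralization avg_clustering
#> 1      60     453   0.256           15.1         0.0684          0.806
```

Of the 1,327 disease pairs that ever co-occur, 453 survive FDR control; the
planted three-module cohort yields a dense, weakly centralized, highly
clustered network. Module detection recovers the three planted clusters
exactly, labelled by their hub diseases:

```r
part <- detect_modules(net, seed = 1)
attr(part, "modules")
#>   module n_nodes  flow label exit_flow
#> 1      1      20 0.333 I00.X         0
#> 2      2      20 0.333 N00.X         0
#> 3      3      20 0.333 Q00.X         0
```

The most genetically similar comorbid pairs, and the pathway enrichment of
the top pair's shared genes:

```r
ov <- rank_pairs_by_jaccard(tidy(net), sim$annotations, top_n = 3)
ov[, c("code_a", "code_b", "n_shared", "n_union", "jaccard")]
#>   code_a code_b n_shared n_union jaccard
#> 1 Q12.X  Q14.X       108     155   0.697
#> 2 Q14.X  Q18.X       105     157   0.669
#> 3 Q07.X  Q14.X       106     159   0.667

enrich_pathways(ov$shared[[1]], sim$pathways)
#>   pathway              k     n     K     U        p        q significant
#> 1 MODULE_1_PATHWAY   106   108   150   724 2.58e-88 3.87e-87 TRUE
#> 2 RANDOM_SET_12       31   108   150   724 2.06e- 2 1.54e- 1 FALSE
#> ...
```

The 108 genes shared by the top pair hit their planted module pathway with
overwhelming significance while every distractor set stays null — exactly
the behaviour the generator plants. `run_comorbidity_pipeline()` chains all
of the above (plus age-stratified networks and a markdown report) in one
call; `autoplot()` methods draw the network, module flows and enrichment.

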