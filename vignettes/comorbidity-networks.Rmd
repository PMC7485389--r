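---
title: "Methods: comorbidity network inference, flow modules and shared-gene analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comorbidity network inference, flow modules and shared-gene analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

This vignette documents the statistical model behind `comorbnet`, the design
decisions taken where several defensible choices existed, the synthetic data
generator used for validation, and the package's numerical conventions and
limitations.

## Records and validation

The unit of analysis is the **discharge record** ("case"), not the unique
patient: repeat admissions count separately, matching how hospital
administrative databases report discharges. A record carries an age in whole
years, a sex used only for descriptive summaries (values outside
female/male are retained as `"unknown"` rather than dropped, because sex
never enters network inference), and a *set* of ICD-10 codes — duplicates
within a record collapse silently.

Two exclusion rules apply, tallied per reason so that
`n_input = n_retained + sum(tallies)` always holds: records with incomplete
information (missing identifier or unusable age), and records left with no
syntactically valid ICD-10 code. Code validation is purely syntactic
(letter + two digits, optional dot + one alphanumeric, `X` as placeholder);
the package deliberately does not ship an ICD-10 ontology, so a well-formed
but unassigned code passes. Records wider than the configured cap (default
6: a principal diagnosis plus up to five comorbidities, the shape of the
motivating source system) trigger a warning, not an exclusion — the cap
describes the upstream EHR convention, not a schema constraint.

Age stratification uses ten decade brackets `0-10`, `11-20`, …, `91-100`
with inclusive bounds and an open-ended final bracket (a 104-year-old is
"91 and over"). Brackets must partition the age axis; this is checked.

## Edge inference

For each unordered pair of diseases co-occurring in at least one record, the
one-sided hypergeometric tail $P(X \ge k)$ with
$X \sim \mathrm{Hypergeom}(N, n_A, n_B)$ tests whether the pair co-occurs
more often than chance. Three choices deserve comment:

* **One-sided, enrichment only.** Significant *avoidance* of co-occurrence
  is not a comorbidity and never draws an edge.
* **The FDR family is the set of co-occurring pairs of one network.** Pairs
  with $k = 0$ are excluded from the family: they can only contribute
  $p = 1$ entries, inflating $m$ and mechanically loosening the correction
  in a way that depends on how many never-co-occurring pairs one chooses to
  enumerate. With this convention $m$ is reproducible from the data alone.
  Each age bracket is adjusted independently — every bracket network is a
  standalone analysis.
* **Strict threshold** $q < \alpha$ (default $\alpha = 0.05$), so a pair
  with $q$ exactly equal to $\alpha$ is not an edge.

The minimum co-occurrence count `min_k` defaults to 1: the significance
test is the only filter. Nodes are edge-incident codes by default;
`include_isolates = TRUE` keeps prevalent-but-unconnected diseases, since
whether isolates belong in the node count is a reporting convention rather
than a modelling question. Edges carry $(k, p, q)$ as metadata but the graph
is treated as **unweighted** for topology and module detection.

Topology metrics are density $2E/(n(n-1))$, average degree $2E/n$, mean
local clustering (degree-<2 nodes contribute 0), and **Freeman degree
centralization** $\sum_i (k_{max} - k_i) / ((n-1)(n-2))$. Freeman's index
was chosen as the meaning of "network centralization" because it is the
standard graph-level degree centralization (1 for a star, 0 for any regular
graph) and is exactly recomputable from $(n, E, k_{max})$ alone — which is
what `topology_from_counts()` does for published summary tables. Degenerate
sizes ($n < 2$ for density, $n < 3$ for centralization) report `NA` rather
than raising.

## Flow modules

Visit rates come from PageRank with damping $d = 0.85$ and uniform
teleportation, computed by power iteration to an L1 tolerance of $10^{-12}$
(deterministic; isolated nodes teleport). The partition objective is the
two-level map equation

$$L(M) = q^{\curvearrowright} H(Q) + \sum_m p_m^{\circlearrowright} H(P_m),$$

with module exit/entry flow taken from edge-crossing walk flow only —
teleportation is *unrecorded*, so disconnected components correctly incur
no index cost and the one-module codelength equals the Shannon entropy of
the visit rates. Entropies are in bits; the decomposition
`codelength = index_term + sum(module_terms)` is exact to $10^{-9}$ bits and
is asserted in tests. Only the two-level form is implemented; hierarchical
(multi-level) decomposition is out of scope.

The search is greedy agglomeration: every node starts in its own module;
single-node moves to neighbouring modules (or to a fresh singleton) are
applied while they strictly decrease $L$; when no node move helps, the best
codelength-decreasing **merge of two connected modules** is applied and node
moves resume. The merge phase matters: single-node moves alone cannot fuse
two multi-node modules without passing through a worse intermediate state
(a ring is the classic failure). The whole procedure runs under
`n_restarts` shuffled sweep orders (default 10) from a user seed, and the
best restart wins, so results are deterministic given `(seed, n_restarts)`.
On a library of small benchmark graphs (up to 8 nodes) the search attains
the exhaustive-partition optimum — verified against a Bell-number
enumeration oracle — in at least 9 of 10 seeded runs, and it can never
return a partition worse than the one-module baseline. Module ids are
renumbered by decreasing flow; each module is labelled by its
highest-visit-rate member, exact ties going to the lexicographically
smallest code.

## Shared genes and pathways

Disease-gene annotations are an input contract (TSV of `icd10`, `gene`
rows), standing in for a manually curated ClinVar-to-ICD-10 mapping that is
not mechanically reproducible. Pair similarity is the Jaccard index
$JI = |A \cap B| / |A \cup B|$. Conventions: pairs with an unannotated
endpoint are excluded rather than scored 0 (their overlap is unobserved);
$JI(\varnothing, \varnothing)$ is reported as 0 with a warning; ranking ties
break by shared-gene count, then code order. Overlap pairs are drawn from
*significant comorbidity edges* (optionally within one module), not from all
code pairs — the analysis follows the comorbidity structure.

Over-representation analysis reuses the same hypergeometric and BH
primitives as edge inference (single implementation, shared tests). The
universe defaults to the union of the GMT collection's genes — a
conservative, self-contained choice when the reference set of an external
enrichment service is unknown — and can be overridden, e.g. with the
annotation table's full gene universe. List genes outside the universe are
dropped (with a message) before testing.

## The synthetic generator

`sim_config()` describes the validation conditions: 5,000 discharge
records, 60 diseases in 3 equal modules, 1–6 codes per record (mean 4), one
hub per module oversampled 3:1, an annotation probability of 0.4 (the
coverage level typical of curated clinical-variant extracts), 150-gene
module pools sampled at rate 0.8 plus sparse background noise, and one
pathway per module mirroring its pool among 12 random distractor sets.

Co-occurrence is induced by a latent module per record: each record draws a
module, an age from that module's bracket profile (the congenital-style
module concentrates in 0–10; the chronic modules in mid and late life —
emulating how congenital malformations dominate childhood cohorts while
ischemic and renal disease rise with age), and codes from the module's
diseases with odds boost 25 (a within-module draw probability of ≈0.93).
This mechanism was preferred over explicit pairwise copulas because it is
simple, gives one interpretable effect-size dial, and matches the intuition
that patients accumulate diseases from a physiopathological cluster. The
boost was fixed by a design calculation — at these sizes the expected
per-pair co-occurrence z-score is far above the BH threshold, so
planted-pair recovery is limited by sampling noise, not by the effect size —
and `within_boost = 1` reduces the generator to an exchangeable null in
which the FDR filter should retain (almost) nothing.

What the generator does **not** emulate: realistic ICD-10 ontology
structure, temporal ordering of diagnoses, sex-specific effect sizes,
overlapping or hierarchical modules, annotation noise (wrong genes rather
than missing genes), and the heavy-tailed prevalence distributions of real
EHRs. Passing recovery tests therefore demonstrates correctness of the
inference machinery under the planted model, not performance on real
hospital data.

## Validation problem sizes

The test suite checks the hypergeometric tail against exhaustive
draw-set enumeration for all counts with $N \le 12$; PageRank against a
dense linear solve on graphs up to 50 nodes (agreement within $10\times$
the iteration tolerance); map-equation search against exhaustive partition
enumeration up to 8 nodes; and the full pipeline on ten 5,000-record
simulated cohorts (edge recovery ≥ 95%, module ARI ≥ 0.9, within- above
between-module mean Jaccard, planted pathway ranked first) plus twenty null
cohorts for type-I control. These sizes keep the whole suite at a few
minutes on a single core while leaving each estimate's Monte Carlo error
well below the margins being asserted.

## Known limitations

* Syntactic-only ICD-10 validation; no ontology, no ICD-9 conversion, no
  free-text mapping.
* Undirected, cross-sectional co-occurrence: no temporal precedence, no
  relative-risk or phi-coefficient alternatives.
* Two-level map equation only; no hierarchical submodules.
* The greedy searcher is adequate at the scale of disease networks
  (hundreds to ~1,500 nodes) but is not the full Infomap core; very large
  graphs would want coarse-graining passes.
* Gene annotations and pathway collections are version-dependent inputs;
  analyses that depend on a specific ClinVar or KEGG snapshot are only as
  reproducible as those inputs.
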