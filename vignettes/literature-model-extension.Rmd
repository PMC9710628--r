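---
title: "Extending causal network models from literature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extending causal network models from literature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnetext)
```

## The problem

Discrete models of intracellular signaling — Boolean or multi-valued networks
over proteins, genes, chemicals and biological processes — are usually built
by hand from the literature. Machine-reading engines can extract very large
sets of candidate events (directed signed interactions with provenance: the
paper and the evidence sentence), but a model should not absorb them
wholesale. `litnetext` selects a coherent, well-supported group of events to
add to a baseline model, using only two signals: how often events occur and
co-occur in the literature, and how well a group of events connects back to
the model.

The pipeline assumes its input event table has already been filtered for
reading errors and classified into potential extensions; corroborating events
(identical to an existing model edge) are flagged in the run report but not
removed, since they are harmless to re-add and their co-occurrence links are
informative.

## The event collaboration graph and its scores

All scoring happens on the *extracted event set* (EES): the multiset of
event occurrences, with $N$ total occurrences over $M$ distinct events.
A distinct event is identified by the triple (regulator key, regulated key,
sign). Interaction subtype (phosphorylation vs. transcription vs. generic
activation) is deliberately **not** part of the identity: the extension
operates on the influence structure of the model, where only direction and
sign matter, and folding subtypes keeps occurrence counts consistent with
that graph view. For the same reason, "activity" and "amount" readings
collapse to their sign. Entity keys prefer the database accession (UniProt,
GO, HMDB, ...) and fall back to the case-folded, whitespace-collapsed name,
because surface names are unstable across readers; model elements use the
same rule so overlap statistics compare like with like.

The *event collaboration graph* (ECLG) has one node per distinct event and
an undirected edge between events co-occurring in at least one common paper.
Note the asymmetry between the two frequency notions: $f_i$ counts
*occurrences* (rows, so repeated sentences within one paper count), while
the pair count $f_{i,j}$ counts *distinct shared papers*. A paper that
states the same interaction five times strengthens the event individually
but not its co-occurrences.

Nodes are scored with the frequency class
$\mathrm{FC}^{IA}_i = \lfloor 0.5 - \log_2(f_i / f_{\max}) \rfloor$,
a corpus-linguistics device: class 0 for the most frequent event(s), +1 per
halving. At least one node always has class 0, and filtering (below) can
therefore never empty the graph on the class rule alone. Edges carry the
analogous pair class $\mathrm{FC}^{PA}_{i,j}$ (low = strong) and the
weighted inverse frequency
$\mathrm{IF}^{PA}_{i,j} = f_{i,j}\,(\ln(N/f_i) + \ln(N/f_j))$
(high = strong; the logarithmic inverse-frequency factor boosts rare but
repeatedly co-mentioned events, the same intuition as tf–idf).

### Filtering

`filter_eclg()` removes nodes with class above a threshold. The default
`"auto"` threshold is the unweighted mean class over all distinct events,
rounded half-up to an integer — the averaging population and the rounding
rule are our choices, made because thresholds are integers in practice and
half-up is the least surprising rule for a quantity that is a mean of small
non-negative integers. An optional neighbour rule additionally keeps only
class-0 nodes and their neighbours; it is **off by default** since it is an
extra selection criterion rather than part of the core flow. Pair metrics
are recomputed on the surviving graph (the pair maximum can change);
isolated survivors are retained by default because singleton clusters can
still qualify for extension through model support, and a `drop_isolated`
flag removes them for users who prefer a tidy candidate graph.

## Clustering

The candidate ECLG is partitioned by two-phase greedy weighted-modularity
maximization (Louvain). Modularity of a partition is
$$Q = \frac{1}{2m}\sum_{u,v}\Bigl[w_{u,v} - \frac{\sigma_u \sigma_v}{2m}\Bigr]\,\delta(c_u, c_v)$$
over ordered node pairs, and the first-phase move gain for a node $u$
joining community $c_v$ is the standard expression in the community's
internal weight $S_v$, incident weight $S_{v,tot}$, the node strength
$\sigma_u$ and the weight $\sigma_{u,v}$ from $u$ into the community. Both
are implemented directly (`modularity_q()`, `delta_q()`) and are
cross-checked in the test suite against brute-force recomputation and
against igraph's independent implementations.

Design choices that the algorithm's literature leaves open are pinned down
for reproducibility:

* **Edge weight.** Clustering defaults to $\mathrm{IF}^{PA}$. When the user
  clusters on $\mathrm{FC}^{PA}$ instead, the raw value would be backwards —
  modularity treats high weight as a strong tie while a low pair class means
  strong support — so the weight used is
  $\max(\mathrm{FC}^{PA}) - \mathrm{FC}^{PA} + 1$, and the run report says
  so. (Raw co-occurrence counts `f_ij` are also accepted.)
* **Determinism.** Louvain is order-sensitive, so the sweep order is the
  canonical sorted node order shuffled by a fixed seed
  (`node_order_seed`, default 1); among equal gains the lowest community
  label wins; a gain must exceed `tol = 1e-12` to count, preventing
  float-noise move loops. Fixed-seed runs are bit-identical.
* **Termination.** Phases repeat until an outer iteration moves no node;
  components are processed implicitly in parallel (no move can cross a
  component boundary) and labels are renumbered contiguously.

Each generated cluster is scored by the arithmetic means of its
intra-cluster edge metrics ($P_l$ edges); clusters with $P_l = 0$ have
undefined averages and are excluded from literature ranking rather than
given a sentinel value.

## Model support and selection

A generated cluster (nodes = events) is *interpreted* as a directed signed
entity graph (nodes = entities, edges = events). Its **node overlap** is the
percentage of its entities already in the baseline model. A **return path**
is a directed path whose edges all come from interpreted clusters and whose
endpoints are both model elements; interior nodes may be new. Edges are
followed strictly head-to-tail (regulator to regulated) — the directed
reading is the only one consistent with the influence-set semantics — and
paths may not reuse baseline-model edges: the definition is about what the
*clusters* contribute. The search is a depth-bounded DFS over simple paths
(default `max_path_len = 6` edges) because unbounded simple-path enumeration
is exponential; observed extension paths in practice are far shorter.

A cluster is selected if

* it has the **minimum** average $\mathrm{FC}^{PA}$ **and** the **maximum**
  average $\mathrm{IF}^{PA}$ over all generated clusters (the min/max are
  global, as the selection rule states them; ties all qualify), **or**
* its node overlap exceeds 50% (a strict inequality; the threshold is
  configurable) **and** it lies on at least one return path.

When a selected cluster shares a return path with others, the path partners
merge into one extension set (transitively), so the extension enters the
model as a connected piece. If exactly one cluster has defined averages it
trivially wins both literature criteria. When nothing qualifies, the result
carries a diagnostic naming the best cluster per criterion instead of
guessing. An optional *element-of-interest* mode first pairs clusters that
regulate and are regulated by a named entity and selects a pair when a
return path connects them.

`extend_model()` adds the merged events: new entities become elements whose
name takes an `_ext` suffix (identifiers carried over) and each regulation
is appended to the regulated element's positive or negative influence
expression joined by `,` (OR). The AND/OR structure of existing update
functions is preserved as text — the method extends structure, not logic —
and a `!`-negated regulator inside a positive expression stays where it is
textually on write. Extension never removes a baseline edge and is
idempotent.

## Evaluation

Against a gold-standard model, precision is the fraction of selected events
(entities) present in the gold model. Recall divides by the *recoverable*
gold items only: gold events that occur in the EES (direction and, by
default, sign must match) and are absent from the baseline — items the
method could possibly have found. The recoverability rule is stated for
events; we mirror it for entities, which can make entity recall undefined
(reported `NA`) when truncation removes edges but no entities. A
sign-agnostic matching mode exists because reader sign errors are common
and users may want the lenient count; the strict mode is the default.

## The synthetic generator

`generate_ees()` emulates the structural features of real reading output
that the method exploits: repeated events across papers (per-event counts
uniform on 1–5 by default, or Zipf), planted co-occurrence communities
(3 communities × 15 events × 5 papers by default — small enough that every
stage runs in seconds, large enough that communities are unambiguous), rare
cross-community leakage (`cross_paper_rate = 0.02`), and entity labels
partially reused from a supplied model (20%) so overlap and return paths are
exercised. `generate_model_pair()` builds a random gold model
(20 elements, each regulated by 1–3 predecessors) and truncates it by
removing a key set's regulators, the paths between element pairs, or random
edges. Injected (removed-gold) events are planted as one extra community
with at least two occurrences each, reflecting that events which made it
into a curated model tend to have multiple evidence statements.

What the generator does **not** emulate: reader mis-grounding and synonym
splits (all labels are exact), evidence-sentence noise, heavy-tailed corpus
sizes, and contradictory signs for the same pair. Passing the planted-
recovery and end-to-end tests therefore shows the machinery is correct and
deterministic, not that real corpora will yield 80%+ recall; on real data
the entity-canonicalization quality dominates.

## Degenerate inputs and numerical notes

Empty record sets build an empty EES (building an ECLG from it is an
error); an edgeless candidate graph clusters into singletons with a
warning; modularity on a weightless graph is an error rather than 0/0;
frequency classes reject counts outside $1 \le f \le f_{\max}$. Floor
operations on exact powers of two are safe because `log2` is exact on
dyadic rationals. Filtering that empties the graph (possible only through
`drop_isolated`) is an error, as is truncation that would empty a model.

Test problem sizes — formula oracles on 200 random event sets of up to 30
events, exhaustive partition search on 6–8 node fixtures, move-gain oracles
on up to 10 nodes, and the default synthetic fixture end to end — were
chosen so the whole suite runs in well under a minute while still covering
every formula and branch; the exhaustive searches stop at 8 nodes because
the number of partitions (4140) is the practical limit of from-scratch
enumeration in the tests.

## Limitations

* No semantic merging of near-duplicate entities beyond canonical keys; a
  synonym pair splits an event's support in two.
* Selection considers only the global best literature cluster; a corpus with
  two strong themes yields one literature winner (the other can still enter
  via model support).
* Update-function logic for new regulators is not inferred; new influences
  are appended as OR terms and need curation before simulation.
* The XLSX dialect is not read directly; export sheets to TSV/CSV first.
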