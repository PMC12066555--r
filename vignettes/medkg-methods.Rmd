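---
title: "Methods: quintuple knowledge graphs and their reasoning procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quintuple knowledge graphs and their reasoning procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medkg)
```

## The model

The atomic knowledge unit is the *quintuple*

$$q = (\mathrm{SUB}, \mathrm{SUBT}, R, \mathrm{OBJ}, \mathrm{OBJT}),$$

an ordered assertion that entity SUB of category SUBT stands in
relation $R$ to entity OBJ of category OBJT. The quintuple is
direction-asymmetric: $(a, \cdot, R, b, \cdot)$ and
$(b, \cdot, R, a, \cdot)$ are different assertions. Quintuple tables
are ingested into a weighted labeled property graph $G = (V, E, w)$
where

* node identity is the pair (name, category) — the same surface name
  may legitimately appear as, say, both a disease and an adverse
  reaction, and those are distinct nodes;
* one edge exists per distinct (subject node, relation, object node)
  triple, and its integer weight $w(e)$ counts the quintuple rows
  asserting it. Weight therefore measures *evidence frequency*: an
  assertion extracted from many guideline sentences outweighs a
  singleton.

Incidence is stored as doubly linked edge records: every node holds a
`first_edge` pointer and every edge holds previous/next pointers for
both of its endpoints (`sp`/`sn` on the start side, `ep`/`en` on the
end side). Walking the chain from `first_edge` enumerates a node's
incident edges in insertion order without scanning the edge table.
The linked layout is an in-memory structure; the test suite checks it
against a brute-force full-scan filter on every node of hundreds of
random graphs.

## The ontology layer

A schema bundles five components: medication types (MT), attribute
ontologies of medication types (AMT; the packaged worked example has
41 entries), a concept-term vocabulary (17 terms), a relation
vocabulary (17 relations) and 13 category-pair rules stating which
relations were observed linking which categories. Validation of a
quintuple checks its categories and relation against those
vocabularies; because the pair rules are samples rather than a closed
grammar, pair-rule findings are *warnings* by default and escalate to
violations only under `strict = TRUE`. Validation collects findings;
it never drops or rewrites data.

## Term normalization

Five standardization rule kinds are applied in a fixed order:
category unification, synonym unification, expression normalization,
reference filling (which may expand one term into several, e.g.
"Intravenous beta-blockers or verapamil" into its two filled-in
members) and redundancy simplification. Two auxiliary lexicons — a
drug pharmacopoeia and a disease codex — drive greedy left-to-right
longest-match segmentation (multiword clinical terms survive as
single tokens; Latin matches must sit on word boundaries; CJK text
falls back to single-character tokens) and alias merging, where alias
nodes are renamed onto their canonical terms and parallel edges
coalesce by weight addition. Merging conserves total edge weight; a
canonical name that exists only under a different category is skipped
and reported, never silently applied.

## The six reasoning procedures

All procedures are read-only and return auditable paths whose edges
exist verbatim in the source graph. Unbounded simple-path search is
exponential, so every traversal takes a `max_hops` bound
(default 6).

1. **Connectivity subgraph** — induced subgraph of all nodes within
   `max_hops` undirected hops of the seeds, optionally restricted to
   allowed categories. Substrate for everything else.
2. **Multi-use discovery** — all disease/symptom nodes reachable from
   a drug-like node, each with a shortest witnessing path; finds
   indications recorded two hops away on the drug's attribute
   ontology node.
3. **Synergy critical path** — BFS-layers the disease's neighborhood
   into a DAG (edges directed shallow → deep, intra-layer edges
   dropped) and computes the maximum-total-weight path to every
   drug-combination node by dynamic programming over a
   deterministically ordered edge list with strict improvement, so
   results are reproducible. The heaviest path is the best-evidenced
   combination therapy.
4. **MK-MST** — Kruskal's minimum spanning tree under edge cost
   $1/w(e)$, so the most frequently asserted relationships are
   retained. Ties are broken lexicographically on
   (cost, smaller endpoint name, larger endpoint name, label), which
   makes the tree independent of row order. Dosing nodes on the tree
   yield records keyed by their nearest disease/symptom ancestor on
   the tree path to the root; dose quantities are parsed from one
   documented pattern family (`number mg`, `number–number mg`,
   `number(–number) times daily`), with the raw strings always
   preserved.
5. **Symptom intersection** — nodes reachable from *every* query
   symptom through disease/symptom/drug/treatment nodes; shared
   drug or treatment nodes are the unified-treatment candidates for
   the comorbidity.
6. **Comorbidity shortest paths / staged retrieval** — minimum-hop
   paths for every unordered pair of selected nodes (the
   lexicographically smallest node sequence among minimum-hop paths,
   hence deterministic), and Kahn topological ordering of disease
   stages along `Stage` edges (lexicographic tie-break; a cycle is an
   error naming the nodes involved) with per-stage treatment
   attachments.

Edge weights can also be graded into quantile tiers:
$\mathrm{tier}(e) = \lceil k \cdot \hat F(w(e)) \rceil$ with
$\hat F$ the empirical CDF of the weights, so equal weights share a
tier and a heavier edge never ranks lower.

## The synthetic generator

`generate_synth_kg()` emits quintuple tables from a single integer
seed (the caller's RNG state is saved and restored, and identical
seed + config give byte-identical files). Five plantable patterns map
one-to-one onto the reasoning procedures: multi-use fans (a drug
linked to $k$ diseases at a chosen hop depth), synergy combinations
(weight boosts realized by duplicate emission, plus a weight-1
decoy), dosage trees, symptom intersections and stage chains.
Planted nodes live in their own namespace and background noise —
drawn uniformly over the schema's category-pair rules — touches only
the background entity pools, so planted patterns are recoverable by
construction: with zero noise recovery is exact (hard test
assertion), and with 200 background edges the planted synergy
combination stayed top-ranked in 100 of 100 seeds when tabulated
before the test threshold (≥ 95/100) was frozen.

**Scope and limits.** The generator produces structural test beds,
not clinically meaningful content; entity names are synthetic
(`drug_001`, …). Background edges never connect to planted nodes, so
it cannot be used to study robustness of the reasoning procedures to
adversarial noise on the patterns themselves — that is a deliberate
trade-off in favor of guaranteed ground truth.

## Numerical and determinism choices

* MST cost is $1/w$ with integer $w \ge 1$: no overflow or
  cancellation concerns; exact rational comparisons are unnecessary
  because ties on cost are resolved lexicographically anyway.
* All orderings (edge sort, BFS frontier, DP edge order, topological
  tie-breaks, serialization order) are lexicographic on names, so
  every result is a pure function of the graph's content, never of
  ingestion order or platform hash ordering.
* Problem sizes in the property suites: exhaustive oracles
  (spanning-tree enumeration, simple-path enumeration) run on graphs
  of ≤ 6–8 nodes where enumeration is cheap; cheap invariants
  (weight conservation, topological validity, linked-record
  equivalence) run on ~1000 random instances.

## Worked example

```{r example}
g <- bb_fixture_graph("mkmst")
res <- mk_mst(g, "propranolol")
res
res$records[["hypertension"]]$parsed
```

## Limitations

* The packaged fixtures transcribe a small published worked example
  (tens of nodes); the package has not been profiled against
  graphs of tens of thousands of entities, and the pure-R linked-list
  ingestion is expected to be the bottleneck there.
* Dose parsing recognizes one documented pattern family only;
  free-text dosing outside it is carried as raw strings.
* Segmentation is dictionary-driven; terms absent from both lexicons
  fall through to plain tokenization rather than statistical
  segmentation.
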