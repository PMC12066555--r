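# medkg

Build, validate and reason over clinical medication knowledge graphs
assembled from quintuple assertions.

## The problem

Clinical medication guidelines encode knowledge as sentences:
*"propranolol is indicated for hypertension; the initial dose is
10 mg"*. `medkg` represents each extracted sentence as a **quintuple**

```
(SUB, SUBT, R, OBJ, OBJT)
```

— subject, subject category, relation, object, object category — and
assembles quintuple tables into a weighted labeled property graph
*G = (V, E, w)*:

* node identity is the pair **(name, category)**, so "bradycardia"
  the symptom and "bradycardia" the adverse reaction are distinct
  nodes;
* re-asserting an existing (subject, relation, object) triple never
  duplicates the edge — it increments the edge's weight, so
  *w(e)* counts supporting sentences and measures evidence strength;
* incidence is stored as **doubly linked edge records** (a
  `first_edge` pointer per node; previous/next pointers on both sides
  of every edge), enumerating a node's incident edges in insertion
  order without a full scan.

On top of the graph sit an **ontology layer** (medication types,
their attribute ontologies, a concept-term and relation vocabulary,
category-pair rules; validation collects findings, it never drops
data), **term normalization** (five standardization rule kinds,
dictionary-assisted longest-match segmentation, alias merging that
conserves total edge weight) and **six reasoning procedures**:

1. connectivity subgraph around seed nodes;
2. multi-hop *multi-use discovery* — all diseases a drug can treat,
   with witnessing paths;
3. *synergy mining* — the maximum-total-weight path through the
   BFS-layered DAG to each drug-combination node (the weighted
   critical path);
4. *MK-MST* — minimum spanning tree under cost 1/*w*, from which
   dosing records, adverse reactions and contraindications are
   extracted per indication;
5. *symptom intersection* — what two symptoms have in common,
   including unified-treatment candidates;
6. comorbidity shortest paths and stage-ordered (topological)
   treatment retrieval.

Everything is deterministic: all tie-breaks are lexicographic, so
results never depend on row order or platform hash ordering. A
seeded synthetic generator plants exactly recoverable instances of
each pattern for testing, and exporters write graph JSON, GraphML and
idempotent (MERGE-only) openCypher scripts.

## Worked example

The package ships the small published beta-blocker worked example as
quintuple tables:

```r
library(medkg)

g <- bb_fixture_graph("all")
g
#> <property_graph> 40 nodes, 43 edges (total weight 48)

# one drug class, many uses (2 hops reaches indications recorded on
# the drug's attribute-ontology node)
res <- multi_use_discovery(g, "beta-blockers", max_hops = 2)
res[["hypertension"]][[1]]
#> <path_result> 2 hop(s), total weight 2
#>   beta-blockers -[Contraindications]-  hypertension and diabetes -[Contains]-  hypertension

# core dosing knowledge via the minimum spanning tree
m <- mk_mst(bb_fixture_graph("mkmst"), "propranolol")
m
#> <mk_mst_result> root 'propranolol': 9 nodes, 8 tree edges, total cost 7.5
#>   dosing records: hypertension, myocardial infarction
#>   adverse reactions: atrioventricular block, hypotension, sinus bradycardia
str(m$records[["hypertension"]]$parsed)
#> List of 3
#>  $ initial_dose_mg  : num 10
#>  $ max_dose_mg      : num 200
#>  $ frequency_per_day: num [1:2] 3 4

# best-evidenced combination therapy for congestive heart failure
s <- synergy_critical_path(bb_fixture_graph("synergy"),
                           "congestive heart failure")
s[[1]]$drugs
#> [1] "bisoprolol" "carvedilol" "felodipine" "metoprolol"

# what do atrial fibrillation and sinus bradycardia share?
symptom_intersection(bb_fixture_graph("cmis"),
                     c("atrial fibrillation", "sinus bradycardia"))
#> <intersection_result> symptoms: atrial fibrillation, sinus bradycardia
#>   shared nodes: bradycardia, cardiogenic syncope, frequent premature contractions, β-receptor blockers
#>   unified treatment: β-receptor blockers
```

A thin command-line interface wraps the same operations
(`inst/cli/medkg.R`; installed under `system.file("cli", "medkg.R",
package = "medkg")`):

```sh
Rscript inst/cli/medkg.R mst --fixture mkmst --root propranolol --format json
Rscript inst/cli/medkg.R simulate --seed 5 --background 50 --out sim.tsv
Rscript inst/cli/medkg.R export --fixture synergy --to cypher --out synergy.cypher
```

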