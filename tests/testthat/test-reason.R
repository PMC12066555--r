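test_that("connectivity subgraph respects hop bounds and category filters", {
  g <- bb_fixture_graph("multiuse")
  # max_hops = 0: the seed only, no edges
  s0 <- connectivity_subgraph(g, "beta-blockers", max_hops = 0)
  expect_identical(graph_nodes(s0)$name, "beta-blockers")
  expect_identical(nrow(graph_edges(s0)), 0L)
  # growing the bound never loses nodes
  n_prev <- 1L
  for (h in 1:4) {
    sh <- connectivity_subgraph(g, "beta-blockers", max_hops = h)
    expect_gte(nrow(graph_nodes(sh)), n_prev)
    n_prev <- nrow(graph_nodes(sh))
  }
  # category restriction blocks traversal through excluded nodes
  only_dis <- connectivity_subgraph(
    g, "beta-blockers", allowed_categories = "Diseases", max_hops = 2)
  expect_true(all(graph_nodes(only_dis)$category %in%
                    c("MT", "Diseases")))
  expect_error(connectivity_subgraph(g, "no such node"),
               class = "medkg_not_found_error")
})

test_that("connectivity subgraph matches igraph reachability (oracle)", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    q <- random_quintuples(n_nodes = 9, n_rows = 12, seed = 4000 + s)
    g <- ingest_quintuples(as_quintuples(q))
    nd <- graph_nodes(g)
    ig <- pg_to_igraph(g)
    seed_key <- paste(nd$name[1], nd$category[1], sep = "//")
    d <- igraph::distances(ig, v = seed_key, weights = NA)[1, ]
    for (h in c(1, 2, 4)) {
      sub <- connectivity_subgraph(g, nd$name[1], max_hops = h)
      got <- paste(graph_nodes(sub)$name, graph_nodes(sub)$category,
                   sep = "//")
      expect_setequal(got, names(d)[d <= h])
    }
  }
})

test_that("multi-use discovery finds the published indication set", {
  g <- bb_fixture_graph("multiuse")
  res <- multi_use_discovery(g, "beta-blockers", max_hops = 2)
  expect_setequal(names(res),
                  c("heart failure", "congestive heart failure",
                    "hereditary long QT", "hypertension"))
  # results come ordered by hop count, heaviest first within a level
  expect_identical(names(res)[1], "heart failure")
  expect_identical(res[["heart failure"]][[1]]$hops, 1L)
  expect_identical(res[["heart failure"]][[1]]$total_weight, 2L)
  expect_identical(res[["hypertension"]][[1]]$hops, 2L)
  # every witnessing path is made of real graph edges
  expect_paths_exist(lapply(res, `[[`, 1), g)
})

test_that("a two-hop indication needs max_hops = 2 (path enumeration)", {
  # 5-node fixture: drug -AT- amt -Indications- d1; drug -Indications- d2
  g <- ingest_quintuples(rbind(
    quintuple("drug", "Drugs", "AT", "amt", "AMT"),
    quintuple("amt", "AMT", "Indications", "d1", "Diseases"),
    quintuple("drug", "Drugs", "Indications", "d2", "Diseases"),
    quintuple("d2", "Diseases", "Causes", "s1", "Symptoms")
  ))
  expect_identical(names(multi_use_discovery(g, "drug", max_hops = 1)),
                   "d2")
  expect_setequal(names(multi_use_discovery(g, "drug", max_hops = 2)),
                  c("d1", "d2", "s1"))
  # oracle: the only simple paths drug->d1 are length 2 via amt
  expect_identical(
    multi_use_discovery(g, "drug", max_hops = 2)[["d1"]][[1]]$hops, 2L)
})

test_that("multi-use discovery guards its inputs", {
  g <- bb_fixture_graph("multiuse")
  expect_error(multi_use_discovery(g, "hypertension"),
               class = "medkg_category_error")
  expect_error(multi_use_discovery(g, "no such drug"),
               class = "medkg_not_found_error")
  # drug with no reachable disease: empty named list
  g2 <- ingest_quintuples(quintuple("lone", "Drugs", "AT", "a", "AMT"))
  expect_identical(length(multi_use_discovery(g2, "lone")), 0L)
})

test_that("synergy mining ranks the best-evidenced combination first", {
  g <- bb_fixture_graph("synergy")
  res <- synergy_critical_path(g, "congestive heart failure")
  expect_identical(res[[1]]$combination,
                   "metoprolol, bisoprolol, carvedilol and felodipine")
  expect_identical(res[[1]]$total_weight, 3)
  expect_setequal(res[[1]]$drugs,
                  c("bisoprolol", "carvedilol", "felodipine",
                    "metoprolol"))
  # the weight-1 decoy ranks strictly below
  decoy <- Filter(function(r)
    r$combination == "beta-blockers with digoxin", res)
  expect_identical(length(decoy), 1L)
  expect_lt(decoy[[1]]$total_weight, res[[1]]$total_weight)
  expect_paths_exist(lapply(res, `[[`, "path"), g)
})

test_that("synergy critical path matches exhaustive DAG enumeration", {
  skip_if_not_installed("igraph")
  check_critical_path_oracle(25)
})

test_that("a disease reaching no combination yields an empty result", {
  g <- ingest_quintuples(
    quintuple("d", "Diseases", "Treatment", "x", "Drugs"))
  expect_identical(synergy_critical_path(g, "d"), list())
})

test_that("mk_mst recovers the published propranolol dosing records", {
  g <- bb_fixture_graph("mkmst")
  res <- mk_mst(g, "propranolol")
  expect_identical(res$root, "propranolol")
  # a spanning tree of the component: |V| - 1 edges
  expect_identical(nrow(res$tree_edges), res$n_nodes - 1L)
  # the fixture has a cycle, so at least one edge is dropped
  expect_lt(nrow(res$tree_edges), nrow(graph_edges(g)))

  hyp <- res$records[["hypertension"]]
  expect_identical(hyp$parsed$initial_dose_mg, 10)
  expect_identical(hyp$parsed$max_dose_mg, 200)
  expect_identical(hyp$parsed$frequency_per_day, c(3, 4))
  mi <- res$records[["myocardial infarction"]]
  expect_identical(mi$parsed$dose_range_mg_range, c(30, 240))
  expect_identical(mi$parsed$frequency_per_day, c(2, 3))
  # raw attribute strings are preserved alongside the parse
  expect_identical(hyp$attributes$initial_dose, "10 mg")

  expect_setequal(res$adverse_reactions,
                  c("atrioventricular block", "hypotension",
                    "sinus bradycardia"))
})

test_that("mk_mst minimizes total 1/weight cost (exhaustive oracle)", {
  skip_if_not_installed("igraph")
  check_mst_oracle(25)
})

test_that("mk_mst agrees with igraph::mst on the packaged fixture", {
  skip_if_not_installed("igraph")
  g <- bb_fixture_graph("mkmst")
  res <- mk_mst(g, "propranolol")
  ig <- pg_to_igraph(g)
  comp <- igraph::components(ig)
  keep <- names(comp$membership)[
    comp$membership == comp$membership["propranolol//Drugs"]]
  sub <- igraph::induced_subgraph(ig, keep)
  mst <- igraph::mst(sub, weights = 1 / igraph::E(sub)$weight)
  expect_equal(res$total_cost,
               sum(1 / igraph::E(mst)$weight), tolerance = 1e-12)
})

test_that("mk_mst tie-breaking is deterministic across row orders", {
  q <- read_quintuple_table(medkg_extdata("bb_mkmst.tsv"))
  base <- mk_mst(ingest_quintuples(q), "propranolol")
  for (s in 1:5) {
    set.seed(s)
    res <- mk_mst(ingest_quintuples(q[sample(nrow(q)), ]),
                  "propranolol")
    expect_identical(res$total_cost, base$total_cost)
    key <- function(r) sort(paste(pmin(r$tree_edges$sub, r$tree_edges$obj),
                                  pmax(r$tree_edges$sub, r$tree_edges$obj),
                                  r$tree_edges$label))
    expect_identical(key(res), key(base))
  }
})

test_that("parse_dosage recognizes the documented pattern family", {
  expect_identical(parse_dosage("10 mg")$mg, 10)
  expect_identical(parse_dosage("30-240 mg")$mg_range, c(30, 240))
  expect_identical(parse_dosage("30–240 mg")$mg_range, c(30, 240))
  expect_identical(parse_dosage("3-4 times daily")$per_day, c(3, 4))
  expect_identical(parse_dosage("2 times daily")$per_day, 2)
  expect_identical(parse_dosage("12.5 mg")$mg, 12.5)
  # unmatched strings yield empty fields, never an error
  p <- parse_dosage("as directed by a physician")
  expect_null(p$mg); expect_null(p$mg_range); expect_null(p$per_day)
  expect_null(parse_dosage("")$mg)
})

test_that("symptom intersection surfaces the shared cause and treatment", {
  g <- bb_fixture_graph("cmis")
  res <- symptom_intersection(
    g, c("atrial fibrillation", "sinus bradycardia"))
  expect_true("bradycardia" %in% res$shared$name)
  expect_true("β-receptor blockers" %in% res$unified_treatment)
  # distances and link labels are reported per query symptom
  brady <- res$shared[res$shared$name == "bradycardia", ]
  expect_identical(brady$dist_1, 1L)
  expect_identical(brady$dist_2, 1L)
  expect_identical(length(brady$link_labels[[1]]), 2L)
  expect_error(symptom_intersection(g, "atrial fibrillation"),
               class = "medkg_argument_error")
})

test_that("symptoms in different components share nothing", {
  g <- ingest_quintuples(rbind(
    quintuple("s1", "Symptoms", "Shows", "a", "Diseases"),
    quintuple("s2", "Symptoms", "Shows", "b", "Diseases")
  ))
  res <- symptom_intersection(g, c("s1", "s2"))
  expect_identical(nrow(res$shared), 0L)
  expect_identical(length(res$unified_treatment), 0L)
})

test_that("shared nodes are the intersection of per-symptom reach (oracle)", {
  skip_if_not_installed("igraph")
  for (s in 1:15) {
    q <- random_quintuples(n_nodes = 9, n_rows = 14, seed = 5000 + s,
                           cats = c("Diseases", "Symptoms", "Drugs",
                                    "Treatment methods"))
    g <- ingest_quintuples(as_quintuples(q))
    nd <- graph_nodes(g)
    sy <- nd$name[nd$category == "Symptoms"]
    if (length(sy) < 2) next
    res <- symptom_intersection(g, sy[1:2], max_hops = 3)
    ig <- pg_to_igraph(g)
    keys <- paste(nd$name, nd$category, sep = "//")
    k1 <- keys[match(sy[1], nd$name)]
    k2 <- keys[match(sy[2], nd$name)]
    d <- igraph::distances(ig, v = c(k1, k2), weights = NA)
    want <- names(which(d[1, ] <= 3 & d[2, ] <= 3))
    want <- setdiff(want, c(k1, k2))
    got <- paste(res$shared$name, res$shared$category, sep = "//")
    expect_setequal(got, want)
  }
})

test_that("comorbidity paths are minimum-hop and deterministic", {
  g <- bb_fixture_graph("cmc")
  paths <- comorbidity_shortest_paths(g, label_filter = "Diseases")
  expect_gt(length(paths), 0)
  expect_identical(
    attr(paths, "n_pairs"),
    as.integer(choose(sum(graph_nodes(g)$category == "Diseases"), 2)))
  expect_paths_exist(paths, g)
  # rerunning returns the identical path set
  paths2 <- comorbidity_shortest_paths(g, label_filter = "Diseases")
  expect_identical(paths, paths2)
  expect_error(comorbidity_shortest_paths(g, names = character(0)),
               class = "medkg_argument_error")
})

test_that("comorbidity hop counts match igraph distances (oracle)", {
  skip_if_not_installed("igraph")
  check_shortest_path_oracle(20)
})

test_that("staged retrieval orders stages and attaches treatments", {
  g <- bb_fixture_graph("cmds")
  stages <- c("grade II hypertension", "grade III hypertension",
              "grade I hypertension")
  res <- staged_retrieval(g, stages)
  expect_identical(res$order,
                   c("grade I hypertension", "grade II hypertension",
                     "grade III hypertension"))
  for (st in res$order) {
    expect_gt(nrow(res$stages[[st]]), 0)
    expect_true(all(res$stages[[st]]$category %in%
                      c("Treatment methods", "Drugs", "Results")))
  }
})

test_that("a Stage cycle is rejected with the nodes named", {
  g <- ingest_quintuples(rbind(
    quintuple("s1", "Disease stages", "Stage", "s2", "Disease stages"),
    quintuple("s2", "Disease stages", "Stage", "s1", "Disease stages")
  ))
  err <- tryCatch(staged_retrieval(g, c("s1", "s2")), error = identity)
  expect_s3_class(err, "medkg_cycle_error")
  expect_match(conditionMessage(err), "s1")
  expect_match(conditionMessage(err), "s2")
})

test_that("topological order respects every Stage edge (property)", {
  check_topo_order_validity(40)
})

test_that("reasoning operations never mutate the graph", {
  g <- bb_fixture_graph("all")
  before <- graph_canonical(g)
  invisible(multi_use_discovery(g, "beta-blockers", max_hops = 2))
  invisible(synergy_critical_path(g, "congestive heart failure"))
  invisible(mk_mst(g, "propranolol"))
  invisible(symptom_intersection(
    g, c("atrial fibrillation", "sinus bradycardia")))
  invisible(comorbidity_shortest_paths(g, label_filter = "Diseases"))
  invisible(staged_retrieval(
    g, c("grade I hypertension", "grade II hypertension",
         "grade III hypertension")))
  expect_identical(graph_canonical(g), before)
})
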