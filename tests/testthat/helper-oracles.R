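# Independent generators and oracles used across the suite.
# Everything here is deliberately written without reference to the
# package internals (plain data-frame scans, recursion, igraph), so
# the implementation and its checks cannot share a bug.

ORACLE_CATS <- c("Drugs", "Diseases", "Symptoms", "AMT",
                 "Treatment methods")
ORACLE_RELS <- c("Indications", "Treatment", "Causes", "Description")

# random quintuple rows over a fixed node universe; duplicates allowed
random_quintuples <- function(n_nodes, n_rows, seed,
                              cats = ORACLE_CATS, rels = ORACLE_RELS) {
  set.seed(seed)
  names <- sprintf("n%02d", seq_len(n_nodes))
  cat_of <- sample(cats, n_nodes, replace = TRUE)
  i <- sample.int(n_nodes, n_rows, replace = TRUE)
  j <- sample.int(n_nodes, n_rows, replace = TRUE)
  bump <- i == j
  j[bump] <- (j[bump] %% n_nodes) + 1L
  data.frame(
    sub = names[i], sub_type = cat_of[i],
    rel = sample(rels, n_rows, replace = TRUE),
    obj = names[j], obj_type = cat_of[j],
    stringsAsFactors = FALSE
  )
}

# full-scan incident-edge oracle (vs the linked edge records)
brute_force_incident <- function(graph, name, category) {
  ed <- graph_edges(graph)
  hit <- (ed$sub == name & ed$sub_category == category) |
    (ed$obj == name & ed$obj_category == category)
  ed[hit, , drop = FALSE]
}

pg_to_igraph <- function(graph) {
  nd <- graph_nodes(graph)
  key <- paste(nd$name, nd$category, sep = "//")
  ed <- graph_edges(graph)
  igraph::graph_from_data_frame(
    data.frame(
      from = paste(ed$sub, ed$sub_category, sep = "//"),
      to = paste(ed$obj, ed$obj_category, sep = "//"),
      weight = ed$weight,
      stringsAsFactors = FALSE
    ),
    directed = FALSE,
    vertices = data.frame(name = key, stringsAsFactors = FALSE)
  )
}

# exhaustive spanning-tree enumeration: minimum total cost (1/weight)
# over all spanning trees of the component containing `root_key`
min_spanning_cost_enum <- function(graph, root_key) {
  ig <- pg_to_igraph(graph)
  comp <- igraph::components(ig)
  cid <- comp$membership[root_key]
  verts <- names(comp$membership)[comp$membership == cid]
  sub <- igraph::induced_subgraph(ig, verts)
  m <- igraph::ecount(sub)
  n <- igraph::vcount(sub)
  if (n == 1) return(0)
  ends <- igraph::ends(sub, igraph::E(sub), names = FALSE)
  cost <- 1 / igraph::E(sub)$weight
  best <- Inf
  for (idx in utils::combn(m, n - 1, simplify = FALSE)) {
    # n-1 edges form a spanning tree iff they connect all n vertices
    g2 <- igraph::make_empty_graph(n, directed = FALSE)
    g2 <- igraph::add_edges(g2, t(ends[idx, , drop = FALSE]))
    if (igraph::is_connected(g2)) {
      best <- min(best, sum(cost[idx]))
    }
  }
  best
}

# all simple paths between layers of a BFS-layered DAG, by recursion;
# returns the maximum total edge weight over paths seed -> target
max_dag_path_enum <- function(graph, seed_name, target_name,
                              max_hops = 6) {
  nd <- graph_nodes(graph)
  ed <- graph_edges(graph)
  key <- function(nm, ct) paste(nm, ct, sep = "//")
  ig <- pg_to_igraph(graph)
  seed_key <- igraph::V(ig)$name[grepl(paste0("^", seed_name, "//"),
                                       igraph::V(ig)$name)][1]
  d <- igraph::distances(ig, v = seed_key, weights = NA)[1, ]
  d[d > max_hops] <- Inf
  ek_sub <- key(ed$sub, ed$sub_category)
  ek_obj <- key(ed$obj, ed$obj_category)
  du <- d[ek_sub]; dv <- d[ek_obj]
  keep <- is.finite(du) & is.finite(dv) & abs(du - dv) == 1
  from <- ifelse(du[keep] < dv[keep], ek_sub[keep], ek_obj[keep])
  to <- ifelse(du[keep] < dv[keep], ek_obj[keep], ek_sub[keep])
  w <- ed$weight[keep]
  tkeys <- key(nd$name, nd$category)[nd$name == target_name]
  best <- -Inf
  recurse <- function(cur, total) {
    if (cur %in% tkeys && total > best) best <<- total
    out <- which(from == cur)
    for (k in out) recurse(to[k], total + w[k])
  }
  recurse(seed_key, 0)
  best
}

# union-find closure over alias pairs, for the merge oracle
union_find_closure <- function(pairs) {
  items <- unique(c(pairs$from, pairs$to))
  parent <- setNames(items, items)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(pairs))) {
    a <- find(pairs$from[i]); b <- find(pairs$to[i])
    if (a != b) parent[[a]] <- b
  }
  setNames(vapply(items, find, character(1)), items)
}

expect_paths_exist <- function(paths, graph) {
  ed <- graph_edges(graph)
  for (p in paths) {
    if (!nrow(p$edges)) next
    for (i in seq_len(nrow(p$edges))) {
      hit <- ed$label == p$edges$label[i] &
        ed$weight == p$edges$weight[i] &
        ((ed$sub == p$edges$sub[i] & ed$obj == p$edges$obj[i]))
      expect_true(any(hit),
                  info = paste("edge missing from source graph:",
                               p$edges$sub[i], p$edges$label[i],
                               p$edges$obj[i]))
    }
  }
}

# shared property drivers (parameterised instance counts so the
# module tests and the acceptance suite can run them at different
# sizes)

check_linked_scan_equivalence <- function(n_instances, seed0 = 100) {
  for (s in seq_len(n_instances)) {
    q <- random_quintuples(n_nodes = 8, n_rows = 14, seed = seed0 + s)
    g <- ingest_quintuples(as_quintuples(q))
    nd <- graph_nodes(g)
    for (i in seq_len(nrow(nd))) {
      got <- linked_edge_scan(g, nd$name[i], nd$category[i])
      want <- brute_force_incident(g, nd$name[i], nd$category[i])
      expect_setequal(got$edge_id, want$edge_id)
    }
  }
}

check_weight_conservation <- function(n_instances, seed0 = 200) {
  for (s in seq_len(n_instances)) {
    q <- random_quintuples(n_nodes = 7, n_rows = 20, seed = seed0 + s)
    g <- ingest_quintuples(as_quintuples(q))
    triples <- unique(paste(q$sub, q$sub_type, q$rel, q$obj,
                            q$obj_type))
    expect_identical(nrow(g$edges), length(triples))
    expect_identical(sum(graph_edges(g)$weight), nrow(q))
  }
}

check_shortest_path_oracle <- function(n_instances, seed0 = 300) {
  for (s in seq_len(n_instances)) {
    q <- random_quintuples(n_nodes = 8, n_rows = 10, seed = seed0 + s)
    g <- ingest_quintuples(as_quintuples(q))
    nd <- graph_nodes(g)
    ig <- pg_to_igraph(g)
    dmat <- igraph::distances(ig, weights = NA)
    key <- paste(nd$name, nd$category, sep = "//")
    paths <- comorbidity_shortest_paths(g, names = unique(nd$name),
                                        max_hops = 10)
    for (p in paths) {
      a <- paste(p$nodes$name[1], p$nodes$category[1], sep = "//")
      b <- paste(p$nodes$name[nrow(p$nodes)],
                 p$nodes$category[nrow(p$nodes)], sep = "//")
      expect_equal(p$hops, unname(dmat[a, b]))
    }
    # unreachable pairs omitted: reported counts line up
    finite_pairs <- sum(is.finite(dmat[key, key]) &
                          upper.tri(dmat[key, key]))
    expect_equal(attr(paths, "n_pairs") - attr(paths, "n_unreachable"),
                 finite_pairs)
  }
}

check_mst_oracle <- function(n_instances, seed0 = 400) {
  for (s in seq_len(n_instances)) {
    q <- random_quintuples(n_nodes = 6, n_rows = 9, seed = seed0 + s)
    g <- ingest_quintuples(as_quintuples(q))
    nd <- graph_nodes(g)
    root <- nd$name[1]
    res <- mk_mst(g, root, root_category = nd$category[1])
    expect_identical(nrow(res$tree_edges), res$n_nodes - 1L)
    want <- min_spanning_cost_enum(
      g, paste(nd$name[1], nd$category[1], sep = "//"))
    expect_equal(res$total_cost, want, tolerance = 1e-12)
  }
}

check_critical_path_oracle <- function(n_instances, seed0 = 500) {
  for (s in seq_len(n_instances)) {
    set.seed(seed0 + s)
    n_combo <- 2L
    q <- random_quintuples(n_nodes = 6, n_rows = 8, seed = seed0 + s)
    # append combination nodes reachable from the disease pool
    extra <- data.frame(
      sub = sample(unique(q$sub), n_combo, replace = TRUE),
      sub_type = NA_character_,
      rel = "Combination medication",
      obj = sprintf("combo%d", seq_len(n_combo)),
      obj_type = "Drug combinations",
      stringsAsFactors = FALSE
    )
    extra$sub_type <- q$sub_type[match(extra$sub, q$sub)]
    q <- rbind(q, extra)
    g <- ingest_quintuples(as_quintuples(q))
    nd <- graph_nodes(g)
    dis <- nd$name[nd$category == "Diseases"]
    if (!length(dis)) next
    res <- synergy_critical_path(g, dis[1], max_hops = 6)
    for (r in res) {
      want <- max_dag_path_enum(g, dis[1], r$combination, max_hops = 6)
      expect_equal(r$total_weight, want)
    }
  }
}

check_topo_order_validity <- function(n_instances, seed0 = 600) {
  for (s in seq_len(n_instances)) {
    set.seed(seed0 + s)
    n_stage <- sample(3:6, 1)
    stages <- sprintf("stage%02d", seq_len(n_stage))
    # random DAG: edges only from lower to higher index, then shuffle
    pairs <- utils::combn(n_stage, 2)
    keep <- sample(ncol(pairs), max(1, rbinom(1, ncol(pairs), 0.4)))
    q <- data.frame(
      sub = stages[pairs[1, keep]], sub_type = "Disease stages",
      rel = "Stage", obj = stages[pairs[2, keep]],
      obj_type = "Disease stages", stringsAsFactors = FALSE
    )
    q <- q[sample(nrow(q)), , drop = FALSE]
    g <- ingest_quintuples(as_quintuples(q))
    present <- intersect(stages, graph_nodes(g)$name)
    res <- staged_retrieval(g, present)
    pos <- match(present, res$order)
    expect_false(anyNA(pos))
    for (i in seq_len(nrow(q))) {
      a <- match(q$sub[i], res$order)
      b <- match(q$obj[i], res$order)
      if (!is.na(a) && !is.na(b)) expect_lt(a, b)
    }
  }
}

check_merge_weight_conservation <- function(n_instances, seed0 = 700) {
  for (s in seq_len(n_instances)) {
    q <- random_quintuples(n_nodes = 8, n_rows = 15, seed = seed0 + s)
    g <- ingest_quintuples(as_quintuples(q))
    # alias half the node names onto the other half (same category
    # guaranteed by renaming within the graph's own categories)
    nd <- graph_nodes(g)
    by_cat <- split(nd$name, nd$category)
    aliases <- character(0)
    for (grp in by_cat) {
      if (length(grp) >= 2) {
        aliases[grp[1]] <- grp[2]
      }
    }
    if (!length(aliases)) next
    lx <- lexicon(terms = setdiff(nd$name, names(aliases)),
                  aliases = aliases, name = "t")
    merged <- merge_aliases(g, list(lx))
    expect_identical(sum(graph_edges(merged)$weight),
                     sum(graph_edges(g)$weight))
  }
}

check_planted_recovery <- function(seed) {
  cfg <- synth_config(
    seed,
    n_background_edges = 0,
    planted = list(
      plant_multi_use(n_diseases = 4, depth = 2),
      plant_synergy(n_drugs = 3, weight_boost = 5),
      plant_dosage_tree(attributes = list(initial_dose = "25 mg",
                                          max_dose = "100 mg")),
      plant_intersection(),
      plant_stage_chain(length = 3, n_treatments = 2)
    )
  )
  out <- generate_synth_kg(cfg)
  g <- ingest_quintuples(out$quintuples)
  tr <- out$truth

  mu <- tr$multi_use[[1]]
  got <- multi_use_discovery(g, mu$drug, max_hops = mu$depth)
  expect_setequal(names(got), mu$diseases)

  sy <- tr$synergy[[1]]
  res <- synergy_critical_path(g, sy$disease, max_hops = 3)
  expect_identical(res[[1]]$combination, sy$combination)
  expect_true(all(sy$drugs %in% res[[1]]$drugs))

  dt <- tr$dosage_tree[[1]]
  mst <- mk_mst(g, dt$drug)
  expect_true(dt$indication %in% names(mst$records))
  expect_identical(mst$records[[dt$indication]]$attributes,
                   dt$attributes)

  it <- tr$intersection[[1]]
  ir <- symptom_intersection(g, it$symptoms, max_hops = 2)
  expect_true(it$shared %in% ir$shared$name)
  expect_true(it$unified %in% ir$unified_treatment)

  sc <- tr$stage_chain[[1]]
  sr <- staged_retrieval(g, sc$stages)
  expect_identical(sr$order, sc$stages)
  for (st in sc$stages) {
    expect_setequal(sr$stages[[st]]$name, sc$treatments[[st]])
  }
}
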