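# Graph-reasoning procedures over a medication property graph.
#
# All six operations are read-only and return auditable structures:
# every reported path/tree edge exists in the source graph with its
# stored label, direction and weight. Unbounded pattern search is
# capped by a configurable `max_hops` (default 6), since unbounded
# simple-path search is exponential. Category names are matched
# case-insensitively, so the lowercase category names used in query
# languages ("diseases", "drugs") reach the canonical schema
# categories.

DRUG_LIKE <- c("drugs", "drug", "mt", "medication type")
DISEASE_LIKE <- c("diseases", "disease", "symptoms", "symptom")
COMBO_LIKE <- c("drug combinations", "drug combination")
CMIS_CATEGORIES <- c("diseases", "symptoms", "drugs", "treatment methods")
TREATMENT_LIKE <- c("drugs", "treatment methods", "mt")

# incident edge ids per node (start or end side)
pg_incident <- function(graph) {
  n <- nrow(graph$nodes)
  inc <- vector("list", n)
  e <- graph$edges
  for (eid in seq_len(nrow(e))) {
    s <- e$start_node[eid]; t <- e$end_node[eid]
    inc[[s]] <- c(inc[[s]], eid)
    if (t != s) inc[[t]] <- c(inc[[t]], eid)
  }
  inc
}

# undirected BFS distances from seed ids; non-seed nodes are entered
# only when their category is allowed (when a restriction is given)
pg_bfs <- function(graph, seeds, max_hops = Inf, allowed = NULL,
                   inc = NULL) {
  if (is.null(inc)) inc <- pg_incident(graph)
  n <- nrow(graph$nodes)
  cats <- canon(graph$nodes$category)
  dist <- rep(NA_integer_, n)
  dist[seeds] <- 0L
  frontier <- seeds
  d <- 0L
  e <- graph$edges
  while (length(frontier) && d < max_hops) {
    d <- d + 1L
    nxt <- integer(0)
    for (u in frontier) {
      for (eid in inc[[u]]) {
        v <- if (e$start_node[eid] == u) e$end_node[eid]
             else e$start_node[eid]
        if (!is.na(dist[v])) next
        if (!is.null(allowed) && !(cats[v] %in% allowed)) next
        dist[v] <- d
        nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
  }
  dist
}

# deterministic minimum-hop path between two ids: greedy walk from
# `from` along decreasing distance-to-`to`, smallest node name first
pg_shortest_path <- function(graph, from, to, max_hops = Inf,
                             allowed = NULL, inc = NULL) {
  if (is.null(inc)) inc <- pg_incident(graph)
  dist <- pg_bfs(graph, to, max_hops, allowed, inc)
  if (is.na(dist[from])) return(NULL)
  e <- graph$edges
  path <- from
  cur <- from
  while (cur != to) {
    cand <- integer(0)
    for (eid in inc[[cur]]) {
      v <- if (e$start_node[eid] == cur) e$end_node[eid]
           else e$start_node[eid]
      if (!is.na(dist[v]) && dist[v] == dist[cur] - 1L) {
        cand <- c(cand, v)
      }
    }
    cand <- unique(cand)
    cur <- cand[order(graph$nodes$name[cand],
                      graph$nodes$category[cand])][1]
    path <- c(path, cur)
  }
  path
}

# connecting edge between two adjacent ids: heaviest, then by label
pg_connecting_edge <- function(graph, u, v) {
  e <- graph$edges
  hit <- which((e$start_node == u & e$end_node == v) |
                 (e$start_node == v & e$end_node == u))
  hit[order(-e$weight[hit], e$label[hit])][1]
}

# assemble a path result from a node-id sequence
path_result <- function(graph, ids) {
  e <- graph$edges
  eids <- integer(0)
  if (length(ids) > 1) {
    eids <- vapply(seq_len(length(ids) - 1L), function(i) {
      pg_connecting_edge(graph, ids[i], ids[i + 1L])
    }, integer(1))
  }
  structure(
    list(
      nodes = data.frame(
        name = graph$nodes$name[ids],
        category = graph$nodes$category[ids],
        stringsAsFactors = FALSE
      ),
      edges = data.frame(
        label = e$label[eids],
        weight = e$weight[eids],
        sub = graph$nodes$name[e$start_node[eids]],
        obj = graph$nodes$name[e$end_node[eids]],
        direction = ifelse(e$start_node[eids] == ids[-length(ids)],
                           "forward", "reverse"),
        stringsAsFactors = FALSE
      ),
      hops = length(ids) - 1L,
      total_weight = sum(e$weight[eids])
    ),
    class = "path_result"
  )
}

#' @export
print.path_result <- function(x, ...) {
  cat("<path_result> ", x$hops, " hop(s), total weight ",
      x$total_weight, "\n  ", sep = "")
  if (nrow(x$nodes) == 1) {
    cat(x$nodes$name, "\n")
  } else {
    cat(paste0(x$nodes$name[-nrow(x$nodes)], " -[",
               x$edges$label, "]- "), collapse = "")
    cat(x$nodes$name[nrow(x$nodes)], "\n")
  }
  invisible(x)
}

#' Connectivity subgraph around seed nodes
#'
#' Induced subgraph of every node reachable from any seed within
#' `max_hops` undirected hops. When `allowed_categories` is given,
#' traversal only enters nodes of those categories (seeds are always
#' included). This is the substrate all other reasoning operations
#' work on.
#'
#' @param graph A `property_graph`.
#' @param seeds Character vector of node names (any category).
#' @param allowed_categories Optional character vector of categories.
#' @param max_hops Hop bound (>= 0); 0 returns the seeds only, with no
#'   edges.
#' @return A `property_graph` (node weights and attributes preserved).
#' @export
connectivity_subgraph <- function(graph, seeds,
                                  allowed_categories = NULL,
                                  max_hops = 6) {
  stopifnot(inherits(graph, "property_graph"), max_hops >= 0)
  seed_ids <- unlist(lapply(seeds, function(s) {
    ids <- find_nodes_by_name(graph, s)
    if (!length(ids)) stop_medkg("not_found", "no node named '", s, "'")
    ids
  }))
  allowed <- if (is.null(allowed_categories)) NULL
             else canon(allowed_categories)
  dist <- pg_bfs(graph, seed_ids, max_hops, allowed)
  keep <- which(!is.na(dist))
  e <- graph$edges
  keep_e <- if (max_hops == 0) integer(0) else {
    which(e$start_node %in% keep & e$end_node %in% keep)
  }
  remap <- match(seq_len(nrow(graph$nodes)), keep)
  pg_build(
    graph$nodes[keep, , drop = FALSE],
    graph$node_attrs[keep],
    data.frame(
      start_node = remap[e$start_node[keep_e]],
      end_node = remap[e$end_node[keep_e]],
      label = e$label[keep_e],
      label_category = e$label_category[keep_e],
      weight = e$weight[keep_e],
      stringsAsFactors = FALSE
    )
  )
}

#' Multi-hop discovery of one drug's multiple uses
#'
#' Finds every disease or symptom node reachable from a drug-like node
#' within `max_hops` undirected hops, each with a shortest witnessing
#' simple path through the graph (so an indication recorded on the
#' drug's attribute ontology node, two hops away, is still found).
#' Results are ordered by hop count, then descending path weight, then
#' name.
#'
#' @param graph A `property_graph`.
#' @param drug Name of a node of drug-like category (a drug or a
#'   medication type).
#' @param max_hops Hop bound.
#' @return Named list (disease/symptom name -> list of `path_result`),
#'   empty when nothing is reachable.
#' @examples
#' g <- bb_fixture_graph("multiuse")
#' names(multi_use_discovery(g, "beta-blockers", max_hops = 2))
#' @export
multi_use_discovery <- function(graph, drug, max_hops = 6) {
  stopifnot(inherits(graph, "property_graph"))
  ids <- find_nodes_by_name(graph, drug)
  if (!length(ids)) stop_medkg("not_found", "no node named '", drug, "'")
  ids <- ids[canon(graph$nodes$category[ids]) %in% DRUG_LIKE]
  if (!length(ids)) {
    stop_medkg("category", "'", drug, "' is not a drug-like node")
  }
  inc <- pg_incident(graph)
  dist <- pg_bfs(graph, ids, max_hops, inc = inc)
  targets <- which(!is.na(dist) & dist > 0 &
                     canon(graph$nodes$category) %in% DISEASE_LIKE)
  if (!length(targets)) return(setNames(list(), character(0)))
  paths <- lapply(targets, function(t) {
    path_result(graph, pg_shortest_path(graph, ids[1], t,
                                        max_hops, inc = inc))
  })
  hops <- vapply(paths, `[[`, numeric(1), "hops")
  wts <- vapply(paths, `[[`, numeric(1), "total_weight")
  o <- order(hops, -wts, graph$nodes$name[targets])
  setNames(lapply(paths[o], list), graph$nodes$name[targets][o])
}

#' Weighted critical-path mining of synergistic drug combinations
#'
#' Layers the disease's connectivity subgraph by BFS depth from the
#' disease into a DAG (edges directed from shallower to deeper layer;
#' intra-layer edges dropped), then, for every drug-combination node
#' reachable, returns the maximum-total-weight path through that DAG —
#' the weighted critical path. High edge weights mark strongly
#' supported relationships, so the critical path surfaces the best-
#' evidenced combination therapy. Results are ranked by total weight
#' (descending), ties by combination name.
#'
#' @param graph A `property_graph`.
#' @param disease Disease node name.
#' @param max_hops BFS depth bound for the layering.
#' @return List of results, each with `combination` (node name),
#'   `drugs` (drug names on the path plus the combination's member
#'   drugs), `path` (a `path_result`) and `total_weight`. Empty list
#'   when the disease reaches no combination node.
#' @examples
#' g <- bb_fixture_graph("synergy")
#' res <- synergy_critical_path(g, "congestive heart failure")
#' res[[1]]$drugs
#' @export
synergy_critical_path <- function(graph, disease, max_hops = 6) {
  stopifnot(inherits(graph, "property_graph"))
  seed <- find_nodes_by_name(graph, disease)
  if (!length(seed)) {
    stop_medkg("not_found", "no node named '", disease, "'")
  }
  dis <- seed[canon(graph$nodes$category[seed]) %in%
                c("diseases", "disease")]
  seed <- if (length(dis)) dis[1] else seed[1]

  inc <- pg_incident(graph)
  depth <- pg_bfs(graph, seed, max_hops, inc = inc)
  e <- graph$edges
  # DAG edges: consecutive layers only, directed shallow -> deep
  du <- depth[e$start_node]; dv <- depth[e$end_node]
  keep <- which(!is.na(du) & !is.na(dv) & abs(du - dv) == 1L)
  dag_from <- ifelse(du[keep] < dv[keep], e$start_node[keep],
                     e$end_node[keep])
  dag_to <- ifelse(du[keep] < dv[keep], e$end_node[keep],
                   e$start_node[keep])
  dag_w <- e$weight[keep]

  n <- nrow(graph$nodes)
  best <- rep(-Inf, n); best[seed] <- 0
  pred <- rep(NA_integer_, n)
  if (length(keep)) {
    o <- order(depth[dag_from], graph$nodes$name[dag_from],
               graph$nodes$name[dag_to])
    for (i in o) {
      u <- dag_from[i]; v <- dag_to[i]
      cand <- best[u] + dag_w[i]
      if (cand > best[v]) {
        best[v] <- cand
        pred[v] <- u
      }
    }
  }

  combos <- which(canon(graph$nodes$category) %in% COMBO_LIKE &
                    is.finite(best) & seq_len(n) != seed)
  if (!length(combos)) return(list())
  results <- lapply(combos, function(cn) {
    ids <- cn
    while (!is.na(pred[ids[1]])) ids <- c(pred[ids[1]], ids)
    pr <- path_result(graph, ids)
    members <- unique(unlist(lapply(inc[[cn]], function(eid) {
      v <- if (e$start_node[eid] == cn) e$end_node[eid]
           else e$start_node[eid]
      if (canon(graph$nodes$category[v]) %in% c("drugs", "drug")) {
        graph$nodes$name[v]
      } else {
        character(0)
      }
    })))
    on_path <- pr$nodes$name[canon(pr$nodes$category) %in%
                               c("drugs", "drug")]
    list(
      combination = graph$nodes$name[cn],
      drugs = sort(unique(c(members, on_path))),
      path = pr,
      total_weight = best[cn]
    )
  })
  wts <- vapply(results, `[[`, numeric(1), "total_weight")
  nms <- vapply(results, `[[`, character(1), "combination")
  results[order(-wts, nms)]
}

# union-find for Kruskal
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, x) {
  while (uf[x] != x) x <- uf[x]
  x
}

#' Medication-knowledge minimum spanning tree
#'
#' Computes a minimum spanning tree of the root's connected component
#' under edge cost `1/weight`, so the highest-frequency (best
#' supported) relationships are retained, with deterministic
#' lexicographic tie-breaking. From the tree it extracts the core
#' medication knowledge: for every tree node of category
#' Drug applications it emits a dosing record keyed by the nearest
#' disease/symptom ancestor on the tree path to the root (the
#' indication), with the node's raw attribute strings and their parsed
#' dose quantities (see [parse_dosage()]); tree nodes of category
#' Adverse reactions, Contraindications and Indications are collected
#' by name.
#'
#' @param graph A `property_graph`.
#' @param root Root node name (typically a drug).
#' @param root_category Optional category qualifier.
#' @return An object of class `mk_mst_result`: list with `root`,
#'   `tree_edges` (data frame), `records` (named by indication; each
#'   has `node`, `attributes`, `parsed`), `adverse_reactions`,
#'   `contraindications`, `indications`, `total_cost`, `n_nodes`.
#' @examples
#' g <- bb_fixture_graph("mkmst")
#' res <- mk_mst(g, "propranolol")
#' res$records[["hypertension"]]$parsed$initial_dose_mg
#' @export
mk_mst <- function(graph, root, root_category = NULL) {
  stopifnot(inherits(graph, "property_graph"))
  rid <- if (is.null(root_category)) {
    ids <- find_nodes_by_name(graph, root)
    if (!length(ids)) stop_medkg("not_found", "no node named '", root, "'")
    pref <- ids[canon(graph$nodes$category[ids]) %in% DRUG_LIKE]
    if (length(pref)) pref[1] else ids[1]
  } else {
    find_node(graph, root, root_category)
  }

  inc <- pg_incident(graph)
  dist <- pg_bfs(graph, rid, Inf, inc = inc)
  comp <- which(!is.na(dist))
  e <- graph$edges
  in_comp <- e$start_node %in% comp & e$end_node %in% comp
  eids <- which(in_comp)

  nm <- graph$nodes$name
  lo <- pmin(nm[e$start_node[eids]], nm[e$end_node[eids]])
  hi <- pmax(nm[e$start_node[eids]], nm[e$end_node[eids]])
  cost <- 1 / e$weight[eids]
  o <- eids[order(cost, lo, hi, e$label[eids])]

  uf <- uf_new(nrow(graph$nodes))
  tree <- integer(0)
  for (eid in o) {
    a <- uf_find(uf, e$start_node[eid])
    b <- uf_find(uf, e$end_node[eid])
    if (a != b) {
      uf[a] <- b
      tree <- c(tree, eid)
      if (length(tree) == length(comp) - 1L) break
    }
  }

  # parent map by DFS from the root through tree edges
  adj <- lapply(seq_len(nrow(graph$nodes)), function(i) integer(0))
  for (eid in tree) {
    s <- e$start_node[eid]; t <- e$end_node[eid]
    adj[[s]] <- c(adj[[s]], t)
    adj[[t]] <- c(adj[[t]], s)
  }
  parent <- rep(NA_integer_, nrow(graph$nodes))
  visited <- rep(FALSE, nrow(graph$nodes))
  stack <- rid; visited[rid] <- TRUE
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (v in adj[[u]]) {
      if (!visited[v]) {
        visited[v] <- TRUE
        parent[v] <- u
        stack <- c(stack, v)
      }
    }
  }

  nearest_indication <- function(id) {
    cur <- parent[id]
    while (!is.na(cur)) {
      if (canon(graph$nodes$category[cur]) %in%
            c(DISEASE_LIKE, "indications")) {
        return(graph$nodes$name[cur])
      }
      cur <- parent[cur]
    }
    "(root)"
  }

  records <- list()
  adverse <- character(0); contra <- character(0); indic <- character(0)
  for (id in comp) {
    cc <- canon(graph$nodes$category[id])
    if (cc == "drug applications") {
      key <- nearest_indication(id)
      a <- graph$node_attrs[[id]]
      parsed <- list()
      for (k in names(a)) {
        p <- parse_dosage(as.character(a[[k]]))
        if (!is.null(p$mg_range)) {
          parsed[[paste0(k, "_mg_range")]] <- p$mg_range
        } else if (!is.null(p$mg)) {
          parsed[[paste0(k, "_mg")]] <- p$mg
        }
        if (!is.null(p$per_day)) {
          parsed[[paste0(k, "_per_day")]] <- p$per_day
        }
      }
      records[[key]] <- list(node = graph$nodes$name[id],
                             attributes = a, parsed = parsed)
    } else if (cc == "adverse reactions" && id != rid) {
      adverse <- c(adverse, graph$nodes$name[id])
    } else if (cc == "contraindications" && id != rid) {
      contra <- c(contra, graph$nodes$name[id])
    } else if (cc == "indications" && id != rid) {
      indic <- c(indic, graph$nodes$name[id])
    }
  }

  structure(
    list(
      root = graph$nodes$name[rid],
      tree_edges = graph_edges(graph)[match(tree, graph$edges$edge_id), ,
                                      drop = FALSE],
      records = records,
      adverse_reactions = sort(adverse),
      contraindications = sort(contra),
      indications = sort(indic),
      total_cost = sum(1 / e$weight[tree]),
      n_nodes = length(comp)
    ),
    class = "mk_mst_result"
  )
}

#' @export
print.mk_mst_result <- function(x, ...) {
  cat("<mk_mst_result> root '", x$root, "': ", x$n_nodes, " nodes, ",
      nrow(x$tree_edges), " tree edges, total cost ",
      signif(x$total_cost, 4), "\n", sep = "")
  if (length(x$records)) {
    cat("  dosing records: ", paste(names(x$records), collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$adverse_reactions)) {
    cat("  adverse reactions: ",
        paste(x$adverse_reactions, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Parse dose quantities out of a free-text dosing string
#'
#' Recognizes one documented pattern family: `number mg`,
#' `number-number mg` (hyphen, en or em dash) and
#' `number(-number) times daily`. Strings that do not match simply
#' yield empty fields; the raw string is never dropped by callers.
#'
#' @param x Character string.
#' @return List with `mg` (single dose), `mg_range` (length-2 numeric),
#'   `per_day` (length-1 or -2 numeric); unmatched fields are `NULL`.
#' @examples
#' parse_dosage("30-240 mg")$mg_range
#' parse_dosage("10 mg")$mg
#' @export
parse_dosage <- function(x) {
  x <- as.character(x)[1]
  out <- list(mg = NULL, mg_range = NULL, per_day = NULL)
  if (is.na(x) || !nzchar(x)) return(out)
  num <- "([0-9]+(?:\\.[0-9]+)?)"
  dash <- "[–—-]"
  m <- regmatches(x, regexec(
    paste0(num, "\\s*", dash, "\\s*", num, "\\s*mg"), x
  ))[[1]]
  if (length(m)) {
    out$mg_range <- as.numeric(m[2:3])
  } else {
    m <- regmatches(x, regexec(paste0(num, "\\s*mg"), x))[[1]]
    if (length(m)) out$mg <- as.numeric(m[2])
  }
  m <- regmatches(x, regexec(
    paste0(num, "(?:\\s*", dash, "\\s*", num, ")?\\s*times daily"), x
  ))[[1]]
  if (length(m)) {
    v <- suppressWarnings(as.numeric(m[2:3]))
    out$per_day <- v[!is.na(v)]
  }
  out
}

#' Symptom-intersection map
#'
#' For two or more query symptoms, finds the nodes reachable from
#' every one of them within `max_hops` hops, traversing only disease,
#' symptom, drug and treatment-method nodes. Shared nodes expose the
#' knowledge the symptoms have in common; shared nodes of drug or
#' treatment-method category are the unified-treatment candidates for
#' the comorbidity.
#'
#' @param graph A `property_graph`.
#' @param symptoms Character vector of at least two node names.
#' @param max_hops Hop bound.
#' @return An `intersection_result`: list with `symptoms`, `shared`
#'   (data frame: `name`, `category`, one distance column per query
#'   symptom, and `link_labels`, the relation labels through which the
#'   node connects back to each symptom) and `unified_treatment`
#'   (character).
#' @examples
#' g <- bb_fixture_graph("cmis")
#' symptom_intersection(g, c("atrial fibrillation", "sinus bradycardia"))
#' @export
symptom_intersection <- function(graph, symptoms, max_hops = 6) {
  stopifnot(inherits(graph, "property_graph"))
  if (length(symptoms) < 2) {
    stop_medkg("argument", "need at least two query symptoms")
  }
  seed_ids <- vapply(symptoms, function(s) {
    ids <- find_nodes_by_name(graph, s)
    if (!length(ids)) stop_medkg("not_found", "no node named '", s, "'")
    pref <- ids[canon(graph$nodes$category[ids]) %in% CMIS_CATEGORIES]
    if (length(pref)) pref[1] else ids[1]
  }, integer(1))

  inc <- pg_incident(graph)
  dists <- lapply(seed_ids, function(s) {
    pg_bfs(graph, s, max_hops, allowed = CMIS_CATEGORIES, inc = inc)
  })
  reach <- Reduce(`&`, lapply(dists, function(d) !is.na(d)))
  shared_ids <- setdiff(which(reach), seed_ids)
  shared_ids <- shared_ids[order(graph$nodes$name[shared_ids])]

  dist_cols <- lapply(dists, function(d) d[shared_ids])
  link_labels <- lapply(shared_ids, function(id) {
    vapply(seq_along(seed_ids), function(k) {
      p <- pg_shortest_path(graph, id, seed_ids[k], max_hops,
                            allowed = CMIS_CATEGORIES, inc = inc)
      if (is.null(p) || length(p) < 2) return(NA_character_)
      graph$edges$label[pg_connecting_edge(graph, p[1], p[2])]
    }, character(1))
  })
  shared <- data.frame(
    name = graph$nodes$name[shared_ids],
    category = graph$nodes$category[shared_ids],
    stringsAsFactors = FALSE
  )
  for (k in seq_along(symptoms)) {
    shared[[paste0("dist_", k)]] <- dist_cols[[k]]
  }
  shared$link_labels <- I(link_labels)

  unified <- shared$name[canon(shared$category) %in% TREATMENT_LIKE]
  structure(
    list(symptoms = symptoms, shared = shared,
         unified_treatment = unified),
    class = "intersection_result"
  )
}

#' @export
print.intersection_result <- function(x, ...) {
  cat("<intersection_result> symptoms: ",
      paste(x$symptoms, collapse = ", "), "\n  shared nodes: ",
      if (nrow(x$shared)) paste(x$shared$name, collapse = ", ")
      else "(none)",
      "\n  unified treatment: ",
      if (length(x$unified_treatment))
        paste(x$unified_treatment, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' All-pairs shortest paths over comorbid conditions
#'
#' For every unordered pair of distinct selected nodes, returns one
#' minimum-hop undirected simple path (when the pair is connected
#' within `max_hops`), chosen deterministically as the
#' lexicographically smallest node-name sequence among the minimum-hop
#' paths. Unreachable pairs are omitted and counted.
#'
#' @param graph A `property_graph`.
#' @param names Character vector of node names to select (optional).
#' @param label_filter Character vector of categories to select
#'   (optional); the union of both selectors is used and must be
#'   non-empty.
#' @param max_hops Hop bound.
#' @return List of `path_result` objects, with attributes `n_pairs`
#'   and `n_unreachable`.
#' @examples
#' g <- bb_fixture_graph("cmc")
#' paths <- comorbidity_shortest_paths(g, label_filter = "Diseases")
#' @export
comorbidity_shortest_paths <- function(graph, names = NULL,
                                       label_filter = NULL,
                                       max_hops = 6) {
  stopifnot(inherits(graph, "property_graph"))
  sel <- integer(0)
  if (!is.null(names)) {
    sel <- c(sel, unlist(lapply(names, function(s)
      find_nodes_by_name(graph, s))))
  }
  if (!is.null(label_filter)) {
    sel <- c(sel, which(canon(graph$nodes$category) %in%
                          canon(label_filter)))
  }
  sel <- sort(unique(sel))
  if (!length(sel)) {
    stop_medkg("argument", "node selection is empty")
  }
  inc <- pg_incident(graph)
  # order selected nodes by name so each unordered pair is visited once
  sel <- sel[order(graph$nodes$name[sel], graph$nodes$category[sel])]
  out <- list()
  seen <- character(0)
  n_unreachable <- 0L
  n_pairs <- 0L
  for (i in seq_along(sel)) {
    for (j in seq_along(sel)) {
      if (j <= i) next
      n_pairs <- n_pairs + 1L
      p <- pg_shortest_path(graph, sel[i], sel[j], max_hops, inc = inc)
      if (is.null(p)) {
        n_unreachable <- n_unreachable + 1L
        next
      }
      key <- paste(graph$nodes$name[p], collapse = "\x1f")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- path_result(graph, p)
    }
  }
  attr(out, "n_pairs") <- n_pairs
  attr(out, "n_unreachable") <- n_unreachable
  out
}

#' Stage-ordered retrieval of treatments along a disease's stages
#'
#' Orders the given stage nodes topologically along their `Stage`
#' edges (Kahn's algorithm, lexicographic tie-break), then reports,
#' per stage, its directly attached treatment-method, drug and result
#' neighbors, plus the shortest inter-stage paths. A cycle among the
#' Stage edges is an error naming the nodes involved.
#'
#' @param graph A `property_graph`.
#' @param stage_names Character vector of stage node names.
#' @return A `staged_retrieval_result`: list with `order` (stage names
#'   in topological order), `stages` (named list of data frames:
#'   `name`, `category`, `relation`, `weight`) and `paths`
#'   (inter-stage shortest paths).
#' @examples
#' g <- bb_fixture_graph("cmds")
#' staged_retrieval(g, c("grade I hypertension", "grade II hypertension",
#'                       "grade III hypertension"))$order
#' @export
staged_retrieval <- function(graph, stage_names) {
  stopifnot(inherits(graph, "property_graph"))
  ids <- vapply(stage_names, function(s) {
    found <- find_nodes_by_name(graph, s)
    if (!length(found)) {
      stop_medkg("not_found", "no node named '", s, "'")
    }
    found[1]
  }, integer(1))

  e <- graph$edges
  stage_e <- which(canon(e$label) == "stage" &
                     e$start_node %in% ids & e$end_node %in% ids)
  indeg <- setNames(integer(length(ids)), ids)
  for (eid in stage_e) {
    k <- as.character(e$end_node[eid])
    indeg[k] <- indeg[k] + 1L
  }
  order_ids <- integer(0)
  remaining <- ids
  while (length(remaining)) {
    zero <- remaining[indeg[as.character(remaining)] == 0L]
    if (!length(zero)) {
      stop_medkg("cycle", "Stage edges contain a cycle among: ",
                 paste(graph$nodes$name[remaining], collapse = " -> "))
    }
    nxt <- zero[order(graph$nodes$name[zero])][1]
    order_ids <- c(order_ids, nxt)
    remaining <- setdiff(remaining, nxt)
    for (eid in stage_e) {
      if (e$start_node[eid] == nxt) {
        k <- as.character(e$end_node[eid])
        indeg[k] <- indeg[k] - 1L
      }
    }
  }

  inc <- pg_incident(graph)
  stage_report <- lapply(order_ids, function(id) {
    rows <- lapply(inc[[id]], function(eid) {
      v <- if (e$start_node[eid] == id) e$end_node[eid]
           else e$start_node[eid]
      if (canon(graph$nodes$category[v]) %in%
            c("treatment methods", "drugs", "results")) {
        data.frame(
          name = graph$nodes$name[v],
          category = graph$nodes$category[v],
          relation = e$label[eid],
          weight = e$weight[eid],
          stringsAsFactors = FALSE
        )
      } else {
        NULL
      }
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows)
    else data.frame(name = character(0), category = character(0),
                    relation = character(0), weight = integer(0))
  })
  names(stage_report) <- graph$nodes$name[order_ids]

  structure(
    list(
      order = graph$nodes$name[order_ids],
      stages = stage_report,
      paths = comorbidity_shortest_paths(graph,
                                         names = stage_names)
    ),
    class = "staged_retrieval_result"
  )
}

#' @export
print.staged_retrieval_result <- function(x, ...) {
  cat("<staged_retrieval_result> ", length(x$order), " stage(s)\n",
      sep = "")
  for (s in x$order) {
    cat("  ", s, ": ",
        if (nrow(x$stages[[s]])) paste(x$stages[[s]]$name,
                                       collapse = "; ")
        else "(nothing attached)", "\n", sep = "")
  }
  invisible(x)
}
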