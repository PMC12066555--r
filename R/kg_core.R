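# Property graph built from quintuple assertions.
#
# Node identity is (name, category): the same surface name may appear
# as, say, both a disease and an adverse reaction, and those are
# distinct nodes. Re-asserting an existing (subject, relation, object)
# never stores a second edge; it increments the edge's occurrence
# weight, so an edge's weight is the number of quintuple rows (i.e.
# supporting sentences) asserting it.
#
# Incidence is stored as doubly linked edge records: each node holds a
# pointer to its first incident edge, and each edge holds
# previous/next pointers at its start side (sp/sn) and at its end side
# (ep/en). Following the chain from first_edge enumerates a node's
# incident edges in insertion order. The linked records are the
# in-memory layout, checked in the test suite against a brute-force
# scan; they are not a serialization format.

#' Construct a quintuple
#'
#' The atomic knowledge unit: an ordered assertion
#' (subject, subject-type, relation, object, object-type). The
#' quintuple is direction-asymmetric: swapping subject and object
#' yields a different assertion.
#'
#' @param sub,sub_type Subject entity name and its category.
#' @param rel Relation (predicate) name.
#' @param obj,obj_type Object entity name and its category.
#' @param sub_attrs,obj_attrs Optional named lists of entity
#'   attributes (e.g. dosage strings).
#' @param rel_label Optional relation category from the schema
#'   vocabulary, when `rel` is a free-text surface form.
#' @return A one-row quintuple table (class `quintuple_tbl`).
#' @examples
#' quintuple("propranolol", "Drugs", "Indications",
#'           "hypertension", "Diseases")
#' @export
quintuple <- function(sub, sub_type, rel, obj, obj_type,
                      sub_attrs = list(), obj_attrs = list(),
                      rel_label = NA_character_) {
  fields <- list(sub = sub, sub_type = sub_type, rel = rel,
                 obj = obj, obj_type = obj_type)
  bad <- names(fields)[!vapply(fields, function(f) {
    is.character(f) && length(f) == 1 && nzchar(trimws(f))
  }, logical(1))]
  if (length(bad)) {
    stop_medkg("format", "quintuple field(s) empty or not scalar: ",
               paste(bad, collapse = ", "))
  }
  df <- data.frame(
    sub = sub, sub_type = sub_type, rel = rel,
    rel_label = rel_label, obj = obj, obj_type = obj_type,
    stringsAsFactors = FALSE
  )
  df$sub_attrs <- list(sub_attrs)
  df$obj_attrs <- list(obj_attrs)
  class(df) <- c("quintuple_tbl", class(df))
  df
}

#' Coerce a data frame to a quintuple table
#'
#' @param df Data frame with columns `sub`, `sub_type`, `rel`, `obj`,
#'   `obj_type`; optional `rel_label`, and list columns `sub_attrs`,
#'   `obj_attrs`.
#' @return A `quintuple_tbl`.
#' @export
as_quintuples <- function(df) {
  if (inherits(df, "quintuple_tbl")) return(df)
  require_columns(df, c("sub", "sub_type", "rel", "obj", "obj_type"),
                  "quintuple table")
  if (is.null(df$rel_label)) {
    df$rel_label <- rep(NA_character_, nrow(df))
  }
  if (is.null(df$sub_attrs)) df$sub_attrs <- rep(list(list()), nrow(df))
  if (is.null(df$obj_attrs)) df$obj_attrs <- rep(list(list()), nrow(df))
  df <- df[c("sub", "sub_type", "rel", "rel_label", "obj", "obj_type",
             "sub_attrs", "obj_attrs")]
  class(df) <- unique(c("quintuple_tbl", class(df)))
  df
}

#' @export
rbind.quintuple_tbl <- function(..., deparse.level = 1) {
  parts <- lapply(list(...), function(x) {
    x <- as_quintuples(x)
    class(x) <- "data.frame"
    x
  })
  out <- do.call(rbind, parts)
  class(out) <- c("quintuple_tbl", class(out))
  out
}

node_key <- function(name, category) {
  paste(canon(name), canon(category), sep = "\x1f")
}

# Build a property graph by ingesting quintuples -----------------------

#' Ingest quintuples into a weighted labeled property graph
#'
#' Iterates over the rows, creating one node per distinct
#' (name, category) and one edge per distinct
#' (subject node, relation, object node); re-asserting an existing
#' triple increments that edge's weight by one. Node attributes merge
#' last-writer-wins, with overwrites of differing values recorded as
#' conflict notes in the diagnostics. The resulting graph is
#' independent of row order up to node-id assignment.
#'
#' @param rows A `quintuple_tbl` (or coercible data frame).
#' @param schema Optional `ontology_schema`; when supplied, every row
#'   is validated (non-strict) and findings are collected in the
#'   diagnostics, never dropped.
#' @param on_name_reuse What to do when a row uses an existing node
#'   name under a new category: `"fork"` (default) keeps the two as
#'   distinct nodes, `"reject"` rejects the row with a diagnostic.
#' @return A `property_graph`. Diagnostics (rejected rows, attribute
#'   conflicts, validation findings) are in `graph_diagnostics()`.
#' @examples
#' g <- ingest_quintuples(rbind(
#'   quintuple("beta-blockers", "MT", "Indications",
#'             "heart failure", "Diseases"),
#'   quintuple("beta-blockers", "MT", "Indications",
#'             "heart failure", "Diseases")
#' ))
#' edge_weight(g, "beta-blockers", "Indications", "heart failure")
#' @export
ingest_quintuples <- function(rows, schema = NULL,
                              on_name_reuse = c("fork", "reject")) {
  on_name_reuse <- match.arg(on_name_reuse)
  rows <- as_quintuples(rows)
  n <- nrow(rows)

  node_ix <- new.env(parent = emptyenv(), hash = TRUE)
  name_cat <- new.env(parent = emptyenv(), hash = TRUE)
  edge_ix <- new.env(parent = emptyenv(), hash = TRUE)

  nm <- character(0); cat_ <- character(0)
  first_edge <- integer(0); last_edge <- integer(0)
  attrs <- list()
  e_start <- integer(0); e_end <- integer(0)
  e_label <- character(0); e_lcat <- character(0); e_w <- integer(0)
  e_sp <- integer(0); e_sn <- integer(0)
  e_ep <- integer(0); e_en <- integer(0)

  rejected <- list(); conflicts <- list(); findings <- list()

  get_node <- function(name, category, row_i) {
    key <- node_key(name, category)
    id <- node_ix[[key]]
    if (!is.null(id)) return(id)
    if (on_name_reuse == "reject") {
      prev <- name_cat[[canon(name)]]
      if (!is.null(prev) && prev != canon(category)) return(-1L)
    }
    id <- length(nm) + 1L
    nm[[id]] <<- name; cat_[[id]] <<- category
    first_edge[[id]] <<- NA_integer_; last_edge[[id]] <<- NA_integer_
    attrs[[id]] <<- list()
    node_ix[[key]] <- id
    name_cat[[canon(name)]] <- canon(category)
    id
  }

  link_side <- function(eid, node, side) {
    # append edge eid to the incidence chain of `node`
    if (is.na(first_edge[[node]])) {
      first_edge[[node]] <<- eid
    } else {
      tl <- last_edge[[node]]
      if (e_start[[tl]] == node) e_sn[[tl]] <<- eid else e_en[[tl]] <<- eid
      if (side == "s") e_sp[[eid]] <<- tl else e_ep[[eid]] <<- tl
    }
    last_edge[[node]] <<- eid
  }

  merge_attrs <- function(id, new, row_i) {
    for (k in names(new)) {
      old <- attrs[[id]][[k]]
      if (!is.null(old) && !identical(old, new[[k]])) {
        conflicts[[length(conflicts) + 1L]] <<- data.frame(
          row = row_i, node = nm[[id]], category = cat_[[id]],
          key = k, old = as.character(old)[1],
          new = as.character(new[[k]])[1], stringsAsFactors = FALSE
        )
      }
      attrs[[id]][[k]] <<- new[[k]]
    }
  }

  for (i in seq_len(n)) {
    f <- c(rows$sub[i], rows$sub_type[i], rows$rel[i],
           rows$obj[i], rows$obj_type[i])
    if (anyNA(f) || any(!nzchar(trimws(f)))) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        row = i, message = "empty mandatory field",
        stringsAsFactors = FALSE
      )
      next
    }
    if (!is.null(schema)) {
      v <- validate_quintuple(rows[i, ], schema, strict = FALSE)
      if (nrow(v)) {
        v$row <- i
        findings[[length(findings) + 1L]] <- as.data.frame(v)
      }
    }
    s <- get_node(rows$sub[i], rows$sub_type[i], i)
    o <- get_node(rows$obj[i], rows$obj_type[i], i)
    if (s < 0L || o < 0L) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        row = i, message = "name already used under another category",
        stringsAsFactors = FALSE
      )
      next
    }
    merge_attrs(s, rows$sub_attrs[[i]], i)
    merge_attrs(o, rows$obj_attrs[[i]], i)

    ekey <- paste(s, canon(rows$rel[i]), o, sep = "\x1f")
    eid <- edge_ix[[ekey]]
    if (!is.null(eid)) {
      e_w[[eid]] <- e_w[[eid]] + 1L
      next
    }
    eid <- length(e_start) + 1L
    e_start[[eid]] <- s; e_end[[eid]] <- o
    e_label[[eid]] <- rows$rel[i]
    e_lcat[[eid]] <- if (is.na(rows$rel_label[i])) rows$rel[i]
                     else rows$rel_label[i]
    e_w[[eid]] <- 1L
    e_sp[[eid]] <- NA_integer_; e_sn[[eid]] <- NA_integer_
    e_ep[[eid]] <- NA_integer_; e_en[[eid]] <- NA_integer_
    link_side(eid, s, "s")
    if (o != s) link_side(eid, o, "e")
    edge_ix[[ekey]] <- eid
  }

  g <- structure(
    list(
      nodes = data.frame(
        node_id = seq_along(nm), name = nm, category = cat_,
        first_edge = first_edge, last_edge = last_edge,
        stringsAsFactors = FALSE
      ),
      node_attrs = attrs,
      edges = data.frame(
        edge_id = seq_along(e_start), start_node = e_start,
        end_node = e_end, label = e_label, label_category = e_lcat,
        weight = e_w, sp = e_sp, sn = e_sn, ep = e_ep, en = e_en,
        stringsAsFactors = FALSE
      ),
      diagnostics = list(
        rejected = if (length(rejected)) do.call(rbind, rejected)
                   else data.frame(row = integer(0),
                                   message = character(0)),
        attr_conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                         else NULL,
        validation = if (length(findings)) do.call(rbind, findings)
                     else NULL
      )
    ),
    class = "property_graph"
  )
  g
}

#' @export
print.property_graph <- function(x, ...) {
  cat("<property_graph> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (total weight ",
      sum(x$edges$weight), ")\n", sep = "")
  invisible(x)
}

#' Graph accessors
#'
#' `graph_nodes()` and `graph_edges()` return plain data frames
#' (edges with endpoint names resolved); `graph_diagnostics()` returns
#' the ingestion diagnostics; `node_attributes()` returns one node's
#' attribute list.
#'
#' @param graph A `property_graph`.
#' @return A data frame, list, or named list respectively.
#' @export
graph_nodes <- function(graph) {
  stopifnot(inherits(graph, "property_graph"))
  graph$nodes[c("node_id", "name", "category")]
}

#' @rdname graph_nodes
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "property_graph"))
  e <- graph$edges
  data.frame(
    edge_id = e$edge_id,
    sub = graph$nodes$name[e$start_node],
    sub_category = graph$nodes$category[e$start_node],
    label = e$label,
    label_category = e$label_category,
    obj = graph$nodes$name[e$end_node],
    obj_category = graph$nodes$category[e$end_node],
    weight = e$weight,
    stringsAsFactors = FALSE
  )
}

#' @rdname graph_nodes
#' @export
graph_diagnostics <- function(graph) {
  stopifnot(inherits(graph, "property_graph"))
  graph$diagnostics
}

#' @rdname graph_nodes
#' @param name,category Node identity.
#' @export
node_attributes <- function(graph, name, category) {
  id <- find_node(graph, name, category)
  graph$node_attrs[[id]]
}

# resolve a node id by name (+ optional category); errors when absent
find_node <- function(graph, name, category = NULL) {
  hit <- canon(graph$nodes$name) == canon(name)
  if (!is.null(category)) {
    hit <- hit & canon(graph$nodes$category) == canon(category)
  }
  ids <- graph$nodes$node_id[hit]
  if (!length(ids)) {
    stop_medkg("not_found", "no node named '", name, "'",
               if (!is.null(category)) paste0(" [", category, "]"))
  }
  if (length(ids) > 1) {
    stop_medkg(
      "ambiguous", "name '", name, "' matches several categories: ",
      paste(graph$nodes$category[hit], collapse = ", "),
      "; supply `category`"
    )
  }
  ids
}

# all ids matching a name (any category)
find_nodes_by_name <- function(graph, name) {
  graph$nodes$node_id[canon(graph$nodes$name) == canon(name)]
}

#' Occurrence weight of one stored edge
#'
#' @param graph A `property_graph`.
#' @param sub_name,rel,obj_name The triple, by entity name and
#'   relation label (case-insensitive).
#' @param sub_category,obj_category Optional category qualifiers when
#'   a name is ambiguous.
#' @return Integer weight (number of supporting quintuple rows).
#' @export
edge_weight <- function(graph, sub_name, rel, obj_name,
                        sub_category = NULL, obj_category = NULL) {
  stopifnot(inherits(graph, "property_graph"))
  e <- graph$edges
  hit <- canon(graph$nodes$name[e$start_node]) == canon(sub_name) &
    canon(graph$nodes$name[e$end_node]) == canon(obj_name) &
    canon(e$label) == canon(rel)
  if (!is.null(sub_category)) {
    hit <- hit &
      canon(graph$nodes$category[e$start_node]) == canon(sub_category)
  }
  if (!is.null(obj_category)) {
    hit <- hit &
      canon(graph$nodes$category[e$end_node]) == canon(obj_category)
  }
  if (!any(hit)) {
    stop_medkg("not_found", "no edge (", sub_name, ") -[", rel, "]-> (",
               obj_name, ")")
  }
  if (sum(hit) > 1) {
    stop_medkg("ambiguous", "several edges match (", sub_name, ") -[",
               rel, "]-> (", obj_name, "); qualify the categories")
  }
  e$weight[hit]
}

#' Grade edge weights into quantile tiers
#'
#' Frequency-based grading of relationship strength: edges are bucketed
#' by the empirical quantile of their weight into `n_tiers` tiers
#' (tier 1 lowest). Equal weights always share a tier and a higher
#' weight never receives a lower tier; when there are fewer distinct
#' weights than tiers, the unused tiers are simply empty.
#'
#' @param graph A `property_graph` with at least one edge.
#' @param n_tiers Number of tiers (>= 1).
#' @return Named integer vector, tier per edge id.
#' @export
grade_weights <- function(graph, n_tiers) {
  stopifnot(inherits(graph, "property_graph"))
  if (!nrow(graph$edges)) {
    stop_medkg("format", "cannot grade weights of an empty graph")
  }
  if (!is.numeric(n_tiers) || n_tiers < 1) {
    stop_medkg("format", "n_tiers must be >= 1")
  }
  w <- graph$edges$weight
  frac <- vapply(w, function(wi) mean(w <= wi), numeric(1))
  tiers <- as.integer(ceiling(n_tiers * frac))
  tiers[tiers < 1L] <- 1L
  setNames(tiers, graph$edges$edge_id)
}

#' Enumerate a node's incident edges via the linked edge records
#'
#' Starts at the node's `first_edge` pointer and follows the next
#' pointer on whichever side of each record the node occupies (`sn`
#' at the start side, `en` at the end side), yielding the incident
#' edges in insertion order. Equivalent to a full scan over all edges;
#' the pointer chain is the storage layout under test.
#'
#' @param graph A `property_graph`.
#' @param node_name,category Node identity.
#' @return Data frame of incident edges (as in [graph_edges()]) in
#'   insertion order.
#' @export
linked_edge_scan <- function(graph, node_name, category = NULL) {
  id <- find_node(graph, node_name, category)
  e <- graph$edges
  out <- integer(0)
  cur <- graph$nodes$first_edge[id]
  seen <- 0L
  while (!is.na(cur)) {
    if (cur < 1L || cur > nrow(e)) {
      stop_medkg("internal", "dangling edge pointer at node '",
                 node_name, "'")
    }
    out <- c(out, cur)
    seen <- seen + 1L
    if (seen > nrow(e)) {
      stop_medkg("internal", "cycle in linked edge records at node '",
                 node_name, "'")
    }
    cur <- if (e$start_node[cur] == id) e$sn[cur] else e$en[cur]
  }
  graph_edges(graph)[out, , drop = FALSE]
}

# rebuild a graph from explicit node/edge tables (weights preserved);
# pointers are re-derived by simulated insertion in edge order
pg_build <- function(nodes_df, node_attrs, edges_df) {
  n <- nrow(nodes_df)
  first_edge <- rep(NA_integer_, n); last_edge <- rep(NA_integer_, n)
  m <- nrow(edges_df)
  sp <- rep(NA_integer_, m); sn <- rep(NA_integer_, m)
  ep <- rep(NA_integer_, m); en <- rep(NA_integer_, m)
  es <- edges_df$start_node; ee <- edges_df$end_node
  for (eid in seq_len(m)) {
    for (side in c("s", "e")) {
      node <- if (side == "s") es[eid] else ee[eid]
      if (side == "e" && ee[eid] == es[eid]) next
      if (is.na(first_edge[node])) {
        first_edge[node] <- eid
      } else {
        tl <- last_edge[node]
        if (es[tl] == node) sn[tl] <- eid else en[tl] <- eid
        if (side == "s") sp[eid] <- tl else ep[eid] <- tl
      }
      last_edge[node] <- eid
    }
  }
  structure(
    list(
      nodes = data.frame(
        node_id = seq_len(n), name = nodes_df$name,
        category = nodes_df$category, first_edge = first_edge,
        last_edge = last_edge, stringsAsFactors = FALSE
      ),
      node_attrs = node_attrs,
      edges = data.frame(
        edge_id = seq_len(m), start_node = es, end_node = ee,
        label = edges_df$label,
        label_category = edges_df$label_category,
        weight = as.integer(edges_df$weight),
        sp = sp, sn = sn, ep = ep, en = en, stringsAsFactors = FALSE
      ),
      diagnostics = list(
        rejected = data.frame(row = integer(0), message = character(0)),
        attr_conflicts = NULL, validation = NULL
      )
    ),
    class = "property_graph"
  )
}

# canonical, id-free representation for graph comparison
graph_canonical <- function(graph) {
  nd <- graph_nodes(graph)
  o <- order(nd$category, nd$name)
  nd <- nd[o, c("name", "category")]
  at <- graph$node_attrs[graph$nodes$node_id[o]]
  at <- lapply(at, function(a) {
    if (length(a)) a[order(names(a))] else list()
  })
  ed <- graph_edges(graph)
  ed <- ed[order(ed$sub, ed$sub_category, ed$label, ed$obj,
                 ed$obj_category),
           c("sub", "sub_category", "label", "label_category",
             "obj", "obj_category", "weight")]
  rownames(nd) <- NULL; rownames(ed) <- NULL
  list(nodes = nd, attrs = at, edges = ed)
}

#' Compare two graphs up to node-id assignment
#'
#' @param g1,g2 `property_graph` objects.
#' @return `TRUE` when the graphs have identical node names,
#'   categories, attributes, edge labels and weights, regardless of
#'   internal ids and insertion order.
#' @export
graph_identical <- function(g1, g2) {
  isTRUE(all.equal(graph_canonical(g1), graph_canonical(g2),
                   check.attributes = FALSE))
}
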