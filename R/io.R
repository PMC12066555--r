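# Interchange formats: quintuple TSV tables (the knowledge-entry
# column layout: Entity1/Type1/Attribute1, Entity2/Type2/Attribute2,
# Direction, R_name, R_label), graph JSON, GraphML, and openCypher
# scripts for loading a graph store.

QT_COLUMNS <- c("Entity1", "Type1", "Attribute1", "Entity2", "Type2",
                "Attribute2", "Direction", "R_name", "R_label")

parse_attr_cell <- function(cell, line, diag) {
  out <- list()
  if (is.na(cell) || !nzchar(trimws(cell))) {
    return(list(attrs = out, diag = diag))
  }
  for (chunk in strsplit(cell, ";", fixed = TRUE)[[1]]) {
    chunk <- trimws(chunk)
    if (!nzchar(chunk)) next
    eq <- regexpr("=", chunk, fixed = TRUE)
    if (eq < 1) {
      diag <- rbind(diag, data.frame(
        line = line,
        message = paste0("attribute chunk without '=': '", chunk, "'"),
        stringsAsFactors = FALSE
      ))
      next
    }
    out[[trimws(substr(chunk, 1, eq - 1))]] <-
      trimws(substr(chunk, eq + 1, nchar(chunk)))
  }
  list(attrs = out, diag = diag)
}

#' Read a quintuple table
#'
#' Reads the tab-separated knowledge-entry layout (columns `Entity1`,
#' `Type1`, `Attribute1`, `Entity2`, `Type2`, `Attribute2`,
#' `Direction`, `R_name`, `R_label`; attribute cells are
#' `key=value;key=value`). Rows with `Direction = reverse` are flipped
#' into canonical forward quintuples at read time. Malformed rows are
#' collected with their line numbers in the `diagnostics` attribute,
#' never silently skipped.
#'
#' @param path UTF-8 TSV file.
#' @return A `quintuple_tbl` with a `diagnostics` attribute
#'   (data frame of `line`, `message`).
#' @examples
#' q <- read_quintuple_table(medkg_extdata("bb_mkmst.tsv"))
#' nrow(q)
#' @export
read_quintuple_table <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, setdiff(QT_COLUMNS, c("Attribute1", "Attribute2",
                                            "R_label")),
                  "quintuple table")
  if (is.null(df$Attribute1)) df$Attribute1 <- ""
  if (is.null(df$Attribute2)) df$Attribute2 <- ""
  if (is.null(df$R_label)) df$R_label <- ""

  diag <- data.frame(line = integer(0), message = character(0),
                     stringsAsFactors = FALSE)
  keep <- logical(nrow(df))
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    mand <- c(df$Entity1[i], df$Type1[i], df$Entity2[i], df$Type2[i],
              df$R_name[i])
    if (any(!nzchar(trimws(mand)))) {
      diag <- rbind(diag, data.frame(
        line = line, message = "empty mandatory field",
        stringsAsFactors = FALSE
      ))
      next
    }
    dir <- canon(df$Direction[i])
    if (!dir %in% c("forward", "reverse")) {
      diag <- rbind(diag, data.frame(
        line = line,
        message = paste0("unknown Direction '", df$Direction[i], "'"),
        stringsAsFactors = FALSE
      ))
      next
    }
    a1 <- parse_attr_cell(df$Attribute1[i], line, diag)
    diag <- a1$diag
    a2 <- parse_attr_cell(df$Attribute2[i], line, diag)
    diag <- a2$diag
    if (dir == "forward") {
      rows[[i]] <- list(sub = df$Entity1[i], sub_type = df$Type1[i],
                        sub_attrs = a1$attrs, obj = df$Entity2[i],
                        obj_type = df$Type2[i], obj_attrs = a2$attrs)
    } else {
      rows[[i]] <- list(sub = df$Entity2[i], sub_type = df$Type2[i],
                        sub_attrs = a2$attrs, obj = df$Entity1[i],
                        obj_type = df$Type1[i], obj_attrs = a1$attrs)
    }
    rows[[i]]$rel <- df$R_name[i]
    rows[[i]]$rel_label <- if (nzchar(df$R_label[i])) df$R_label[i]
                           else NA_character_
    keep[i] <- TRUE
  }
  rows <- rows[keep]
  out <- data.frame(
    sub = vapply(rows, `[[`, character(1), "sub"),
    sub_type = vapply(rows, `[[`, character(1), "sub_type"),
    rel = vapply(rows, `[[`, character(1), "rel"),
    rel_label = vapply(rows, `[[`, character(1), "rel_label"),
    obj = vapply(rows, `[[`, character(1), "obj"),
    obj_type = vapply(rows, `[[`, character(1), "obj_type"),
    stringsAsFactors = FALSE
  )
  out$sub_attrs <- lapply(rows, `[[`, "sub_attrs")
  out$obj_attrs <- lapply(rows, `[[`, "obj_attrs")
  out <- as_quintuples(out)
  attr(out, "diagnostics") <- diag
  out
}

format_attr_cell <- function(attrs) {
  if (!length(attrs)) return("")
  paste(paste0(names(attrs), "=",
               vapply(attrs, function(v) as.character(v)[1],
                      character(1))),
        collapse = ";")
}

#' Write a quintuple table
#'
#' Inverse of [read_quintuple_table()]; all rows are written with
#' `Direction = forward`.
#'
#' @param quintuples A `quintuple_tbl`.
#' @param path Output path.
#' @export
write_quintuple_table <- function(quintuples, path) {
  q <- as_quintuples(quintuples)
  df <- data.frame(
    Entity1 = q$sub, Type1 = q$sub_type,
    Attribute1 = vapply(q$sub_attrs, format_attr_cell, character(1)),
    Entity2 = q$obj, Type2 = q$obj_type,
    Attribute2 = vapply(q$obj_attrs, format_attr_cell, character(1)),
    Direction = "forward", R_name = q$rel,
    R_label = ifelse(is.na(q$rel_label), "", q$rel_label),
    stringsAsFactors = FALSE
  )
  write_tsv_strict(df, path)
}

# graph JSON ------------------------------------------------------------

#' Graph JSON serialization
#'
#' `write_graph_json()` writes a canonical, deterministic JSON
#' document (nodes sorted by category and name; edges by endpoint
#' names and label); `read_graph_json()` rebuilds an equivalent graph,
#' preserving names, categories, attributes, labels and weights
#' byte-for-byte (including non-ASCII characters).
#'
#' @param graph A `property_graph`.
#' @param path File path.
#' @return `read_graph_json()` returns a `property_graph`.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "property_graph"))
  cg <- graph_canonical(graph)
  nodes <- lapply(seq_len(nrow(cg$nodes)), function(i) {
    o <- list(name = cg$nodes$name[i], category = cg$nodes$category[i])
    if (length(cg$attrs[[i]])) o$attributes <- cg$attrs[[i]]
    o
  })
  edges <- lapply(seq_len(nrow(cg$edges)), function(i) as.list(cg$edges[i, ]))
  jsonlite::write_json(
    list(format = "medkg-graph", version = 1L,
         nodes = nodes, edges = edges),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- data.frame(
    name = vapply(j$nodes, `[[`, character(1), "name"),
    category = vapply(j$nodes, `[[`, character(1), "category"),
    stringsAsFactors = FALSE
  )
  attrs <- lapply(j$nodes, function(n) n$attributes %||% list())
  key <- node_key(nodes$name, nodes$category)
  edges <- data.frame(
    start_node = vapply(j$edges, function(e) {
      match(node_key(e$sub, e$sub_category), key)
    }, integer(1)),
    end_node = vapply(j$edges, function(e) {
      match(node_key(e$obj, e$obj_category), key)
    }, integer(1)),
    label = vapply(j$edges, `[[`, character(1), "label"),
    label_category = vapply(j$edges, `[[`, character(1),
                            "label_category"),
    weight = vapply(j$edges, function(e) as.integer(e$weight),
                    integer(1)),
    stringsAsFactors = FALSE
  )
  if (anyNA(edges$start_node) || anyNA(edges$end_node)) {
    stop_medkg("format", "graph JSON references undeclared node(s)")
  }
  pg_build(nodes, attrs, edges)
}

#' Round-trip a graph through its JSON serialization
#'
#' Writes the graph to a temporary JSON file and reads it back;
#' useful as an identity check.
#'
#' @param graph A `property_graph`.
#' @return The re-read `property_graph`.
#' @export
roundtrip_graph <- function(graph) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_graph_json(graph, tmp)
  read_graph_json(tmp)
}

# GraphML ---------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Export a graph to GraphML
#'
#' Nodes carry `name` and `category` keys; edges carry `label`,
#' `label_category` and `weight`. Output is deterministic (sorted as
#' in [write_graph_json()]).
#'
#' @param graph A `property_graph`.
#' @param path Output path.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "property_graph"))
  cg <- graph_canonical(graph)
  key <- node_key(cg$nodes$name, cg$nodes$category)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, useBytes = FALSE)
  w("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  w("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">")
  w("  <key id=\"name\" for=\"node\" attr.name=\"name\" ",
    "attr.type=\"string\"/>")
  w("  <key id=\"category\" for=\"node\" attr.name=\"category\" ",
    "attr.type=\"string\"/>")
  w("  <key id=\"label\" for=\"edge\" attr.name=\"label\" ",
    "attr.type=\"string\"/>")
  w("  <key id=\"label_category\" for=\"edge\" ",
    "attr.name=\"label_category\" attr.type=\"string\"/>")
  w("  <key id=\"weight\" for=\"edge\" attr.name=\"weight\" ",
    "attr.type=\"int\"/>")
  w("  <graph edgedefault=\"directed\">")
  for (i in seq_len(nrow(cg$nodes))) {
    w("    <node id=\"n", i, "\">")
    w("      <data key=\"name\">", xml_escape(cg$nodes$name[i]),
      "</data>")
    w("      <data key=\"category\">",
      xml_escape(cg$nodes$category[i]), "</data>")
    w("    </node>")
  }
  for (i in seq_len(nrow(cg$edges))) {
    s <- match(node_key(cg$edges$sub[i], cg$edges$sub_category[i]), key)
    t <- match(node_key(cg$edges$obj[i], cg$edges$obj_category[i]), key)
    w("    <edge source=\"n", s, "\" target=\"n", t, "\">")
    w("      <data key=\"label\">", xml_escape(cg$edges$label[i]),
      "</data>")
    w("      <data key=\"label_category\">",
      xml_escape(cg$edges$label_category[i]), "</data>")
    w("      <data key=\"weight\">", cg$edges$weight[i], "</data>")
    w("    </edge>")
  }
  w("  </graph>")
  w("</graphml>")
  invisible(path)
}

# Cypher export ---------------------------------------------------------

cypher_str <- function(x) {
  paste0("'", gsub("'", "\\\\'", gsub("\\", "\\\\", x, fixed = TRUE)),
         "'")
}

cypher_ident <- function(x) {
  paste0("`", gsub("`", "``", x, fixed = TRUE), "`")
}

#' Generate an openCypher load script for a graph
#'
#' Emits one `MERGE` per node keyed on (name, category-label) and one
#' `MERGE` per edge keyed on endpoints and relation label, carrying
#' the weight and node attributes as properties. Because `MERGE` (not
#' `CREATE`) is emitted, re-running the script on a populated store
#' cannot duplicate knowledge. Statement order is deterministic: all
#' nodes then all edges, each lexicographically sorted.
#'
#' @param graph A `property_graph`.
#' @return A `cypher_script`: list with `statements` (character
#'   vector) and `stats` (`n_merge_node`, `n_merge_edge`).
#' @examples
#' g <- bb_fixture_graph("cmds")
#' sc <- export_cypher(g)
#' sc$stats
#' @export
export_cypher <- function(graph) {
  stopifnot(inherits(graph, "property_graph"))
  cg <- graph_canonical(graph)
  node_stmts <- vapply(seq_len(nrow(cg$nodes)), function(i) {
    base <- paste0(
      "MERGE (n:", cypher_ident(cg$nodes$category[i]),
      " {name: ", cypher_str(cg$nodes$name[i]), "})"
    )
    a <- cg$attrs[[i]]
    if (length(a)) {
      sets <- paste0("n.", cypher_ident(names(a)), " = ",
                     cypher_str(vapply(a, function(v)
                       as.character(v)[1], character(1))))
      base <- paste0(base, " SET ", paste(sets, collapse = ", "))
    }
    paste0(base, ";")
  }, character(1))
  edge_stmts <- vapply(seq_len(nrow(cg$edges)), function(i) {
    paste0(
      "MATCH (a:", cypher_ident(cg$edges$sub_category[i]),
      " {name: ", cypher_str(cg$edges$sub[i]), "}), (b:",
      cypher_ident(cg$edges$obj_category[i]),
      " {name: ", cypher_str(cg$edges$obj[i]), "}) ",
      "MERGE (a)-[r:", cypher_ident(cg$edges$label[i]),
      "]->(b) SET r.weight = ", cg$edges$weight[i],
      ", r.label_category = ", cypher_str(cg$edges$label_category[i]),
      ";"
    )
  }, character(1))
  structure(
    list(
      statements = c(node_stmts, edge_stmts),
      stats = list(n_merge_node = length(node_stmts),
                   n_merge_edge = length(edge_stmts))
    ),
    class = "cypher_script"
  )
}

#' @export
print.cypher_script <- function(x, ...) {
  cat("<cypher_script> ", x$stats$n_merge_node, " node MERGEs, ",
      x$stats$n_merge_edge, " edge MERGEs\n", sep = "")
  invisible(x)
}

#' @rdname export_cypher
#' @param script A `cypher_script`.
#' @param path Output path (`.cypher`).
#' @export
write_cypher <- function(script, path) {
  stopifnot(inherits(script, "cypher_script"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(script$statements, con)
  invisible(path)
}

# packaged worked-example graphs ----------------------------------------

BB_FIXTURES <- c(multiuse = "bb_multiuse.tsv", synergy = "bb_synergy.tsv",
                 mkmst = "bb_mkmst.tsv", cmis = "bb_cmis.tsv",
                 cmc = "bb_cmc.tsv", cmds = "bb_cmds.tsv")

#' Load the packaged beta-blocker worked-example graphs
#'
#' The package ships six small quintuple tables transcribing the
#' published beta-blocker reasoning narratives: multi-hop indication
#' discovery (`"multiuse"`), synergy mining (`"synergy"`), the
#' propranolol dosing spanning tree (`"mkmst"`), symptom intersection
#' (`"cmis"`), comorbidity shortest paths (`"cmc"`) and staged
#' hypertension treatment (`"cmds"`). `"all"` concatenates every
#' table into one combined graph.
#'
#' @param which One of the six fixture names, `"all"`, or a character
#'   vector of fixture names to combine.
#' @return A `property_graph`.
#' @export
bb_fixture_graph <- function(which = "all") {
  if (identical(which, "all")) which <- names(BB_FIXTURES)
  bad <- setdiff(which, names(BB_FIXTURES))
  if (length(bad)) {
    stop_medkg("argument", "unknown fixture(s): ",
               paste(bad, collapse = ", "))
  }
  q <- do.call(rbind, lapply(unname(BB_FIXTURES[which]), function(f) {
    read_quintuple_table(medkg_extdata(f))
  }))
  ingest_quintuples(q)
}
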