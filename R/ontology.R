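# Ontology schema: medication types (MT), their attribute ontologies
# (AMT), the concept-term vocabulary, the relation vocabulary, and
# advisory category-pair rules constraining which relations may link
# which entity categories.

PROVENANCE_FLAGS <- c("G", "EC", "St", "Sc", "R", "EE")

#' Load an ontology schema from tabular files
#'
#' Reads up to five UTF-8 TSV tables and cross-references them into a
#' single schema object. All tables are optional; missing tables yield
#' empty components (an empty schema is valid). Name matching between
#' tables is case-insensitive; names are stored in their as-loaded form.
#'
#' @param amt AMT table (columns `mt`, `amt_name`, `concept_term`):
#'   one row per attribute ontology of a medication type. Path or
#'   data frame.
#' @param concepts Concept-term table (columns `name`, `sources`;
#'   sources semicolon-separated provenance flags among
#'   G, EC, St, Sc, R, EE).
#' @param relations Relation vocabulary (columns `relation`, `sources`).
#' @param pair_rules Category-pair rules (columns `subject_category`,
#'   `object_category`, `relations`, the last semicolon-separated).
#' @param mts Medication-type list (column `mt`). When omitted, the MT
#'   list is derived from the AMT table. The MT list is configuration,
#'   not a fixed constant.
#' @return An object of class `ontology_schema`.
#' @examples
#' sch <- bb_schema()
#' schema_stats(sch)
#' @seealso [schema_stats()], [validate_quintuple()], [write_schema()]
#' @export
load_schema <- function(amt = NULL, concepts = NULL, relations = NULL,
                        pair_rules = NULL, mts = NULL) {
  as_table <- function(x, cols, what) {
    if (is.null(x)) {
      return(as.data.frame(
        setNames(rep(list(character(0)), length(cols)), cols),
        stringsAsFactors = FALSE
      ))
    }
    if (is.character(x) && length(x) == 1) x <- read_tsv_strict(x)
    require_columns(x, cols, what)
    x[cols]
  }

  amt_df <- as_table(amt, c("mt", "amt_name", "concept_term"), "AMT table")
  con_df <- as_table(concepts, c("name", "sources"), "concept table")
  rel_df <- as_table(relations, c("relation", "sources"), "relation table")
  pr_df <- as_table(
    pair_rules,
    c("subject_category", "object_category", "relations"),
    "pair-rule table"
  )
  mt_df <- if (is.null(mts)) NULL else as_table(mts, "mt", "MT table")

  problems <- character(0)

  # concept terms: unique names, known provenance flags
  if (anyDuplicated(canon(con_df$name))) {
    dup <- unique(con_df$name[duplicated(canon(con_df$name))])
    problems <- c(problems, paste0(
      "duplicate concept term(s): ", paste(dup, collapse = ", ")
    ))
  }
  con_sources <- split_semicolon(con_df$sources)
  bad_flags <- setdiff(unique(unlist(con_sources)), PROVENANCE_FLAGS)
  if (length(bad_flags)) {
    problems <- c(problems, paste0(
      "unknown provenance flag(s): ", paste(bad_flags, collapse = ", ")
    ))
  }
  if (any(lengths(con_sources) == 0 & nzchar(con_df$name))) {
    problems <- c(problems, "concept term with empty source set")
  }

  # relations: unique names
  if (anyDuplicated(canon(rel_df$relation))) {
    dup <- unique(rel_df$relation[duplicated(canon(rel_df$relation))])
    problems <- c(problems, paste0(
      "duplicate relation(s): ", paste(dup, collapse = ", ")
    ))
  }
  rel_sources <- split_semicolon(rel_df$sources)
  bad_flags <- setdiff(unique(unlist(rel_sources)), PROVENANCE_FLAGS)
  if (length(bad_flags)) {
    problems <- c(problems, paste0(
      "unknown relation provenance flag(s): ",
      paste(bad_flags, collapse = ", ")
    ))
  }

  # AMT entries: (mt, amt_name) unique, concept term resolvable
  amt_key <- paste(canon(amt_df$mt), canon(amt_df$amt_name), sep = "\x1f")
  if (anyDuplicated(amt_key)) {
    dup <- amt_df$amt_name[duplicated(amt_key)]
    problems <- c(problems, paste0(
      "duplicate (mt, amt_name) entries: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  unresolved <- !(canon(amt_df$concept_term) %in% canon(con_df$name))
  if (any(unresolved)) {
    problems <- c(problems, paste0(
      "AMT entries referencing undeclared concept term(s): ",
      paste(unique(amt_df$concept_term[unresolved]), collapse = ", ")
    ))
  }

  # MT cross-reference
  mt_list <- if (is.null(mt_df)) unique(amt_df$mt) else mt_df$mt
  missing_mt <- !(canon(amt_df$mt) %in% canon(mt_list))
  if (any(missing_mt)) {
    problems <- c(problems, paste0(
      "AMT entries whose mt is not a declared medication type: ",
      paste(unique(amt_df$mt[missing_mt]), collapse = ", ")
    ))
  }

  # pair rules: unique pairs, relations resolvable, non-empty
  pr_key <- paste(canon(pr_df$subject_category),
                  canon(pr_df$object_category), sep = "\x1f")
  if (anyDuplicated(pr_key)) {
    problems <- c(problems, "duplicate category-pair rule(s)")
  }
  pr_rels <- split_semicolon(pr_df$relations)
  if (any(lengths(pr_rels) == 0 & nzchar(pr_df$subject_category))) {
    problems <- c(problems, "category-pair rule with empty relation set")
  }
  bad_rel <- setdiff(canon(unlist(pr_rels)), canon(rel_df$relation))
  if (length(bad_rel)) {
    problems <- c(problems, paste0(
      "pair-rule relation(s) not in the relation vocabulary: ",
      paste(bad_rel, collapse = ", ")
    ))
  }

  if (length(problems)) {
    stop_medkg("schema", "invalid ontology schema:\n  - ",
               paste(problems, collapse = "\n  - "))
  }

  structure(
    list(
      mts = mt_list,
      amts = amt_df,
      concept_terms = data.frame(
        name = con_df$name, sources = I(con_sources),
        stringsAsFactors = FALSE
      ),
      relations = data.frame(
        relation = rel_df$relation, sources = I(rel_sources),
        stringsAsFactors = FALSE
      ),
      pair_rules = data.frame(
        subject_category = pr_df$subject_category,
        object_category = pr_df$object_category,
        relations = I(pr_rels),
        stringsAsFactors = FALSE
      )
    ),
    class = "ontology_schema"
  )
}

#' Write an ontology schema back to TSV tables
#'
#' Inverse of [load_schema()]: writes `amt.tsv`, `concepts.tsv`,
#' `relations.tsv`, `pair_rules.tsv` and `mt.tsv` into `dir`.
#' `load_schema()` on the written files reproduces the schema.
#'
#' @param schema An `ontology_schema`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_schema <- function(schema, dir) {
  stopifnot(inherits(schema, "ontology_schema"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_strict(schema$amts, file.path(dir, "amt.tsv"))
  write_tsv_strict(
    data.frame(
      name = schema$concept_terms$name,
      sources = join_semicolon(schema$concept_terms$sources),
      stringsAsFactors = FALSE
    ),
    file.path(dir, "concepts.tsv")
  )
  write_tsv_strict(
    data.frame(
      relation = schema$relations$relation,
      sources = join_semicolon(schema$relations$sources),
      stringsAsFactors = FALSE
    ),
    file.path(dir, "relations.tsv")
  )
  write_tsv_strict(
    data.frame(
      subject_category = schema$pair_rules$subject_category,
      object_category = schema$pair_rules$object_category,
      relations = join_semicolon(schema$pair_rules$relations),
      stringsAsFactors = FALSE
    ),
    file.path(dir, "pair_rules.tsv")
  )
  write_tsv_strict(
    data.frame(mt = schema$mts, stringsAsFactors = FALSE),
    file.path(dir, "mt.tsv")
  )
  invisible(dir)
}

#' Load the packaged beta-blocker example schema
#'
#' Loads the schema transcribed from the published beta-blocker worked
#' example: 41 attribute ontologies over 17 concept terms, a 17-relation
#' vocabulary and 13 category-pair rules.
#'
#' @return An `ontology_schema`.
#' @export
bb_schema <- function() {
  load_schema(
    amt = medkg_extdata("bb_amt.tsv"),
    concepts = medkg_extdata("concepts.tsv"),
    relations = medkg_extdata("relations.tsv"),
    pair_rules = medkg_extdata("pair_rules.tsv"),
    mts = medkg_extdata("mt.tsv")
  )
}

#' Summary counts of an ontology schema
#'
#' @param schema An `ontology_schema`.
#' @return A list with `n_mts`, `n_amts`, `n_concept_terms`,
#'   `n_relations`, `n_pair_rules`, each the cardinality of the
#'   deduplicated component.
#' @export
schema_stats <- function(schema) {
  stopifnot(inherits(schema, "ontology_schema"))
  list(
    n_mts = length(unique(canon(schema$mts))),
    n_amts = nrow(unique(data.frame(
      mt = canon(schema$amts$mt), amt = canon(schema$amts$amt_name)
    ))),
    n_concept_terms = length(unique(canon(schema$concept_terms$name))),
    n_relations = length(unique(canon(schema$relations$relation))),
    n_pair_rules = nrow(unique(data.frame(
      s = canon(schema$pair_rules$subject_category),
      o = canon(schema$pair_rules$object_category)
    )))
  )
}

#' @export
print.ontology_schema <- function(x, ...) {
  s <- schema_stats(x)
  cat("<ontology_schema> ",
      s$n_mts, " medication types, ",
      s$n_amts, " AMT entries, ",
      s$n_concept_terms, " concept terms, ",
      s$n_relations, " relations, ",
      s$n_pair_rules, " pair rules\n", sep = "")
  invisible(x)
}

# categories a schema recognizes: concept terms, the MT/AMT layer
# names (when the schema declares that layer), and any category
# mentioned by a pair rule; an empty schema recognizes nothing and
# category checks pass vacuously
schema_categories <- function(schema) {
  layer <- if (length(schema$mts) || nrow(schema$amts)) c("MT", "AMT")
           else character(0)
  unique(canon(c(
    schema$concept_terms$name, layer,
    schema$pair_rules$subject_category, schema$pair_rules$object_category
  )))
}

#' Validate one quintuple against an ontology schema
#'
#' Checks the subject/object categories against the schema's category
#' vocabulary, the relation against the relation vocabulary (the
#' relation label category, when present, may satisfy the check if the
#' surface relation name does not), and the (subject-category,
#' object-category) pair against the pair rules. Pair rules are
#' advisory samples, so pair-rule findings are warnings unless
#' `strict = TRUE`. Validation never fails on content, only on
#' malformed input.
#'
#' @param q A quintuple: a list or one-row data frame with fields
#'   `sub`, `sub_type`, `rel`, `obj`, `obj_type` (optional `rel_label`).
#' @param schema An `ontology_schema`.
#' @param strict Escalate pair-rule findings to violations.
#' @return A `validation_report`: data frame with columns `code`,
#'   `severity` (`"violation"` or `"warning"`) and `message`; zero rows
#'   when the quintuple is clean.
#' @examples
#' sch <- bb_schema()
#' q <- quintuple("propranolol", "Drugs", "Indications",
#'                "hypertension", "Diseases")
#' validate_quintuple(q, sch)
#' @export
validate_quintuple <- function(q, schema, strict = FALSE) {
  stopifnot(inherits(schema, "ontology_schema"))
  q <- as.list(q)
  need <- c("sub", "sub_type", "rel", "obj", "obj_type")
  got <- vapply(need, function(f) {
    !is.null(q[[f]]) && length(q[[f]]) == 1 && nzchar(trimws(q[[f]]))
  }, logical(1))
  if (!all(got)) {
    stop_medkg("format", "malformed quintuple: empty or missing field(s) ",
               paste(need[!got], collapse = ", "))
  }

  rep <- data.frame(code = character(0), severity = character(0),
                    message = character(0), stringsAsFactors = FALSE)
  add <- function(code, severity, message) {
    rbind(rep, data.frame(code = code, severity = severity,
                          message = message, stringsAsFactors = FALSE))
  }

  cats <- schema_categories(schema)
  for (side in c("sub_type", "obj_type")) {
    if (length(cats) && !(canon(q[[side]]) %in% cats)) {
      rep <- add("unknown_category", "violation",
                 paste0("unknown category '", q[[side]], "' (", side, ")"))
    }
  }

  rels <- canon(schema$relations$relation)
  rel_known <- canon(q$rel) %in% rels ||
    (!is.null(q$rel_label) && !is.na(q$rel_label) &&
       canon(q$rel_label) %in% rels)
  if (length(rels) && !rel_known) {
    rep <- add("unknown_relation", "violation",
               paste0("unknown relation '", q$rel, "'"))
  }

  if (nrow(schema$pair_rules)) {
    sev <- if (strict) "violation" else "warning"
    hit <- canon(schema$pair_rules$subject_category) == canon(q$sub_type) &
      canon(schema$pair_rules$object_category) == canon(q$obj_type)
    if (!any(hit)) {
      rep <- add("unlisted_pair", sev, paste0(
        "no pair rule for (", q$sub_type, ", ", q$obj_type, ")"
      ))
    } else {
      allowed <- canon(unlist(schema$pair_rules$relations[hit]))
      ok <- canon(q$rel) %in% allowed ||
        (!is.null(q$rel_label) && !is.na(q$rel_label) &&
           canon(q$rel_label) %in% allowed)
      if (!ok) {
        rep <- add("pair_rule_violation", sev, paste0(
          "relation '", q$rel, "' not allowed for (",
          q$sub_type, ", ", q$obj_type, ")"
        ))
      }
    }
  }

  class(rep) <- c("validation_report", class(rep))
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("<validation_report> clean\n")
  } else {
    cat("<validation_report> ", sum(x$severity == "violation"),
        " violation(s), ", sum(x$severity == "warning"),
        " warning(s)\n", sep = "")
    print.data.frame(x)
  }
  invisible(x)
}
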