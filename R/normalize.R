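# Term standardization and dictionary-assisted segmentation.
#
# Two auxiliary lexicons — a drug pharmacopoeia and a disease codex —
# drive longest-match tokenization (so multiword clinical terms such
# as "acute myocardial infarction" survive as single tokens and are
# kept distinct from "myocardial infarction") and alias unification
# (different surface forms of one drug collapse onto a canonical
# term). Standardization rules implement five fixed rule kinds applied
# in a fixed order.

RULE_KINDS <- c("category_unification", "synonym",
                "expression_normalization", "reference_fill",
                "redundancy_simplification")

#' Read a lexicon from TSV
#'
#' Lexicon files have columns `term` and `alias_of`; rows with an empty
#' `alias_of` declare canonical terms, other rows declare aliases.
#' Alias chains (a -> b, b -> c) are resolved transitively at load
#' time; an alias cycle or an alias whose final target is not a
#' canonical term is an error.
#'
#' @param path TSV file path.
#' @param name Lexicon name (defaults to the file stem); used as the
#'   token source tag and for tie-breaking priority in
#'   [segment_text()].
#' @return A `lexicon` object: list with `name`, `terms` (canonical
#'   terms) and `aliases` (named character vector, alias -> canonical).
#' @examples
#' lex <- read_lexicon(medkg_extdata("pharmacopoeia.tsv"))
#' lex$name
#' @export
read_lexicon <- function(path, name = NULL) {
  df <- read_tsv_strict(path)
  require_columns(df, "term", "lexicon file")
  if (is.null(df$alias_of)) df$alias_of <- ""
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lexicon(terms = df$term[!nzchar(df$alias_of)],
          aliases = setNames(df$alias_of[nzchar(df$alias_of)],
                             df$term[nzchar(df$alias_of)]),
          name = name)
}

#' @rdname read_lexicon
#' @param terms Character vector of canonical terms.
#' @param aliases Named character vector (names are aliases, values
#'   their targets; targets may themselves be aliases and are resolved).
#' @export
lexicon <- function(terms, aliases = character(0), name = "lexicon") {
  terms <- unique(terms[nzchar(terms)])
  if (length(aliases)) {
    if (any(canon(names(aliases)) == canon(aliases))) {
      stop_medkg("format", "alias mapping to itself in lexicon '",
                 name, "'")
    }
    # transitive resolution with cycle detection
    resolve <- function(a) {
      seen <- character(0)
      cur <- a
      repeat {
        nxt <- aliases[match(canon(cur), canon(names(aliases)))]
        if (is.na(nxt)) return(cur)
        if (canon(nxt) %in% seen) {
          stop_medkg("format", "alias cycle involving '", a,
                     "' in lexicon '", name, "'")
        }
        seen <- c(seen, canon(cur))
        cur <- unname(nxt)
      }
    }
    aliases <- setNames(vapply(unname(aliases), resolve, character(1)),
                        names(aliases))
    bad <- !(canon(aliases) %in% canon(terms))
    if (any(bad)) {
      stop_medkg("format", "alias target(s) not canonical terms in '",
                 name, "': ", paste(unique(aliases[bad]), collapse = ", "))
    }
  }
  structure(list(name = name, terms = terms, aliases = aliases),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon '", x$name, "'> ", length(x$terms), " terms, ",
      length(x$aliases), " aliases\n", sep = "")
  invisible(x)
}

#' Write a lexicon back to TSV
#' @param lex A `lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  df <- data.frame(
    term = c(lex$terms, names(lex$aliases)),
    alias_of = c(rep("", length(lex$terms)), unname(lex$aliases)),
    stringsAsFactors = FALSE
  )
  write_tsv_strict(df, path)
}

#' The packaged drug pharmacopoeia and disease codex
#' @return A list of two `lexicon` objects, pharmacopoeia first (the
#'   priority order used for segmentation tie-breaks).
#' @export
bb_lexicons <- function() {
  list(
    read_lexicon(medkg_extdata("pharmacopoeia.tsv"), "pharmacopoeia"),
    read_lexicon(medkg_extdata("disease_codex.tsv"), "disease_codex")
  )
}

# standardization rules -------------------------------------------------

#' Load term-standardization rules from YAML
#'
#' The rule file holds a top-level `rules` list; each rule has `kind`
#' (one of the five fixed kinds), `pattern` (a source expression,
#' matched case-insensitively against the whole term) and
#' `replacement` (one or more standardized terms; more than one only
#' makes sense for `reference_fill`, which expands a conjunction like
#' "X or Y" into its filled-in members). Two rules of the same kind
#' with the same pattern but different replacements are a
#' configuration error.
#'
#' @param path YAML file path. The packaged default is
#'   `medkg_extdata("standardization_rules.yaml")`.
#' @return A `standardization_rules` object.
#' @export
read_standardization_rules <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- y$rules %||% y
  parsed <- lapply(rules, function(r) {
    if (is.null(r$kind) || !(r$kind %in% RULE_KINDS)) {
      stop_medkg("format", "unknown rule kind: ",
                 r$kind %||% "<missing>")
    }
    if (is.null(r$pattern) || !length(r$replacement)) {
      stop_medkg("format", "rule needs a pattern and a non-empty ",
                 "replacement")
    }
    list(kind = r$kind, pattern = as.character(r$pattern),
         replacement = as.character(unlist(r$replacement)))
  })
  key <- vapply(parsed, function(r) paste(r$kind, canon(r$pattern)),
                character(1))
  if (anyDuplicated(key)) {
    dups <- key[duplicated(key)]
    reps <- lapply(split(parsed, key), function(g) {
      unique(lapply(g, `[[`, "replacement"))
    })
    if (any(lengths(reps[unique(dups)]) > 1)) {
      stop_medkg("format", "conflicting rules for pattern(s): ",
                 paste(unique(dups), collapse = "; "))
    }
  }
  structure(list(rules = parsed), class = "standardization_rules")
}

#' Standardize a term
#'
#' Applies the five rule kinds in their fixed order (category
#' unification, synonym unification, expression normalization,
#' reference filling, redundancy simplification). A reference-fill rule
#' may expand one term into several; all other kinds map one term to
#' one. Unmatched input is returned unchanged, so the operation is
#' idempotent whenever replacements are themselves in standardized
#' form.
#'
#' @param term Non-empty input term.
#' @param rules A `standardization_rules` object.
#' @return Character vector of standardized terms (usually length 1).
#' @examples
#' rules <- read_standardization_rules(
#'   medkg_extdata("standardization_rules.yaml"))
#' standardize_term("ACE inhibitors", rules)
#' standardize_term("Intravenous beta-blockers or verapamil", rules)
#' @export
standardize_term <- function(term, rules) {
  stopifnot(inherits(rules, "standardization_rules"))
  if (!is.character(term) || length(term) != 1 || !nzchar(trimws(term))) {
    stop_medkg("format", "term must be a non-empty string")
  }
  out <- term
  for (kind in RULE_KINDS) {
    kr <- Filter(function(r) r$kind == kind, rules$rules)
    if (!length(kr)) next
    pats <- canon(vapply(kr, `[[`, character(1), "pattern"))
    out <- unlist(lapply(out, function(t) {
      i <- match(canon(t), pats)
      if (is.na(i)) t else kr[[i]]$replacement
    }), use.names = FALSE)
  }
  out
}

# segmentation ----------------------------------------------------------

is_cjk <- function(code) {
  (code >= 0x4E00 & code <= 0x9FFF) | (code >= 0x3400 & code <= 0x4DBF) |
    (code >= 0xF900 & code <= 0xFAFF) | (code >= 0x3040 & code <= 0x30FF)
}

is_word_char <- function(ch) grepl("^[[:alnum:]'_-]$", ch)

#' Dictionary-assisted longest-match segmentation
#'
#' Greedy left-to-right tokenization: at each position the longest
#' lexicon entry (term or alias) starting there becomes one token,
#' tagged with its source lexicon; length ties go to the earlier
#' lexicon in `lexicons` (the packaged order puts the pharmacopoeia
#' before the disease codex). Latin-script lexicon matches must sit on
#' word boundaries. Text not covered by any lexicon entry falls
#' through to plain tokens: runs of word characters, runs of
#' whitespace, single CJK characters, or single punctuation marks.
#' Concatenating the token texts always reproduces the input exactly.
#'
#' @param text Non-empty string.
#' @param lexicons List of `lexicon` objects (may be empty).
#' @return Data frame with columns `token`, `source` (lexicon name or
#'   `NA` for fallback tokens), `start` and `end` (1-based character
#'   positions, inclusive).
#' @examples
#' segment_text("propranolol treats acute myocardial infarction",
#'              bb_lexicons())
#' @export
segment_text <- function(text, lexicons = list()) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop_medkg("format", "text must be a non-empty string")
  }
  if (inherits(lexicons, "lexicon")) lexicons <- list(lexicons)
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  low <- tolower(chars)
  n <- length(chars)

  # flatten entries: surface form, lexicon tag, priority
  entries <- do.call(rbind, c(list(
    data.frame(surface = character(0), lex = character(0),
               prio = integer(0), stringsAsFactors = FALSE)),
    lapply(seq_along(lexicons), function(i) {
      lx <- lexicons[[i]]
      surf <- c(lx$terms, names(lx$aliases))
      if (!length(surf)) return(NULL)
      data.frame(surface = surf, lex = lx$name, prio = i,
                 stringsAsFactors = FALSE)
    })
  ))
  if (nrow(entries)) {
    entries$low <- tolower(entries$surface)
    entries$len <- nchar(entries$low)
    entries <- entries[order(-entries$len, entries$prio), , drop = FALSE]
  }

  boundary_ok <- function(from, to) {
    # Latin terms must not butt against adjacent word characters
    first <- chars[from]; last <- chars[to]
    pre_ok <- from == 1 || !is_word_char(chars[from - 1]) ||
      !is_word_char(first)
    post_ok <- to == n || !is_word_char(chars[to + 1]) ||
      !is_word_char(last)
    pre_ok && post_ok
  }

  toks <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    if (nrow(entries)) {
      rest <- paste(low[i:min(n, i + max(entries$len) - 1L)],
                    collapse = "")
      for (r in seq_len(nrow(entries))) {
        len <- entries$len[r]
        if (i + len - 1L > n) next
        if (substr(rest, 1L, len) == entries$low[r] &&
            boundary_ok(i, i + len - 1L)) {
          toks[[length(toks) + 1L]] <- data.frame(
            token = paste(chars[i:(i + len - 1L)], collapse = ""),
            source = entries$lex[r], start = i, end = i + len - 1L,
            stringsAsFactors = FALSE
          )
          i <- i + len
          matched <- TRUE
          break
        }
      }
    }
    if (matched) next
    ch <- chars[i]
    code <- utf8ToInt(ch)
    if (grepl("^[[:space:]]$", ch)) {
      j <- i
      while (j < n && grepl("^[[:space:]]$", chars[j + 1L])) j <- j + 1L
    } else if (is_cjk(code)) {
      j <- i
    } else if (is_word_char(ch)) {
      j <- i
      while (j < n && is_word_char(chars[j + 1L]) &&
             !is_cjk(utf8ToInt(chars[j + 1L]))) j <- j + 1L
    } else {
      j <- i
    }
    toks[[length(toks) + 1L]] <- data.frame(
      token = paste(chars[i:j], collapse = ""),
      source = NA_character_, start = i, end = j,
      stringsAsFactors = FALSE
    )
    i <- j + 1L
  }
  do.call(rbind, toks)
}

# alias merging ---------------------------------------------------------

#' Merge alias nodes onto their canonical terms
#'
#' Nodes whose names are lexicon aliases are renamed to their canonical
#' term; when a node of the same category already bears the canonical
#' name the two merge, with incident edges re-attached and parallel
#' edges coalescing by weight addition (total edge weight is
#' preserved). A rename whose canonical target exists only under a
#' different category is skipped and reported, never silently applied.
#'
#' @param graph A `property_graph`.
#' @param lexicons List of `lexicon` objects supplying alias maps.
#' @return The merged `property_graph`, with a `merge_report`
#'   attribute: data frame of (`from`, `to`, `category`, `action`)
#'   where action is `"merged"`, `"renamed"` or `"skipped"`.
#' @export
merge_aliases <- function(graph, lexicons) {
  stopifnot(inherits(graph, "property_graph"))
  if (inherits(lexicons, "lexicon")) lexicons <- list(lexicons)
  amap <- character(0)
  for (lx in lexicons) {
    keep <- !(canon(names(lx$aliases)) %in% canon(names(amap)))
    amap <- c(amap, setNames(unname(lx$aliases[keep]),
                             names(lx$aliases)[keep]))
  }
  report <- data.frame(from = character(0), to = character(0),
                       category = character(0), action = character(0),
                       stringsAsFactors = FALSE)
  if (!length(amap) || !nrow(graph$nodes)) {
    attr(graph, "merge_report") <- report
    return(graph)
  }

  nd <- graph$nodes
  target <- amap[match(canon(nd$name), canon(names(amap)))]
  new_name <- nd$name
  for (i in seq_len(nrow(nd))) {
    if (is.na(target[i])) next
    to <- unname(target[i])
    same_cat <- canon(nd$name) == canon(to) &
      canon(nd$category) == canon(nd$category[i])
    other_cat <- canon(nd$name) == canon(to) &
      canon(nd$category) != canon(nd$category[i])
    if (any(same_cat)) {
      action <- "merged"
    } else if (any(other_cat)) {
      report <- rbind(report, data.frame(
        from = nd$name[i], to = to, category = nd$category[i],
        action = "skipped", stringsAsFactors = FALSE
      ))
      next
    } else {
      action <- "renamed"
    }
    new_name[i] <- to
    report <- rbind(report, data.frame(
      from = nd$name[i], to = to, category = nd$category[i],
      action = action, stringsAsFactors = FALSE
    ))
  }

  # rebuild: expand edges to one row per supporting occurrence and
  # re-ingest under the new names, so coalesced weights add up
  ed <- graph$edges
  rows <- data.frame(
    sub = new_name[ed$start_node],
    sub_type = nd$category[ed$start_node],
    rel = ed$label, rel_label = ed$label_category,
    obj = new_name[ed$end_node],
    obj_type = nd$category[ed$end_node],
    stringsAsFactors = FALSE
  )
  rows <- rows[rep(seq_len(nrow(rows)), ed$weight), , drop = FALSE]
  rows$sub_attrs <- rep(list(list()), nrow(rows))
  rows$obj_attrs <- rep(list(list()), nrow(rows))
  merged <- ingest_quintuples(as_quintuples(rows))

  # carry node attributes over (aliases first so canonical wins)
  ord <- order(is.na(target))
  for (i in seq_len(nrow(nd))[ord]) {
    a <- graph$node_attrs[[i]]
    if (!length(a)) next
    ids <- which(canon(merged$nodes$name) == canon(new_name[i]) &
                   canon(merged$nodes$category) == canon(nd$category[i]))
    for (id in ids) {
      merged$node_attrs[[id]] <- utils::modifyList(
        merged$node_attrs[[id]], a
      )
    }
  }
  # isolated nodes carry over too (re-ingest only sees edge endpoints)
  touched <- unique(c(ed$start_node, ed$end_node))
  isolated <- setdiff(seq_len(nrow(nd)), touched)
  for (i in isolated) {
    key_hit <- canon(merged$nodes$name) == canon(new_name[i]) &
      canon(merged$nodes$category) == canon(nd$category[i])
    if (!any(key_hit)) {
      merged$nodes <- rbind(merged$nodes, data.frame(
        node_id = nrow(merged$nodes) + 1L, name = new_name[i],
        category = nd$category[i], first_edge = NA_integer_,
        last_edge = NA_integer_, stringsAsFactors = FALSE
      ))
      merged$node_attrs[[nrow(merged$nodes)]] <- graph$node_attrs[[i]]
    }
  }
  attr(merged, "merge_report") <- report
  merged
}
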