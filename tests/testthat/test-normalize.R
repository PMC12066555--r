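rules <- read_standardization_rules(
  medkg_extdata("standardization_rules.yaml"))

test_that("the five standardization rule kinds behave as documented", {
  # category unification: subdivided categories collapse to one
  expect_identical(standardize_term("Short-acting nitrates", rules),
                   "nitrate drugs")
  expect_identical(standardize_term("Long-acting nitrates", rules),
                   "nitrate drugs")
  # synonym unification, case-insensitive
  expect_identical(standardize_term("ACE inhibitors", rules), "ACEI")
  expect_identical(standardize_term("ace INHIBITORS", rules), "ACEI")
  expect_identical(
    standardize_term("angiotensin-converting enzyme inhibitors", rules),
    "ACEI")
  # expression normalization
  expect_identical(
    standardize_term("Research status of angina pectoris prognosis",
                     rules),
    "Angina pectoris prognosis study")
  # reference fill expands a conjunction into its members
  expect_identical(
    standardize_term("Intravenous beta-blockers or verapamil", rules),
    c("Intravenous beta-blockers", "Intravenous verapamil"))
  # redundancy simplification
  expect_identical(
    standardize_term("Complications related to hypertension", rules),
    "Hypertension complications")
  # unmatched terms pass through unchanged
  expect_identical(standardize_term("propranolol", rules),
                   "propranolol")
})

test_that("standardization is idempotent on its own outputs", {
  inputs <- c("Short-acting nitrates", "ACE inhibitors",
              "Intravenous beta-blockers or verapamil",
              "Complications related to hypertension", "propranolol")
  for (x in inputs) {
    once <- standardize_term(x, rules)
    twice <- unlist(lapply(once, standardize_term, rules = rules))
    expect_identical(twice, once)
  }
})

test_that("conflicting rules are a configuration error", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c(
    "rules:",
    "  - kind: synonym",
    "    pattern: \"ACE inhibitors\"",
    "    replacement: [\"ACEI\"]",
    "  - kind: synonym",
    "    pattern: \"ace inhibitors\"",
    "    replacement: [\"ACE-I\"]"
  ), tmp)
  expect_error(read_standardization_rules(tmp),
               class = "medkg_format_error")
  unlink(tmp)
})

test_that("unknown rule kinds and empty replacements are rejected", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("rules:",
               "  - kind: frobnication",
               "    pattern: \"x\"",
               "    replacement: [\"y\"]"), tmp)
  expect_error(read_standardization_rules(tmp),
               class = "medkg_format_error")
  unlink(tmp)
})

test_that("lexicons resolve alias chains and reject cycles", {
  lx <- lexicon(terms = "c", aliases = c(a = "b", b = "c"))
  expect_identical(unname(lx$aliases[["a"]]), "c")
  expect_identical(unname(lx$aliases[["b"]]), "c")
  expect_error(lexicon(terms = "z", aliases = c(a = "b", b = "a")),
               class = "medkg_format_error")
  expect_error(lexicon(terms = "z", aliases = c(a = "a")),
               class = "medkg_format_error")
  expect_error(lexicon(terms = "z", aliases = c(a = "nowhere")),
               class = "medkg_format_error")
})

test_that("lexicons round-trip through TSV", {
  lx <- bb_lexicons()[[1]]
  tmp <- tempfile(fileext = ".tsv")
  write_lexicon(lx, tmp)
  lx2 <- read_lexicon(tmp, name = lx$name)
  expect_setequal(lx2$terms, lx$terms)
  expect_identical(lx2$aliases[order(names(lx2$aliases))],
                   lx$aliases[order(names(lx$aliases))])
  unlink(tmp)
})

test_that("segmentation keeps multiword clinical terms whole", {
  lexs <- bb_lexicons()
  toks <- segment_text(
    "propranolol treats acute myocardial infarction", lexs)
  expect_true("propranolol" %in% toks$token)
  expect_true("acute myocardial infarction" %in% toks$token)
  # the longer codex entry wins over its substring
  expect_false("myocardial infarction" %in% toks$token)
  expect_identical(
    toks$source[toks$token == "acute myocardial infarction"],
    "disease_codex")
  # and aliases match too
  toks2 <- segment_text("high blood pressure after digoxin", lexs)
  expect_true("high blood pressure" %in% toks2$token)
})

test_that("lexicon matches respect word boundaries", {
  lexs <- bb_lexicons()
  toks <- segment_text("hypertensionx", lexs)
  expect_false("hypertension" %in% toks$token)
  expect_true(all(is.na(toks$source)))
})

test_that("segmentation covers the input exactly", {
  lexs <- bb_lexicons()
  texts <- c(
    "propranolol 10 mg, 3-4 times daily for hypertension",
    "β-receptor blockers improve bradycardia",
    "unknown words fall through to plain tokens",
    "混合 text with 高血压 characters",
    "  leading and trailing   spaces  "
  )
  for (tx in texts) {
    toks <- segment_text(tx, lexs)
    expect_identical(paste(toks$token, collapse = ""), tx)
    expect_identical(toks$start[1], 1L)
    expect_identical(toks$end[nrow(toks)], nchar(tx))
    # positions tile the string with no gaps or overlaps
    if (nrow(toks) > 1) {
      expect_identical(toks$start[-1], head(toks$end, -1) + 1L)
    }
    expect_identical(
      vapply(seq_len(nrow(toks)), function(i)
        substr(tx, toks$start[i], toks$end[i]), character(1)),
      toks$token)
  }
})

test_that("CJK characters segment one per token without a lexicon", {
  toks <- segment_text("高血压治疗", list())
  expect_identical(nrow(toks), 5L)
  expect_true(all(nchar(toks$token) == 1))
})

test_that("earlier lexicons win segmentation length ties", {
  a <- lexicon(terms = "shared term", name = "first")
  b <- lexicon(terms = "shared term", name = "second")
  toks <- segment_text("a shared term here", list(a, b))
  expect_identical(toks$source[toks$token == "shared term"], "first")
  toks2 <- segment_text("a shared term here", list(b, a))
  expect_identical(toks2$source[toks2$token == "shared term"], "second")
})

test_that("alias nodes merge onto canonical terms with weight addition", {
  g <- ingest_quintuples(rbind(
    quintuple("β-receptor blockers", "Drugs", "Indications",
              "hypertension", "Diseases"),
    quintuple("beta-blockers", "Drugs", "Indications",
              "hypertension", "Diseases"),
    quintuple("beta-blockers", "Drugs", "Indications",
              "hypertension", "Diseases")
  ))
  merged <- merge_aliases(g, bb_lexicons())
  expect_identical(length(find_nodes_by_name(merged, "β-receptor blockers")),
                   0L)
  expect_identical(
    edge_weight(merged, "beta-blockers", "Indications", "hypertension"),
    3L)
  rep <- attr(merged, "merge_report")
  expect_identical(rep$action[rep$from == "β-receptor blockers"],
                   "merged")
})

test_that("an alias with no existing canonical node is renamed", {
  g <- ingest_quintuples(
    quintuple("high blood pressure", "Diseases", "Treatment",
              "propranolol", "Drugs"))
  merged <- merge_aliases(g, bb_lexicons())
  expect_identical(length(find_nodes_by_name(merged, "hypertension")), 1L)
  rep <- attr(merged, "merge_report")
  expect_identical(rep$action, "renamed")
})

test_that("a cross-category canonical target is skipped and reported", {
  g <- ingest_quintuples(rbind(
    quintuple("high blood pressure", "Symptoms", "Shows",
              "dizziness", "Symptoms"),
    quintuple("propranolol", "Drugs", "Indications",
              "hypertension", "Diseases")
  ))
  merged <- merge_aliases(g, bb_lexicons())
  rep <- attr(merged, "merge_report")
  expect_identical(rep$action[rep$from == "high blood pressure"],
                   "skipped")
  # the alias node is untouched
  expect_identical(
    length(find_nodes_by_name(merged, "high blood pressure")), 1L)
  expect_true(graph_identical(g, merged))
})

test_that("merging with no applicable aliases is the identity", {
  g <- bb_fixture_graph("cmds")
  merged <- merge_aliases(g, list(lexicon(terms = "zzz")))
  expect_true(graph_identical(g, merged))
  expect_identical(nrow(attr(merged, "merge_report")), 0L)
})

test_that("node attributes survive merging, canonical node wins", {
  g <- ingest_quintuples(rbind(
    quintuple("β-blockers", "Drugs", "Indications", "x", "Diseases",
              sub_attrs = list(note = "from alias", extra = "kept")),
    quintuple("beta-blockers", "Drugs", "Indications", "y", "Diseases",
              sub_attrs = list(note = "from canonical"))
  ))
  merged <- merge_aliases(g, bb_lexicons())
  a <- node_attributes(merged, "beta-blockers", "Drugs")
  expect_identical(a$note, "from canonical")
  expect_identical(a$extra, "kept")
})

test_that("merged edge weight totals are conserved (property)", {
  check_merge_weight_conservation(40)
})

test_that("alias chains merge transitively, matching a union-find oracle", {
  for (s in 1:15) {
    q <- random_quintuples(n_nodes = 8, n_rows = 12, seed = 3000 + s,
                           cats = "Drugs")
    g <- ingest_quintuples(as_quintuples(q))
    nd <- graph_nodes(g)
    if (nrow(nd) < 4) next
    # chain: n[2] -> n[3] -> n[1] (so n[2] resolves through n[3])
    lx <- lexicon(terms = setdiff(nd$name, nd$name[2:3]),
                  aliases = setNames(c(nd$name[3], nd$name[1]),
                                     c(nd$name[2], nd$name[3])))
    merged <- merge_aliases(g, list(lx))
    closure <- union_find_closure(data.frame(
      from = nd$name[2:3], to = c(nd$name[3], nd$name[1]),
      stringsAsFactors = FALSE))
    reps <- unique(c(closure, setdiff(nd$name, names(closure))))
    got <- graph_nodes(merged)$name
    expect_setequal(got, setdiff(reps, setdiff(names(closure), reps)))
    expect_identical(sum(graph_edges(merged)$weight),
                     sum(graph_edges(g)$weight))
  }
})
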