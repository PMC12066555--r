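# Seeded synthetic knowledge-graph generator.
#
# Emits quintuple tables with planted, exactly recoverable reasoning
# patterns so every reasoning operation can be exercised without any
# external data. With zero background edges each planted pattern is
# recovered exactly by the corresponding operation; background edges
# add schema-conforming noise drawn over the packaged category-pair
# rules, among the background entity pools only — planted nodes live
# in their own namespace, so noise can never rewire a planted
# neighborhood and recoverability is guaranteed by construction.
# Output depends only on (seed, config): a single integer seed
# drives one RNG stream, snapshotted and restored around generation.

#' Planted-pattern constructors
#'
#' Each constructor describes one recoverable pattern for
#' [generate_synth_kg()]:
#' * `plant_multi_use()`: a drug linked to `n_diseases` diseases at
#'   hop depth `depth` (depth 1 is a direct indication edge; deeper
#'   patterns route through a chain of attribute-ontology nodes).
#' * `plant_synergy()`: a disease linked to a drug-combination node of
#'   `n_drugs` member drugs with `weight_boost` supporting rows, plus
#'   a weight-1 decoy combination.
#' * `plant_dosage_tree()`: a drug with an indication whose dosing
#'   node carries `attributes`.
#' * `plant_intersection()`: two symptoms sharing a node that links to
#'   a unified-treatment drug.
#' * `plant_stage_chain()`: `length` stages in a Stage chain, each
#'   with `n_treatments` attached treatment nodes.
#'
#' @param n_diseases,depth,n_drugs,weight_boost,attributes,length,n_treatments
#'   Pattern parameters, see above.
#' @return A pattern spec (list) for the `planted` field of
#'   [synth_config()].
#' @name planted_patterns
NULL

#' @rdname planted_patterns
#' @export
plant_multi_use <- function(n_diseases = 3, depth = 1) {
  if (depth < 1) stop_medkg("config", "multi_use depth must be >= 1")
  if (n_diseases < 1) stop_medkg("config", "multi_use needs >= 1 disease")
  list(type = "multi_use", n_diseases = n_diseases, depth = depth)
}

#' @rdname planted_patterns
#' @export
plant_synergy <- function(n_drugs = 3, weight_boost = 5) {
  if (n_drugs < 2) stop_medkg("config", "synergy needs >= 2 drugs")
  if (weight_boost < 1) stop_medkg("config", "weight_boost must be >= 1")
  list(type = "synergy", n_drugs = n_drugs, weight_boost = weight_boost)
}

#' @rdname planted_patterns
#' @export
plant_dosage_tree <- function(attributes = list(
                                initial_dose = "10 mg",
                                max_dose = "200 mg",
                                frequency = "3-4 times daily")) {
  if (!length(attributes)) {
    stop_medkg("config", "dosage_tree needs attributes")
  }
  list(type = "dosage_tree", attributes = attributes)
}

#' @rdname planted_patterns
#' @export
plant_intersection <- function() list(type = "intersection")

#' @rdname planted_patterns
#' @export
plant_stage_chain <- function(length = 3, n_treatments = 1) {
  if (length < 1) stop_medkg("config", "stage chain length must be >= 1")
  list(type = "stage_chain", length = length,
       n_treatments = n_treatments)
}

#' Synthetic-graph configuration
#'
#' @param seed Integer seed; together with the remaining fields it
#'   fully determines the output.
#' @param n_drugs,n_diseases,n_symptoms,n_amts Sizes of the background
#'   entity pools.
#' @param n_background_edges Number of schema-conforming noise edges.
#' @param planted List of pattern specs (see [planted_patterns]).
#' @return A `synth_config` object.
#' @export
synth_config <- function(seed, n_drugs = 10, n_diseases = 8,
                         n_symptoms = 6, n_amts = 5,
                         n_background_edges = 0, planted = list()) {
  counts <- c(n_drugs, n_diseases, n_symptoms, n_amts,
              n_background_edges)
  if (any(counts < 0)) stop_medkg("config", "counts must be >= 0")
  for (p in planted) {
    if (is.null(p$type) ||
        !p$type %in% c("multi_use", "synergy", "dosage_tree",
                       "intersection", "stage_chain")) {
      stop_medkg("config", "unknown planted pattern type")
    }
  }
  structure(
    list(seed = as.integer(seed), n_drugs = n_drugs,
         n_diseases = n_diseases, n_symptoms = n_symptoms,
         n_amts = n_amts, n_background_edges = n_background_edges,
         planted = planted),
    class = "synth_config"
  )
}

pad3 <- function(i) formatC(i, width = 3, flag = "0")

#' Generate a synthetic knowledge graph with planted patterns
#'
#' @param config A `synth_config`.
#' @param schema Ontology schema constraining background edges;
#'   defaults to the packaged schema, so emitted quintuples always
#'   pass non-strict validation.
#' @return List with `quintuples` (a `quintuple_tbl`) and `truth`
#'   (per-pattern expected answers: disease sets, combination drug
#'   sets, dosing attributes, shared nodes, stage order).
#' @examples
#' out <- generate_synth_kg(synth_config(1, planted = list(
#'   plant_multi_use(n_diseases = 4, depth = 2))))
#' out$truth$multi_use[[1]]$diseases
#' @export
generate_synth_kg <- function(config, schema = bb_schema()) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  rows <- list()
  emit <- function(sub, sub_type, rel, obj, obj_type,
                   rel_label = rel, times = 1,
                   sub_attrs = list(), obj_attrs = list()) {
    for (k in seq_len(times)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sub = sub, sub_type = sub_type, rel = rel,
        rel_label = rel_label, obj = obj, obj_type = obj_type,
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$sub_attrs <<- list(sub_attrs)
      rows[[length(rows)]]$obj_attrs <<- list(obj_attrs)
    }
  }

  truth <- list(multi_use = list(), synergy = list(),
                dosage_tree = list(), intersection = list(),
                stage_chain = list())

  # background entity pools, by category
  pools <- list(
    "Drugs" = paste0("drug_", pad3(seq_len(max(1, config$n_drugs)))),
    "Diseases" = paste0("disease_",
                        pad3(seq_len(max(1, config$n_diseases)))),
    "Symptoms" = paste0("symptom_",
                        pad3(seq_len(max(1, config$n_symptoms)))),
    "AMT" = paste0("amt_", pad3(seq_len(max(1, config$n_amts)))),
    "MT" = paste0("mt_", pad3(1:2)),
    "Patients" = paste0("patient_", pad3(1:2)),
    "Drug combinations" = paste0("combo_", pad3(1:3)),
    "Drug effects" = paste0("effect_", pad3(1:3)),
    "Drug characteristics" = paste0("characteristic_", pad3(1:2)),
    "Drug categories" = paste0("category_", pad3(1:2)),
    "Treatment methods" = paste0("treatment_", pad3(1:3)),
    "Disease stages" = paste0("stage_", pad3(1:3))
  )

  pat_i <- 0L
  for (p in config$planted) {
    pat_i <- pat_i + 1L
    tag <- paste0("p", pat_i)
    if (p$type == "multi_use") {
      drug <- paste0(tag, "_drug")
      diseases <- paste0(tag, "_disease_", pad3(seq_len(p$n_diseases)))
      chain <- if (p$depth > 1) {
        paste0(tag, "_amt_", pad3(seq_len(p$depth - 1L)))
      } else {
        character(0)
      }
      prev <- drug; prev_t <- "Drugs"
      for (a in chain) {
        emit(prev, prev_t, "AT", a, "AMT")
        prev <- a; prev_t <- "AMT"
      }
      for (d in diseases) {
        emit(prev, prev_t, "Indications", d, "Diseases")
      }
      truth$multi_use[[length(truth$multi_use) + 1L]] <-
        list(drug = drug, diseases = diseases, depth = p$depth)
    } else if (p$type == "synergy") {
      disease <- paste0(tag, "_disease")
      combo <- paste0(tag, "_combo")
      drugs <- paste0(tag, "_drug_", pad3(seq_len(p$n_drugs)))
      decoy <- paste0(tag, "_decoy_combo")
      decoy_drug <- paste0(tag, "_decoy_drug")
      emit(disease, "Diseases", "The combined effect is better than",
           combo, "Drug combinations",
           rel_label = "Combination medication",
           times = p$weight_boost)
      for (d in drugs) {
        emit(combo, "Drug combinations", "Drug combination", d, "Drugs")
      }
      emit(disease, "Diseases", "Treatment", decoy,
           "Drug combinations", rel_label = "Treatment")
      emit(decoy, "Drug combinations", "Drug combination", decoy_drug,
           "Drugs")
      truth$synergy[[length(truth$synergy) + 1L]] <-
        list(disease = disease, combination = combo,
             drugs = sort(drugs), weight = p$weight_boost)
    } else if (p$type == "dosage_tree") {
      drug <- paste0(tag, "_drug")
      disease <- paste0(tag, "_indication")
      dosing <- paste0(tag, "_dosing")
      emit(drug, "Drugs", "Indications", disease, "Diseases",
           times = 2)
      emit(disease, "Diseases", "Description", dosing,
           "Drug applications", obj_attrs = p$attributes)
      truth$dosage_tree[[length(truth$dosage_tree) + 1L]] <-
        list(drug = drug, indication = disease,
             attributes = p$attributes)
    } else if (p$type == "intersection") {
      s1 <- paste0(tag, "_symptom_a")
      s2 <- paste0(tag, "_symptom_b")
      shared <- paste0(tag, "_shared")
      treat <- paste0(tag, "_treatment_drug")
      emit(s1, "Symptoms", "Shows", shared, "Symptoms")
      emit(s2, "Symptoms", "Shows", shared, "Symptoms")
      emit(treat, "Drugs", "Improves", shared, "Symptoms")
      truth$intersection[[length(truth$intersection) + 1L]] <-
        list(symptoms = c(s1, s2), shared = shared, unified = treat)
    } else if (p$type == "stage_chain") {
      stages <- paste0(tag, "_stage_", pad3(seq_len(p$length)))
      treatments <- list()
      for (i in seq_len(p$length)) {
        if (i > 1) {
          emit(stages[i - 1], "Disease stages", "Stage", stages[i],
               "Disease stages")
        }
        tr <- if (p$n_treatments > 0) {
          paste0(tag, "_treatment_", pad3(i), "_",
                 seq_len(p$n_treatments))
        } else {
          character(0)
        }
        for (t in tr) {
          emit(stages[i], "Disease stages", "Treatment", t,
               "Treatment methods")
        }
        treatments[[stages[i]]] <- tr
      }
      if (p$length == 1) {
        # a singleton chain still needs its node in the graph
        emit(stages[1], "Disease stages", "Treatment",
             paste0(tag, "_treatment_001_1"), "Treatment methods")
        treatments[[stages[1]]] <-
          unique(c(treatments[[stages[1]]],
                   paste0(tag, "_treatment_001_1")))
      }
      truth$stage_chain[[length(truth$stage_chain) + 1L]] <-
        list(stages = stages, treatments = treatments)
    }
  }

  # background noise over schema-allowed category pairs
  pr <- schema$pair_rules
  usable <- which(canon(pr$subject_category) %in% canon(names(pools)) &
                    canon(pr$object_category) %in% canon(names(pools)))
  if (config$n_background_edges > 0 && !length(usable)) {
    stop_medkg("config", "no usable category pair for background edges")
  }
  pool_of <- function(cat) {
    pools[[match(canon(cat), canon(names(pools)))]]
  }
  for (k in seq_len(config$n_background_edges)) {
    r <- usable[sample.int(length(usable), 1)]
    sub_pool <- pool_of(pr$subject_category[r])
    obj_pool <- pool_of(pr$object_category[r])
    rels <- pr$relations[[r]]
    emit(sub_pool[sample.int(length(sub_pool), 1)],
         pr$subject_category[r],
         rels[sample.int(length(rels), 1)],
         obj_pool[sample.int(length(obj_pool), 1)],
         pr$object_category[r])
  }

  q <- if (length(rows)) {
    as_quintuples(do.call(rbind, rows))
  } else {
    empty <- data.frame(sub = character(0), sub_type = character(0),
                        rel = character(0), rel_label = character(0),
                        obj = character(0), obj_type = character(0),
                        stringsAsFactors = FALSE)
    empty$sub_attrs <- list(); empty$obj_attrs <- list()
    as_quintuples(empty)
  }
  list(quintuples = q, truth = truth)
}
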