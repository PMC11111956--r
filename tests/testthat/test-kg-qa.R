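# toy knowledge graph around pulmonary embolism, mirroring the published
# subgraph: five symptoms attached via DIS plus some unrelated edges
pe_triples <- function() {
  sym <- c("chest pain", "shortness of breath", "hemoptysis",
           "respiratory failure", "cough")
  rbind(
    data.frame(sub_surface = "pulmonary embolism", sub_type = "Disease",
               relation = "DIS", obj_surface = sym, obj_type = "Symptom",
               stringsAsFactors = FALSE),
    data.frame(sub_surface = "anticoagulant", sub_type = "Drug",
               relation = "DrAD", obj_surface = "pulmonary embolism",
               obj_type = "Disease", stringsAsFactors = FALSE),
    data.frame(sub_surface = "CT pulmonary angiography",
               sub_type = "Test", relation = "TeRD",
               obj_surface = "pulmonary embolism", obj_type = "Disease",
               stringsAsFactors = FALSE))
}

test_that("knowledge graph deduplicates nodes and counts edge support", {
  kg0 <- build_kg(NULL)
  expect_equal(nrow(kg0$nodes), 0)
  expect_equal(nrow(kg0$edges), 0)
  one <- data.frame(sub_surface = "x", sub_type = "Disease",
                    relation = "DIS", obj_surface = "y",
                    obj_type = "Symptom", stringsAsFactors = FALSE)
  kg2 <- build_kg(rbind(one, one))
  expect_equal(nrow(kg2$nodes), 2)
  expect_equal(nrow(kg2$edges), 1)
  expect_equal(kg2$edges$support, 2L)
  # same surface under two types stays two nodes
  two <- rbind(one,
               data.frame(sub_surface = "x", sub_type = "Factor",
                          relation = "FCS", obj_surface = "y",
                          obj_type = "Symptom", stringsAsFactors = FALSE))
  expect_equal(nrow(build_kg(two)$nodes), 3)
})

test_that("node and edge counts match a set-based oracle on 500 triples", {
  corp <- generate_corpus(generator_config(400, seed = 99,
                                           p_multi_object = 0.4))
  tr <- corpus_triples(corp)
  tr <- tr[seq_len(min(500, nrow(tr))), ]
  kg <- build_kg(tr)
  node_oracle <- unique(c(paste(tr$sub_surface, tr$sub_type, sep = "\r"),
                          paste(tr$obj_surface, tr$obj_type, sep = "\r")))
  edge_oracle <- unique(paste(tr$sub_surface, tr$sub_type, tr$relation,
                              tr$obj_surface, tr$obj_type, sep = "\r"))
  expect_equal(nrow(kg$nodes), length(node_oracle))
  expect_equal(nrow(kg$edges), length(edge_oracle))
  expect_equal(sum(kg$edges$support), nrow(tr))
  # idempotence on deduplicated input
  kg2 <- build_kg(unique(tr))
  expect_equal(kg2$nodes, kg$nodes)
  expect_equal(kg2$edges[, c("source_id", "target_id", "relation")],
               kg$edges[, c("source_id", "target_id", "relation")])
})

test_that("CSV export round-trips and the worked example yields 3 nodes, 2 edges", {
  kg <- build_kg(corpus_triples(list(worked_example_fixture()$sentence)))
  expect_equal(nrow(kg$nodes), 3)
  expect_equal(nrow(kg$edges), 2)
  td <- tempfile()
  export_kg_csv(kg, td)
  back <- read_kg_csv(td)
  expect_equal(back$nodes, kg$nodes)
  expect_equal(back$edges, kg$edges)
  # empty graph -> header-only files
  td2 <- tempfile()
  export_kg_csv(build_kg(NULL), td2)
  expect_length(readLines(file.path(td2, "nodes.csv")), 1)
  expect_length(readLines(file.path(td2, "edges.csv")), 1)
  empty_back <- read_kg_csv(td2)
  expect_equal(nrow(empty_back$nodes), 0)
  expect_equal(nrow(empty_back$edges), 0)
})

test_that("node ids are stable across insertion orders", {
  tr <- pe_triples()
  kg1 <- build_kg(tr)
  kg2 <- build_kg(tr[rev(seq_len(nrow(tr))), ])
  expect_equal(kg1$nodes, kg2$nodes)
  expect_equal(kg1$edges, kg2$edges)
})

test_that("the symptom question returns the five published manifestations", {
  rules <- load_question_rules()
  kg <- build_kg(pe_triples())
  res <- answer_question("What are the symptoms of pulmonary embolism?",
                         kg, rules)
  expect_true(res$ok)
  expect_equal(res$category, "DIS")
  expect_equal(res$entity, "pulmonary embolism")
  expect_setequal(res$answers,
                  c("chest pain", "shortness of breath", "hemoptysis",
                    "respiratory failure", "cough"))
  expect_match(res$answer, "^Clinical manifestations of pulmonary embolism")
  expect_match(res$query, "MATCH .*DIS")
})

test_that("unanswerable questions yield structured refusals, not errors", {
  rules <- load_question_rules()
  kg <- build_kg(pe_triples())
  no_ent <- answer_question("What are the symptoms of influenza?", kg, rules)
  expect_false(no_ent$ok)
  expect_match(no_ent$answer, "no known entity")
  no_cat <- answer_question("Tell me about pulmonary embolism.", kg, rules)
  expect_false(no_cat$ok)
  expect_match(no_cat$answer, "no feature word")
  no_fact <- answer_question("What drug is used for chest pain?", kg, rules)
  expect_false(no_fact$ok)
  expect_equal(no_fact$category, "DrAD")
  empty <- answer_question("anything", build_kg(NULL), rules)
  expect_false(empty$ok)
})

test_that("every question category is answerable over a one-edge-per-relation graph", {
  sc <- default_vte_schema()
  rules <- load_question_rules()
  # one edge per relation type with distinctive surfaces
  tr <- do.call(rbind, lapply(sc$relation_types, function(r) {
    sig <- sc$relation_signature[[r]]
    data.frame(sub_surface = paste0("sub-", r), sub_type = sig[1],
               relation = r, obj_surface = paste0("obj-", r),
               obj_type = sig[2], stringsAsFactors = FALSE)
  }))
  kg <- build_kg(tr)
  questions <- c(
    TrAD = "What is the treatment for obj-TrAD?",
    TrAS = "What can relieve obj-TrAS?",
    TeRD = "Which test can confirm obj-TeRD?",
    TeBD = "Which test should be undergone for obj-TeBD?",
    TeRS = "Which test can reveal obj-TeRS?",
    TeAS = "Which examination is taken because of obj-TeAS?",
    DIS  = "What are the symptoms of sub-DIS?",
    SDD  = "What disease does sub-SDD indicate?",
    FCS  = "What discomfort does sub-FCS cause?",
    DrAD = "Which drug is used for obj-DrAD?",
    DrAS = "Which medication eases obj-DrAS?",
    DrTr = "Which drug is prescribed as part of obj-DrTr?",
    DM   = "What precautions apply to sub-DM?",
    SM   = "What advice is given for sub-SM?")
  expect_setequal(names(questions), sc$relation_types)
  for (r in sc$relation_types) {
    res <- answer_question(questions[[r]], kg, rules)
    expect_true(res$ok, label = paste("category", r, "answerable"))
    expect_equal(res$category, r)
    expected <- if (grepl(paste0("sub-", r), questions[[r]], fixed = TRUE))
      paste0("obj-", r) else paste0("sub-", r)
    expect_equal(res$answers, expected)
  }
})

test_that("rules must cover the schema exactly once with nonempty features", {
  expect_s3_class(load_question_rules(), "question_rules")
  tf <- tempfile(fileext = ".yaml")
  writeLines("- relation: DIS\n  features: [symptom]\n  direction: subject\n  template: 'x'",
             tf)
  expect_error(load_question_rules(tf), "cover each schema relation")
})
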