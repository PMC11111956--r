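#' Load question-classification rules
#'
#' One rule per relation type (14 for the default schema). Each rule holds
#' the feature words that trigger its category, the direction of the lookup
#' (whether the entity mentioned in the question is the subject or the
#' object of the relation), and an answer template with `{entity}` and
#' `{answers}` slots. The shipped defaults (`qa_rules.yaml`, English plus a
#' few Chinese feature words) are configuration, not code: replace the file
#' to retarget the classifier. Rule order defines matching precedence.
#'
#' @param path YAML rules file; default: the file shipped with the package.
#' @param schema Schema the rules must cover.
#' @return List of rules (class `question_rules`).
#' @export
load_question_rules <- function(path = system.file("extdata",
                                                   "qa_rules.yaml",
                                                   package = "tripletag"),
                                schema = default_vte_schema()) {
  rules <- yaml::read_yaml(path)
  rels <- vapply(rules, function(r) r$relation, character(1))
  if (!setequal(rels, schema$relation_types) || anyDuplicated(rels))
    stop("rules must cover each schema relation type exactly once")
  for (r in rules) {
    if (!length(r$features) || !all(nzchar(r$features)))
      stop("rule ", r$relation, " has an empty feature-word list")
    if (!r$direction %in% c("subject", "object"))
      stop("rule ", r$relation, " direction must be subject or object")
  }
  structure(rules, class = "question_rules")
}

#' Answer a template question over a knowledge graph
#'
#' The pipeline mirrors a template question-answering front end over a graph
#' database: (1) entity linking by longest dictionary match of node surfaces
#' against the question; (2) question classification by the first rule whose
#' feature word occurs in the question (case-insensitive); (3) neighbor
#' lookup along the rule's relation in the rule's direction; (4) answer
#' generation from the rule's template. The equivalent graph-query (Cypher)
#' text is emitted for auditability but executed against the in-memory
#' graph, keeping the pipeline self-contained. Failure to link an entity or
#' classify the question yields a structured cannot-answer result, never an
#' error.
#'
#' @param question Question string.
#' @param kg A `knowledge_graph`.
#' @param rules A `question_rules` list.
#' @return List with `ok`, `answer` (string), `category`, `entity`,
#'   `answers` (character vector of answer surfaces, sorted), `query`
#'   (graph-query text).
#' @export
answer_question <- function(question, kg, rules) {
  cannot <- function(reason) list(ok = FALSE,
                                  answer = paste0("Cannot answer: ", reason),
                                  category = NA_character_,
                                  entity = NA_character_,
                                  answers = character(),
                                  query = NA_character_)
  if (!nrow(kg$nodes)) return(cannot("the knowledge graph is empty"))
  ql <- tolower(question)
  surfaces <- unique(kg$nodes$surface)
  hit <- surfaces[vapply(surfaces, function(s)
    grepl(tolower(s), ql, fixed = TRUE), logical(1))]
  if (!length(hit)) return(cannot("no known entity found in the question"))
  hit <- hit[order(-nchar(hit), hit)][1]
  rule <- NULL
  for (r in rules) {
    if (any(vapply(r$features, function(fw)
      grepl(tolower(fw), ql, fixed = TRUE), logical(1)))) {
      rule <- r
      break
    }
  }
  if (is.null(rule))
    return(cannot("no feature word matched a question category"))
  ids <- kg$nodes$id[kg$nodes$surface == hit]
  if (rule$direction == "subject") {
    sel <- kg$edges$relation == rule$relation & kg$edges$source_id %in% ids
    ans_ids <- kg$edges$target_id[sel]
    query <- sprintf(
      "MATCH (a {surface: '%s'})-[:%s]->(b) RETURN b.surface",
      hit, rule$relation)
  } else {
    sel <- kg$edges$relation == rule$relation & kg$edges$target_id %in% ids
    ans_ids <- kg$edges$source_id[sel]
    query <- sprintf(
      "MATCH (b)-[:%s]->(a {surface: '%s'}) RETURN b.surface",
      rule$relation, hit)
  }
  answers <- sort(unique(kg$nodes$surface[match(ans_ids, kg$nodes$id)]))
  if (!length(answers)) {
    out <- cannot(paste0("no ", rule$relation, " facts recorded for '",
                         hit, "'"))
    out$category <- rule$relation
    out$entity <- hit
    out$query <- query
    return(out)
  }
  text <- rule$template
  text <- gsub("{entity}", hit, text, fixed = TRUE)
  text <- gsub("{answers}", .join_answers(answers), text, fixed = TRUE)
  list(ok = TRUE, answer = text, category = rule$relation, entity = hit,
       answers = answers, query = query)
}

.join_answers <- function(x) {
  if (length(x) == 1L) return(x)
  paste0(paste(x[-length(x)], collapse = ", "), ", and ", x[length(x)])
}
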