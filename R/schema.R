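#' Define an annotation schema
#'
#' A schema is the closed inventory of entity types and relation types used
#' by a corpus, together with the signature of each relation: which entity
#' type acts as subject and which as object.
#'
#' @param entity_types Character vector of unique, non-empty entity-type
#'   symbols.
#' @param relation_types Character vector of unique, non-empty relation-type
#'   symbols.
#' @param relation_signature Named list mapping each relation type to a
#'   length-2 character vector `c(subject_type, object_type)`; both must be
#'   declared entity types.
#' @return An object of class `re_schema`.
#' @seealso [default_vte_schema()]
#' @export
re_schema <- function(entity_types, relation_types, relation_signature) {
  stopifnot(is.character(entity_types), is.character(relation_types))
  if (anyDuplicated(entity_types) || any(!nzchar(entity_types)))
    stop("entity types must be unique non-empty strings")
  if (anyDuplicated(relation_types) || any(!nzchar(relation_types)))
    stop("relation types must be unique non-empty strings")
  if (!setequal(names(relation_signature), relation_types))
    stop("relation_signature must have exactly one entry per relation type")
  for (r in relation_types) {
    sig <- relation_signature[[r]]
    if (length(sig) != 2L || !all(sig %in% entity_types))
      stop("signature of ", r, " must be two declared entity types")
  }
  structure(
    list(
      entity_types = entity_types,
      relation_types = relation_types,
      relation_signature = relation_signature[relation_types]
    ),
    class = "re_schema"
  )
}

#' @export
print.re_schema <- function(x, ...) {
  cat("<re_schema> ", length(x$entity_types), " entity types, ",
      length(x$relation_types), " relation types\n", sep = "")
  cat("  entities:  ", paste(x$entity_types, collapse = ", "), "\n", sep = "")
  sig <- vapply(x$relation_types, function(r)
    paste0(r, " (", x$relation_signature[[r]][1], " -> ",
           x$relation_signature[[r]][2], ")"), character(1))
  cat("  relations: ", paste(sig, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The default VTE annotation schema
#'
#' The venous-thromboembolism (VTE) clinical schema: 7 entity types
#' (Disease, Symptom, Drug, Factor, Treatment, Test, Matter) and 14 relation
#' types, each with a fixed (subject type, object type) signature. For
#' example `DIS` links a Disease subject to a Symptom object ("the disease
#' causes symptoms") and `TrAD` links a Treatment to the Disease it treats.
#'
#' @return An `re_schema` with 7 entity types and 14 relation types.
#' @export
default_vte_schema <- function() {
  re_schema(
    entity_types = c("Disease", "Symptom", "Drug", "Factor",
                     "Treatment", "Test", "Matter"),
    relation_types = c("TrAD", "TrAS", "TeRD", "TeBD", "TeRS", "TeAS",
                       "DIS", "SDD", "FCS", "DrAD", "DrAS", "DrTr",
                       "DM", "SM"),
    relation_signature = list(
      TrAD = c("Treatment", "Disease"),
      TrAS = c("Treatment", "Symptom"),
      TeRD = c("Test", "Disease"),
      TeBD = c("Test", "Disease"),
      TeRS = c("Test", "Symptom"),
      TeAS = c("Test", "Symptom"),
      DIS  = c("Disease", "Symptom"),
      SDD  = c("Symptom", "Disease"),
      FCS  = c("Factor", "Symptom"),
      DrAD = c("Drug", "Disease"),
      DrAS = c("Drug", "Symptom"),
      DrTr = c("Drug", "Treatment"),
      DM   = c("Disease", "Matter"),
      SM   = c("Symptom", "Matter")
    )
  )
}

#' Construct an annotated sentence
#'
#' Tokens are single characters (character-level tokenization, the standard
#' choice for Chinese clinical text; ASCII corpora are tokenized the same
#' way so fixtures stay language-agnostic). Spans are 0-based and inclusive
#' on both ends, matching the (head, tail) cell indexing of the token-pair
#' matrices. Triples reference entities by 1-based index into `entities`.
#'
#' @param tokens Character vector of tokens, or a single string to be split
#'   into characters.
#' @param entities Data frame with columns `start`, `end` (0-based inclusive
#'   token indices), `type`; a `surface` column is filled in from the tokens
#'   if absent.
#' @param triples Data frame with columns `sub`, `relation`, `obj` where
#'   `sub`/`obj` are row indices into `entities`.
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(tokens, entities = NULL, triples = NULL) {
  if (length(tokens) == 1L && nchar(tokens) > 1L)
    tokens <- strsplit(tokens, "", fixed = TRUE)[[1]]
  tokens <- as.character(tokens)
  if (is.null(entities))
    entities <- data.frame(start = integer(), end = integer(),
                           type = character(), surface = character(),
                           stringsAsFactors = FALSE)
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  if (is.null(entities$surface) && nrow(entities) > 0)
    entities$surface <- vapply(seq_len(nrow(entities)), function(i)
      paste(tokens[(entities$start[i] + 1L):(entities$end[i] + 1L)],
            collapse = ""), character(1))
  if (is.null(entities$surface)) entities$surface <- character()
  if (is.null(triples))
    triples <- data.frame(sub = integer(), relation = character(),
                          obj = integer(), stringsAsFactors = FALSE)
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  structure(list(tokens = tokens, entities = entities, triples = triples),
            class = "annotated_sentence")
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("<annotated_sentence> \"", paste(x$tokens, collapse = ""), "\" (",
      length(x$tokens), " tokens, ", nrow(x$entities), " entities, ",
      nrow(x$triples), " triples)\n", sep = "")
  invisible(x)
}

#' Validate a sentence against a schema
#'
#' Checks span bounds, surface/token agreement, entity and relation type
#' membership, triple references, and sentence length. Relation-signature
#' consistency (subject/object entity types matching the schema signature)
#' is controlled by `signature`: annotations that violate signatures are
#' warned about by default rather than rejected, since real corpora may
#' contain them.
#'
#' @param sentence An `annotated_sentence`.
#' @param schema An `re_schema`.
#' @param max_len Maximum allowed sentence length in tokens.
#' @param signature One of `"warn"` (default), `"enforce"`, `"ignore"`.
#' @return Invisibly `TRUE`; stops with a descriptive error on violation.
#' @export
validate_sentence <- function(sentence, schema, max_len = 256L,
                              signature = c("warn", "enforce", "ignore")) {
  signature <- match.arg(signature)
  s <- length(sentence$tokens)
  if (s < 1L) stop("sentence has no tokens")
  if (s > max_len) stop("sentence length ", s, " exceeds max_len ", max_len)
  ent <- sentence$entities
  if (nrow(ent) > 0) {
    ok <- ent$start >= 0L & ent$start <= ent$end & ent$end < s
    if (!all(ok))
      stop("entity span out of bounds: rows ",
           paste(which(!ok), collapse = ", "),
           " (sentence length ", s, ")")
    if (!all(ent$type %in% schema$entity_types))
      stop("unknown entity type(s): ",
           paste(unique(setdiff(ent$type, schema$entity_types)),
                 collapse = ", "))
    surf <- vapply(seq_len(nrow(ent)), function(i)
      paste(sentence$tokens[(ent$start[i] + 1L):(ent$end[i] + 1L)],
            collapse = ""), character(1))
    if (!all(surf == ent$surface))
      stop("entity surface does not match tokens at rows ",
           paste(which(surf != ent$surface), collapse = ", "))
  }
  tri <- sentence$triples
  if (nrow(tri) > 0) {
    if (!all(tri$relation %in% schema$relation_types))
      stop("unknown relation type(s): ",
           paste(unique(setdiff(tri$relation, schema$relation_types)),
                 collapse = ", "))
    if (!all(tri$sub >= 1L & tri$sub <= nrow(ent) &
             tri$obj >= 1L & tri$obj <= nrow(ent)))
      stop("triple references an entity index out of range")
    if (signature != "ignore") {
      for (i in seq_len(nrow(tri))) {
        sig <- schema$relation_signature[[tri$relation[i]]]
        got <- c(ent$type[tri$sub[i]], ent$type[tri$obj[i]])
        if (!identical(sig, got)) {
          msg <- paste0("triple ", i, " (", tri$relation[i],
                        ") has types (", got[1], ", ", got[2],
                        "), signature expects (", sig[1], ", ", sig[2], ")")
          if (signature == "enforce") stop(msg) else warning(msg)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Expand a sentence's triples to full span records
#'
#' Resolves the entity indices of each triple into explicit subject/object
#' span fields, the form used by evaluation and knowledge-graph building.
#'
#' @param sentence An `annotated_sentence`.
#' @return Data frame with columns `sub_start`, `sub_end`, `sub_type`,
#'   `sub_surface`, `relation`, `obj_start`, `obj_end`, `obj_type`,
#'   `obj_surface`.
#' @export
sentence_triples <- function(sentence) {
  tri <- sentence$triples
  ent <- sentence$entities
  data.frame(
    sub_start = ent$start[tri$sub], sub_end = ent$end[tri$sub],
    sub_type = ent$type[tri$sub], sub_surface = ent$surface[tri$sub],
    relation = tri$relation,
    obj_start = ent$start[tri$obj], obj_end = ent$end[tri$obj],
    obj_type = ent$type[tri$obj], obj_surface = ent$surface[tri$obj],
    stringsAsFactors = FALSE
  )
}
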