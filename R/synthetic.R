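#' Default surface vocabulary for the synthetic generator
#'
#' Synthetic surfaces only: each entity type gets a pool of short strings
#' whose first character tags the type (so a character-level model can learn
#' typing) followed by distinct lowercase letters. No real clinical terms.
#'
#' @param n_per_type Number of surfaces per entity type.
#' @param schema The schema whose entity types need vocabularies.
#' @return Named list mapping entity type to a character vector of surfaces.
#' @export
default_vocab <- function(schema = default_vte_schema(), n_per_type = 12L) {
  tags <- c(Disease = "D", Symptom = "S", Drug = "G", Factor = "F",
            Treatment = "W", Test = "T", Matter = "M")
  extra <- setdiff(schema$entity_types, names(tags))
  if (length(extra)) {
    pool <- setdiff(LETTERS, tags)
    tags <- c(tags, stats::setNames(pool[seq_along(extra)], extra))
  }
  out <- list()
  for (et in schema$entity_types) {
    # deterministic two-letter bodies: ab, cd, ef, ... then ba, dc, ...
    body <- apply(cbind(letters[seq(1, 2 * n_per_type, 2)],
                        letters[seq(2, 2 * n_per_type, 2)]), 1,
                  paste, collapse = "")
    out[[et]] <- paste0(tags[[et]], body[seq_len(n_per_type)])
  }
  out
}

#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the structure of an annotated clinical corpus:
#' short character-tokenized sentences, each carrying one subject entity
#' related to one or (with probability `p_multi_object`) two object entities
#' under a single relation type, plus a fraction of entity-only sentences
#' providing negative relation examples. Relation frequencies follow
#' `relation_profile`; the default is the training-split relation profile of
#' the VTE corpus being emulated (TrAS and TeAS dominant, DM and SM rare).
#'
#' @param n_sentences Number of sentences to generate.
#' @param schema Target `re_schema`.
#' @param vocab Named list: entity type -> surface strings
#'   (default [default_vocab()]).
#' @param templates List of slot sequences; each template is a character
#'   vector over slots `"filler"`, `"subject"`, `"marker"`, `"objects"`.
#' @param relation_profile Named non-negative weights per relation type, not
#'   all zero; need not sum to 1.
#' @param max_len Maximum sentence length in tokens (<= 256).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param p_multi_object Probability that a relational sentence links one
#'   subject to two objects under the same relation.
#' @param p_entity_only Probability that a sentence holds a single entity
#'   and no triple.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_sentences,
                             schema = default_vte_schema(),
                             vocab = default_vocab(schema),
                             templates = list(c("filler", "subject",
                                                "marker", "objects",
                                                "filler")),
                             relation_profile = vte_relation_profile(),
                             max_len = 64L,
                             seed = 1L,
                             p_multi_object = 0.3,
                             p_entity_only = 0.1) {
  relation_profile <- relation_profile[schema$relation_types]
  if (any(is.na(relation_profile)))
    stop("relation_profile must cover every relation type of the schema")
  if (any(relation_profile < 0) || all(relation_profile == 0))
    stop("relation weights must be >= 0 and not all zero")
  if (max_len > 256L) stop("max_len must be <= 256")
  if (!all(schema$entity_types %in% names(vocab)) ||
      any(!vapply(vocab[schema$entity_types], length, 0L)))
    stop("vocab must provide at least one surface for every entity type")
  for (tp in templates)
    if (!all(tp %in% c("filler", "subject", "marker", "objects")))
      stop("unknown template slot: ",
           paste(setdiff(tp, c("filler", "subject", "marker", "objects")),
                 collapse = ", "))
  structure(list(n_sentences = as.integer(n_sentences), schema = schema,
                 vocab = vocab, templates = templates,
                 relation_profile = relation_profile,
                 max_len = as.integer(max_len), seed = as.integer(seed),
                 p_multi_object = p_multi_object,
                 p_entity_only = p_entity_only),
            class = "generator_config")
}

#' Training-split relation frequency profile of the emulated VTE corpus
#'
#' Raw counts per relation type in the training split of the clinical
#' corpus the generator imitates; used as sampling weights.
#'
#' @return Named numeric vector of counts for the 14 relation types.
#' @export
vte_relation_profile <- function() {
  c(TrAD = 395, TrAS = 1406, TeRD = 326, TeBD = 151, TeRS = 148,
    TeAS = 706, DIS = 271, SDD = 188, FCS = 95, DrAD = 258, DrAS = 269,
    DrTr = 296, DM = 88, SM = 109)
}

# one distinct marker character per relation type; fillers never use these
.relation_markers <- function(relation_types) {
  pool <- c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
            "!", "@", "#", "$", "%", "&", "*", "=", "?", "~")
  if (length(relation_types) > length(pool))
    stop("marker pool exhausted")
  stats::setNames(pool[seq_along(relation_types)], relation_types)
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given `config$seed`. Every sentence is schema-valid; every
#' triple obeys the relation signature; entities never overlap and sentences
#' never exceed `max_len`.
#'
#' @param config A `generator_config`.
#' @return List of `annotated_sentence` objects.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  schema <- config$schema
  markers <- .relation_markers(schema$relation_types)
  fillers <- strsplit("uvwxyz.,;: ", "")[[1]]
  prob <- config$relation_profile / sum(config$relation_profile)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  out <- vector("list", config$n_sentences)
  for (k in seq_len(config$n_sentences)) {
    entity_only <- stats::runif(1) < config$p_entity_only
    rel <- sample(schema$relation_types, 1, prob = prob)
    sig <- schema$relation_signature[[rel]]
    n_obj <- if (!entity_only && stats::runif(1) < config$p_multi_object)
      2L else 1L
    sub_surface <- sample(config$vocab[[sig[1]]], 1)
    obj_surfaces <- sample(config$vocab[[sig[2]]],
                           n_obj, replace = FALSE)
    template <- config$templates[[sample.int(length(config$templates), 1)]]
    tokens <- character(0)
    ent <- data.frame(start = integer(), end = integer(),
                      type = character(), stringsAsFactors = FALSE)
    tri <- data.frame(sub = integer(), relation = character(),
                      obj = integer(), stringsAsFactors = FALSE)
    push_entity <- function(surface, type) {
      st <- length(tokens)
      tokens <<- c(tokens, strsplit(surface, "")[[1]])
      ent[nrow(ent) + 1L, ] <<- list(st, length(tokens) - 1L, type)
      nrow(ent)
    }
    for (slot in template) {
      if (slot == "filler") {
        n_fill <- sample(0:2, 1)
        tokens <- c(tokens, sample(fillers, n_fill, replace = TRUE))
      } else if (slot == "subject") {
        if (entity_only) {
          push_entity(sub_surface, sig[1])
        } else {
          si <- push_entity(sub_surface, sig[1])
          tri_sub <- si
        }
      } else if (slot == "marker") {
        if (!entity_only) tokens <- c(tokens, markers[[rel]])
      } else if (slot == "objects") {
        if (!entity_only) {
          for (j in seq_len(n_obj)) {
            if (j > 1L) tokens <- c(tokens, "+")
            oi <- push_entity(obj_surfaces[j], sig[2])
            tri[nrow(tri) + 1L, ] <- list(tri_sub, rel, oi)
          }
        }
      }
    }
    if (length(tokens) > config$max_len)
      stop("generated sentence exceeds max_len; shorten vocab or templates")
    sent <- annotated_sentence(tokens, ent, tri)
    validate_sentence(sent, schema, max_len = config$max_len)
    out[[k]] <- sent
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' The worked pulmonary-embolism example sentence and its gold matrices
#'
#' A 17-character Chinese clinical sentence ("Pulmonary embolism is
#' characterized by sudden chest pain, hemoptysis and other discomforts")
#' annotated with one Disease entity (pulmonary embolism) and two Symptom
#' entities (chest pain, hemoptysis), linked by two DIS (disease causes
#' symptom) triples sharing the subject: the canonical one-subject,
#' two-objects configuration of the token-pair tagging scheme. The exact
#' filler characters between the three mentions are one concrete rendering;
#' only the entity and relation structure is load-bearing.
#'
#' @return List with elements `sentence` (an `annotated_sentence`) and
#'   `matrices` (sign-valued gold `global_matrices`).
#' @export
worked_example_fixture <- function() {
  # unicode escapes keep the source file ASCII-safe
  text <- paste0("\u80ba\u6813\u585e\u8868\u73b0\u4e3a\u7a81\u53d1",
                 "\u7684\u80f8\u75db\uff0c\u54af\u8840\u7b49\u4e0d\u9002")
  sent <- annotated_sentence(
    text,
    entities = data.frame(
      start = c(0L, 9L, 12L), end = c(2L, 10L, 13L),
      type = c("Disease", "Symptom", "Symptom"),
      stringsAsFactors = FALSE),
    triples = data.frame(
      sub = c(1L, 1L), relation = c("DIS", "DIS"), obj = c(2L, 3L),
      stringsAsFactors = FALSE))
  schema <- default_vte_schema()
  validate_sentence(sent, schema)
  list(sentence = sent, matrices = encode_gold(sent, schema))
}
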