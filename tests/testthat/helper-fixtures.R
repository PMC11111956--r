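# Small shared fixtures: a 2-entity-type / 2-relation schema and a tiny
# model configuration that keeps neural tests fast.

tiny_schema <- function() {
  re_schema(c("A", "B"), c("r1", "r2"),
            list(r1 = c("A", "B"), r2 = c("B", "A")))
}

tiny_vocab <- function() letters[1:8]

tiny_model_config <- function(...) {
  model_config(schema = tiny_schema(), vocab = tiny_vocab(),
               d = 8L, gru_hidden = 4L, n_slots = 3L, ...)
}

tiny_sentence <- function() {
  annotated_sentence(
    c("a", "b", "c", "a", "d"),
    entities = data.frame(start = c(0L, 2L), end = c(1L, 3L),
                          type = c("A", "B"), stringsAsFactors = FALSE),
    triples = data.frame(sub = 1L, relation = "r1", obj = 2L,
                         stringsAsFactors = FALSE))
}

# random sign-valued global matrices with the given density of positives;
# entity lower triangle stays invalid (0)
random_sign_matrices <- function(s, entity_types, relation_types,
                                 density = 0.15) {
  rs <- function(cc) {
    a <- array(sample(c(1, -1), cc * s * s, replace = TRUE,
                      prob = c(density, 1 - density)), dim = c(cc, s, s))
    a
  }
  ent <- rs(length(entity_types))
  for (k in seq_along(entity_types))
    ent[k, , ][lower.tri(matrix(0, s, s))] <- 0
  global_matrices(ent, rs(length(relation_types)),
                  rs(length(relation_types)),
                  entity_types, relation_types)
}

# random real-valued score matrices
random_score_matrices <- function(s, entity_types, relation_types,
                                  sd = 1) {
  ra <- function(cc) array(stats::rnorm(cc * s * s, sd = sd),
                           dim = c(cc, s, s))
  global_matrices(ra(length(entity_types)), ra(length(relation_types)),
                  ra(length(relation_types)), entity_types, relation_types)
}

# canonical sorted key set for a sentence's annotations
entity_keys <- function(sent)
  sort(paste(sent$entities$start, sent$entities$end, sent$entities$type,
             sep = "|"))
triple_keys_of <- function(sent) {
  tr <- sentence_triples(sent)
  sort(paste(tr$sub_start, tr$sub_end, tr$sub_type, tr$relation,
             tr$obj_start, tr$obj_end, tr$obj_type, sep = "|"))
}
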