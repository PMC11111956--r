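#' Decode entities from global matrices
#'
#' An entity span `(start, end, type)` is emitted for every entity-family
#' cell with `start <= end` whose score strictly exceeds the threshold.
#' Threshold 0 is the decision boundary built into the multi-label
#' cross-entropy loss, which drives positive-cell scores above 0 and
#' negative-cell scores below 0; ties at exactly the threshold are excluded.
#'
#' @param M A `global_matrices`.
#' @param threshold Score threshold (strict).
#' @return Data frame with columns `start`, `end` (0-based inclusive),
#'   `type`, sorted by `(start, end, type)`.
#' @export
decode_entities <- function(M, threshold = 0) {
  hits <- which(M$entity > threshold, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(start = integer(), end = integer(),
                      type = character(), stringsAsFactors = FALSE))
  keep <- hits[, 2] <= hits[, 3]
  hits <- hits[keep, , drop = FALSE]
  out <- data.frame(start = as.integer(hits[, 2] - 1L),
                    end = as.integer(hits[, 3] - 1L),
                    type = M$entity_types[hits[, 1]],
                    stringsAsFactors = FALSE)
  out[order(out$start, out$end, out$type), , drop = FALSE]
}

#' Decode relational triples from global matrices
#'
#' One-step joint decoding: entities are decoded first; then for every
#' ordered pair of decoded entities and every relation channel, a triple is
#' emitted when both the subject-head/object-head cell and the
#' subject-tail/object-tail cell exceed the threshold. Only decoded entities
#' are paired -- raw head/tail indices that do not form a decoded span never
#' produce triples.
#'
#' @param M A `global_matrices`.
#' @param threshold Score threshold (strict).
#' @param schema Optional `re_schema`; required when `enforce_signature`.
#' @param enforce_signature If `TRUE`, drop triples whose subject/object
#'   entity types violate the schema's relation signature.
#' @return Data frame with columns `sub_start`, `sub_end`, `sub_type`,
#'   `relation`, `obj_start`, `obj_end`, `obj_type`, sorted.
#' @export
decode_triples <- function(M, threshold = 0, schema = NULL,
                           enforce_signature = FALSE) {
  empty <- data.frame(sub_start = integer(), sub_end = integer(),
                      sub_type = character(), relation = character(),
                      obj_start = integer(), obj_end = integer(),
                      obj_type = character(), stringsAsFactors = FALSE)
  ents <- decode_entities(M, threshold)
  m <- nrow(ents)
  if (m == 0) return(empty)
  # vectorized over all ordered entity pairs and relation channels
  ai <- rep(seq_len(m), each = m)
  bi <- rep.int(seq_len(m), m)
  sh <- cbind(ents$start[ai] + 1L, ents$start[bi] + 1L)
  st <- cbind(ents$end[ai] + 1L, ents$end[bi] + 1L)
  rows <- vector("list", length(M$relation_types))
  for (r in seq_along(M$relation_types)) {
    hit <- M$sub_head_obj_head[r, , ][sh] > threshold &
      M$sub_tail_obj_tail[r, , ][st] > threshold
    if (enforce_signature) {
      sig <- schema$relation_signature[[M$relation_types[r]]]
      hit <- hit & ents$type[ai] == sig[1] & ents$type[bi] == sig[2]
    }
    if (!any(hit)) next
    rows[[r]] <- data.frame(
      sub_start = ents$start[ai[hit]], sub_end = ents$end[ai[hit]],
      sub_type = ents$type[ai[hit]], relation = M$relation_types[r],
      obj_start = ents$start[bi[hit]], obj_end = ents$end[bi[hit]],
      obj_type = ents$type[bi[hit]], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$sub_start, out$sub_end, out$relation,
                   out$obj_start, out$obj_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decode a full sentence annotation from global matrices
#'
#' Convenience wrapper returning an `annotated_sentence` whose entities and
#' triples are the decoder output over `M`, attached to the given tokens.
#'
#' @param tokens Token vector of the sentence the matrices score.
#' @param M A `global_matrices` with `s == length(tokens)`.
#' @param threshold Score threshold.
#' @return An `annotated_sentence`.
#' @export
decode_sentence <- function(tokens, M, threshold = 0) {
  stopifnot(M$s == length(tokens))
  ents <- decode_entities(M, threshold)
  tris <- decode_triples(M, threshold)
  key <- function(st, en, tp) paste(st, en, tp, sep = ":")
  ekeys <- key(ents$start, ents$end, ents$type)
  tri <- data.frame(
    sub = match(key(tris$sub_start, tris$sub_end, tris$sub_type), ekeys),
    relation = tris$relation,
    obj = match(key(tris$obj_start, tris$obj_end, tris$obj_type), ekeys),
    stringsAsFactors = FALSE)
  annotated_sentence(tokens, ents, tri)
}
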