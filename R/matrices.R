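#' Construct a set of token-pair global matrices
#'
#' Three score families over token pairs of a length-`s` sentence: entity
#' head-tail (one channel per entity type, or a single untyped channel),
#' subject-head to object-head and subject-tail to object-tail (one channel
#' per relation type each). Arrays are indexed `[channel, i, j]` with
#' 1-based R indices; token positions are 0-based elsewhere.
#'
#' @param entity Numeric array `(n_entity_channels, s, s)`.
#' @param sub_head_obj_head Numeric array `(n_relations, s, s)`.
#' @param sub_tail_obj_tail Numeric array `(n_relations, s, s)`.
#' @param entity_types Channel labels of the entity family.
#' @param relation_types Channel labels of the two relation families.
#' @return Object of class `global_matrices`.
#' @export
global_matrices <- function(entity, sub_head_obj_head, sub_tail_obj_tail,
                            entity_types, relation_types) {
  s <- dim(entity)[2]
  stopifnot(dim(entity)[3] == s,
            all(dim(sub_head_obj_head) == c(length(relation_types), s, s)),
            all(dim(sub_tail_obj_tail) == c(length(relation_types), s, s)),
            dim(entity)[1] == length(entity_types))
  if (!all(is.finite(entity)) || !all(is.finite(sub_head_obj_head)) ||
      !all(is.finite(sub_tail_obj_tail)))
    stop("global matrices must be finite")
  structure(list(entity = entity,
                 sub_head_obj_head = sub_head_obj_head,
                 sub_tail_obj_tail = sub_tail_obj_tail,
                 entity_types = entity_types,
                 relation_types = relation_types,
                 s = s),
            class = "global_matrices")
}

#' @export
print.global_matrices <- function(x, ...) {
  cat("<global_matrices> s=", x$s, ", entity channels=",
      length(x$entity_types), ", relation channels=",
      length(x$relation_types), "\n", sep = "")
  invisible(x)
}

#' Encode gold annotations as sign-valued global matrices
#'
#' The labeling construction inverse to decoding: the entity family gets +1
#' at `(type, start, end)` for every gold entity; the head family gets +1 at
#' `(relation, subject start, object start)` and the tail family +1 at
#' `(relation, subject end, object end)` for every gold triple; every other
#' valid cell is -1. Entity cells with `i > j` (a span ending before it
#' starts) are invalid rather than negative; they are stored as 0 and must
#' be masked, never trained or decoded.
#'
#' @param sentence A schema-valid `annotated_sentence`.
#' @param schema An `re_schema`.
#' @param untyped_entity If `TRUE`, collapse the entity family to a single
#'   untyped channel.
#' @return Sign-valued `global_matrices`.
#' @export
encode_gold <- function(sentence, schema, untyped_entity = FALSE) {
  s <- length(sentence$tokens)
  etypes <- if (untyped_entity) "*" else schema$entity_types
  nR <- length(schema$relation_types)
  ent <- array(-1, dim = c(length(etypes), s, s))
  # invalid lower triangle (i > j): neither positive nor negative
  for (k in seq_along(etypes))
    ent[k, , ][lower.tri(matrix(0, s, s))] <- 0
  sho <- array(-1, dim = c(nR, s, s))
  sto <- array(-1, dim = c(nR, s, s))
  E <- sentence$entities
  for (i in seq_len(nrow(E))) {
    k <- if (untyped_entity) 1L else match(E$type[i], etypes)
    ent[k, E$start[i] + 1L, E$end[i] + 1L] <- 1
  }
  Tr <- sentence$triples
  for (i in seq_len(nrow(Tr))) {
    r <- match(Tr$relation[i], schema$relation_types)
    su <- Tr$sub[i]; ob <- Tr$obj[i]
    sho[r, E$start[su] + 1L, E$start[ob] + 1L] <- 1
    sto[r, E$end[su] + 1L, E$end[ob] + 1L] <- 1
  }
  global_matrices(ent, sho, sto, etypes, schema$relation_types)
}

#' Fuse two sets of global matrices
#'
#' Element-wise additive fusion of corresponding score tensors (logit
#' addition). With either side `NULL` (an ablated branch) the other side is
#' returned unchanged. `method = "learned_gate"` instead forms a convex
#' combination `sigmoid(gate) * a + (1 - sigmoid(gate)) * b` per family.
#'
#' @param a,b `global_matrices` of matching shapes, or `NULL`.
#' @param method `"sum"` (default) or `"learned_gate"`.
#' @param gates Named numeric vector of per-family gate logits
#'   (`entity`, `sub_head_obj_head`, `sub_tail_obj_tail`), used only by the
#'   gated method.
#' @return A `global_matrices`.
#' @export
fuse_matrices <- function(a, b, method = c("sum", "learned_gate"),
                          gates = c(entity = 0, sub_head_obj_head = 0,
                                    sub_tail_obj_tail = 0)) {
  method <- match.arg(method)
  if (is.null(a) && is.null(b)) stop("both inputs are absent")
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  fams <- c("entity", "sub_head_obj_head", "sub_tail_obj_tail")
  for (f in fams)
    if (!all(dim(a[[f]]) == dim(b[[f]])))
      stop("shape mismatch in family ", f)
  out <- a
  for (f in fams) {
    if (method == "sum") {
      out[[f]] <- a[[f]] + b[[f]]
    } else {
      g <- 1 / (1 + exp(-gates[[f]]))
      out[[f]] <- g * a[[f]] + (1 - g) * b[[f]]
    }
  }
  out
}
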