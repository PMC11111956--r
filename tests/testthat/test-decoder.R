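# independent brute-force decoders used as oracles
brute_entities <- function(M, threshold = 0) {
  out <- data.frame(start = integer(), end = integer(), type = character(),
                    stringsAsFactors = FALSE)
  for (k in seq_along(M$entity_types)) for (i in seq_len(M$s))
    for (j in seq_len(M$s))
      if (i <= j && M$entity[k, i, j] > threshold)
        out[nrow(out) + 1L, ] <- list(i - 1L, j - 1L, M$entity_types[k])
  out[order(out$start, out$end, out$type), , drop = FALSE]
}

brute_triples <- function(M, threshold = 0) {
  ents <- brute_entities(M, threshold)
  out <- data.frame(sub_start = integer(), sub_end = integer(),
                    sub_type = character(), relation = character(),
                    obj_start = integer(), obj_end = integer(),
                    obj_type = character(), stringsAsFactors = FALSE)
  for (a in seq_len(nrow(ents))) for (b in seq_len(nrow(ents)))
    for (r in seq_along(M$relation_types)) {
      if (M$sub_head_obj_head[r, ents$start[a] + 1, ents$start[b] + 1] >
          threshold &&
          M$sub_tail_obj_tail[r, ents$end[a] + 1, ents$end[b] + 1] >
          threshold)
        out[nrow(out) + 1L, ] <- list(ents$start[a], ents$end[a],
                                      ents$type[a], M$relation_types[r],
                                      ents$start[b], ents$end[b],
                                      ents$type[b])
    }
  out <- unique(out)
  out[order(out$sub_start, out$sub_end, out$relation, out$obj_start,
            out$obj_end), , drop = FALSE]
}

test_that("entity decoding matches exhaustive enumeration on random scores", {
  set.seed(41)
  for (rep in 1:20) {
    M <- random_score_matrices(6, c("A", "B"), c("r1", "r2", "r3"))
    got <- decode_entities(M)
    want <- brute_entities(M)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
  # all scores below threshold -> empty set
  M <- random_score_matrices(4, "A", "r")
  expect_equal(nrow(decode_entities(M, threshold = max(M$entity) + 1)), 0)
})

test_that("triple decoding matches the O(|E|^2 |R|) brute force", {
  set.seed(42)
  for (rep in 1:12) {
    M <- random_sign_matrices(8, c("A", "B", "C"),
                              c("r1", "r2", "r3", "r4"), density = 0.2)
    got <- decode_triples(M)
    want <- brute_triples(M)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("no decoded entities means no triples, whatever the relation scores", {
  s <- 5
  ent <- array(-1, dim = c(1, s, s))
  hot <- array(10, dim = c(2, s, s))
  M <- global_matrices(ent, hot, hot, "A", c("r1", "r2"))
  expect_equal(nrow(decode_triples(M)), 0)
})

test_that("raising the threshold never adds entities or triples", {
  set.seed(43)
  M <- random_score_matrices(7, c("A", "B"), c("r1", "r2"))
  th <- sort(stats::runif(5, -1, 1))
  prev_e <- Inf; prev_t <- Inf
  for (t in th) {
    ne <- nrow(decode_entities(M, t)); nt <- nrow(decode_triples(M, t))
    expect_lte(ne, prev_e); expect_lte(nt, prev_t)
    prev_e <- ne; prev_t <- nt
  }
})

test_that("decoder ignores invalid lower-triangle entity cells", {
  set.seed(44)
  M <- random_score_matrices(6, c("A", "B"), "r1")
  base_e <- decode_entities(M)
  base_t <- decode_triples(M)
  # blast the i > j cells with huge scores; nothing may change
  for (k in 1:2) M$entity[k, , ][lower.tri(matrix(0, 6, 6))] <- 1e6
  expect_equal(decode_entities(M), base_e)
  expect_equal(decode_triples(M), base_t)
})

test_that("gold encoding partitions cells and decodes losslessly", {
  sc <- tiny_schema()
  s <- tiny_sentence()
  M <- encode_gold(s, sc)
  # entity family: positives only at gold cells, lower triangle invalid
  expect_equal(sum(M$entity == 1), 2)
  expect_equal(M$entity[1, 1, 2], 1)  # span (0,1) type A
  expect_equal(M$entity[2, 3, 4], 1)  # span (2,3) type B
  for (k in 1:2)
    expect_true(all(M$entity[k, , ][lower.tri(matrix(0, 5, 5))] == 0))
  # head family positive at (r1, sub start 0, obj start 2)
  expect_equal(M$sub_head_obj_head[1, 1, 3], 1)
  expect_equal(sum(M$sub_head_obj_head == 1), 1)
  # tail family positive at (r1, sub end 1, obj end 3)
  expect_equal(M$sub_tail_obj_tail[1, 2, 4], 1)
  expect_equal(sum(M$sub_tail_obj_tail == 1), 1)
  dec <- decode_sentence(s$tokens, M)
  expect_identical(triple_keys_of(dec), triple_keys_of(s))
  # a sentence without annotations encodes to all-negative valid cells
  blank <- annotated_sentence(c("x", "y", "z"))
  Mb <- encode_gold(blank, sc)
  expect_true(all(Mb$sub_head_obj_head == -1))
  expect_true(all(Mb$entity[Mb$entity != 0] == -1))
})

test_that("worked example matrices carry the one-subject-two-objects pattern", {
  fx <- worked_example_fixture()
  M <- fx$matrices
  r <- match("DIS", M$relation_types)
  # subject head (position 0) linked to the two object heads (9 and 12)
  expect_equal(which(M$sub_head_obj_head[r, , ] == 1, arr.ind = TRUE),
               cbind(row = c(1L, 1L), col = c(10L, 13L)))
  # subject tail (position 2) linked to the two object tails (10 and 13)
  expect_equal(which(M$sub_tail_obj_tail[r, , ] == 1, arr.ind = TRUE),
               cbind(row = c(3L, 3L), col = c(11L, 14L)))
  # no other relation channel holds positives
  expect_equal(sum(M$sub_head_obj_head == 1), 2)
  expect_equal(sum(M$sub_tail_obj_tail == 1), 2)
})

test_that("head/tail pair factorization has a known cross-combination ambiguity", {
  # Entities A1=(0,0) and A2=(0,1) share their head token; B1=(3,4) and
  # B2=(2,4) share their tail token. Gold triples (A1,r,B1) and (A2,r,B2)
  # put head pair (0,2) and tail pair (0,4) into the matrices, which also
  # licenses the spurious (A1,r,B2): an inherent limit of factorizing
  # triples into independent head and tail links, not a decoder bug.
  sc <- re_schema(c("A", "B"), "r", list(r = c("A", "B")))
  sent <- annotated_sentence(
    c("t0", "t1", "t2", "t3", "t4"),
    entities = data.frame(start = c(0L, 0L, 3L, 2L),
                          end = c(0L, 1L, 4L, 4L),
                          type = c("A", "A", "B", "B"),
                          stringsAsFactors = FALSE),
    triples = data.frame(sub = c(1L, 2L), relation = "r",
                         obj = c(3L, 4L), stringsAsFactors = FALSE))
  M <- encode_gold(sent, sc)
  dec <- decode_triples(M)
  want_gold <- triple_keys_of(sent)
  got <- sort(paste(dec$sub_start, dec$sub_end, dec$sub_type, dec$relation,
                    dec$obj_start, dec$obj_end, dec$obj_type, sep = "|"))
  spurious <- "0|0|A|r|2|4|B"
  expect_true(all(want_gold %in% got))
  expect_true(spurious %in% got)
  # non-overlapping entities (the generator's regime) cannot cross-combine,
  # which is why the codec round-trip holds there
})

test_that("fusion is element-wise addition with identity and commutativity", {
  set.seed(45)
  a <- random_score_matrices(5, c("A", "B"), c("r1", "r2"))
  b <- random_score_matrices(5, c("A", "B"), c("r1", "r2"))
  zero <- global_matrices(array(0, dim(a$entity)),
                          array(0, dim(a$sub_head_obj_head)),
                          array(0, dim(a$sub_tail_obj_tail)),
                          a$entity_types, a$relation_types)
  expect_equal(fuse_matrices(a, zero), a)
  expect_equal(fuse_matrices(a, b), fuse_matrices(b, a))
  f <- fuse_matrices(a, b)
  expect_equal(f$entity, a$entity + b$entity)
  expect_equal(f$sub_tail_obj_tail, a$sub_tail_obj_tail +
                 b$sub_tail_obj_tail)
  # ablated side: the other input passes through unchanged
  expect_identical(fuse_matrices(a, NULL), a)
  expect_identical(fuse_matrices(NULL, b), b)
  bad <- random_score_matrices(4, c("A", "B"), c("r1", "r2"))
  expect_error(fuse_matrices(a, bad), "shape mismatch")
})
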