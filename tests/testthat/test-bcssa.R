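# independent step-by-step oracle for the slot formulation
oracle_slot_attention <- function(H, Wq, Wk, Wv, C, scale) {
  s <- nrow(H)
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  KC <- rbind(K, C); VC <- rbind(V, C)
  O <- matrix(0, s, ncol(H))
  for (i in seq_len(s)) {
    scores <- numeric(nrow(KC))
    for (j in seq_len(nrow(KC)))
      scores[j] <- sum(Q[i, ] * KC[j, ]) / scale
    w <- exp(scores - max(scores)); w <- w / sum(w)
    for (j in seq_len(nrow(KC))) O[i, ] <- O[i, ] + w[j] * VC[j, ]
  }
  O
}

csa_params <- function(d, n, seed = 1) {
  set.seed(seed)
  list(csa_Wq = matrix(rnorm(d * d, sd = 0.5), d, d),
       csa_Wk = matrix(rnorm(d * d, sd = 0.5), d, d),
       csa_Wv = matrix(rnorm(d * d, sd = 0.5), d, d),
       csa_C = matrix(rnorm(n * d, sd = 0.5), n, d))
}

test_that("n = 0 reduces the layer to vanilla self-attention", {
  set.seed(61)
  d <- 8; s <- 5
  pp <- csa_params(d, 0)
  H <- matrix(rnorm(s * d), s, d)
  got <- common_sequence_attention(H, pp)
  want <- oracle_slot_attention(H, pp$csa_Wq, pp$csa_Wk, pp$csa_Wv,
                                matrix(0, 0, d), sqrt(d))
  expect_equal(got, want, tolerance = 1e-6)
  # n = 0, s = 1: softmax over one element, output is the value vector
  H1 <- matrix(rnorm(d), 1, d)
  expect_equal(common_sequence_attention(H1, pp), H1 %*% pp$csa_Wv,
               tolerance = 1e-10)
})

test_that("slot formulation matches the dense step-by-step oracle", {
  set.seed(62)
  d <- 8; s <- 4; n <- 2
  pp <- csa_params(d, n, seed = 62)
  H <- matrix(rnorm(s * d), s, d)
  got <- common_sequence_attention(H, pp, return_attention = TRUE)
  want <- oracle_slot_attention(H, pp$csa_Wq, pp$csa_Wk, pp$csa_Wv,
                                pp$csa_C, sqrt(d))
  A <- attr(got, "attention")
  attr(got, "attention") <- NULL
  expect_equal(got, want, tolerance = 1e-6)
  # attention weights: one row per query over s + n keys, each summing to 1
  expect_equal(dim(A), c(s, s + n))
  expect_true(all(A >= 0))
  expect_equal(rowSums(A), rep(1, s), tolerance = 1e-6)
  # alternative d_k scaling divides by d instead of sqrt(d)
  got_dk <- common_sequence_attention(H, pp, attn_scale = "dk")
  want_dk <- oracle_slot_attention(H, pp$csa_Wq, pp$csa_Wk, pp$csa_Wv,
                                   pp$csa_C, d)
  expect_equal(got_dk, want_dk, tolerance = 1e-6)
})

test_that("literal formulation projects through the shared matrix", {
  set.seed(63)
  d <- 6; s <- 3; n <- 4
  pp <- csa_params(d, n, seed = 63)
  H <- matrix(rnorm(s * d), s, d)
  Q <- H %*% pp$csa_Wq; K <- H %*% pp$csa_Wk; V <- H %*% pp$csa_Wv
  Qc <- Q %*% t(pp$csa_C); Kc <- K %*% t(pp$csa_C)
  S <- Qc %*% t(Kc) / sqrt(d)
  A <- t(apply(S, 1, function(r) {
    e <- exp(r - max(r)); e / sum(e)
  }))
  want <- (A %*% (V %*% t(pp$csa_C))) %*% pp$csa_C
  got <- common_sequence_attention(H, pp, formulation = "literal")
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("permuting the rows of the shared matrix leaves slot output unchanged", {
  set.seed(64)
  d <- 8; n <- 5
  pp <- csa_params(d, n, seed = 64)
  H <- matrix(rnorm(4 * d), 4, d)
  base <- common_sequence_attention(H, pp)
  pp2 <- pp
  pp2$csa_C <- pp$csa_C[sample(n), , drop = FALSE]
  expect_equal(common_sequence_attention(H, pp2), base, tolerance = 1e-10)
})

test_that("dimension mismatches raise configuration errors", {
  pp <- csa_params(8, 2)
  expect_error(common_sequence_attention(matrix(0, 3, 5), pp),
               "dimension")
  pp$csa_C <- matrix(0, 2, 5)
  expect_error(common_sequence_attention(matrix(rnorm(24), 3, 8), pp),
               "shared matrix")
})

test_that("biaffine scoring: bias-only case and pencil-and-paper oracle", {
  s <- 3; p <- 4; cc <- 2
  Hs <- matrix(rnorm(s * p), s, p); He <- matrix(rnorm(s * p), s, p)
  U0 <- array(0, dim = c(p + 1, p + 1, cc))
  G <- biaffine_score(Hs, He, U0, b = c(0.7, 0.7))
  expect_equal(dim(G), c(cc, s, s))
  expect_true(all(G == 0.7))
  # s = 2, p = 1, hand-set weights: cell (1, i, j) =
  #   u11*hs_i*he_j + u12*hs_i + u21*he_j + u22 + b
  hs <- c(2, -1); he <- c(0.5, 3)
  U <- array(c(1, 10, 100, 1000), dim = c(2, 2, 1))
  # column-major fill: U[1,1]=1 u11, U[2,1]=10 (1 coeff * he),
  # U[1,2]=100 (hs * 1), U[2,2]=1000
  Gp <- biaffine_score(matrix(hs, 2, 1), matrix(he, 2, 1), U, b = 0.25)
  manual <- function(a, e) 1 * a * e + 10 * e + 100 * a + 1000 + 0.25
  for (i in 1:2) for (j in 1:2)
    expect_equal(Gp[1, i, j], manual(hs[i], he[j]))
})

test_that("full matrix builder composes attention and biaffine heads", {
  mc <- tiny_model_config(use_global_pointer = FALSE)
  pp <- init_params(mc, seed = 7)
  toks <- c("a", "b", "c", "d")
  fw <- model_forward(toks, pp, mc)
  # composition oracle from the exported primitives
  ec <- encoder_config("lookup", d = mc$d, gru_hidden = mc$gru_hidden,
                       vocab = mc$vocab)
  H <- contextualize(embed_tokens(toks, ec, pp$emb), ec, pp)
  O <- common_sequence_attention(H, pp)
  for (fam in c("ent", "sho", "sto")) {
    Hs <- tanh(sweep(O %*% pp[[paste0("ffnn_s_", fam, "_W")]], 2,
                     pp[[paste0("ffnn_s_", fam, "_b")]], "+"))
    He <- tanh(sweep(O %*% pp[[paste0("ffnn_e_", fam, "_W")]], 2,
                     pp[[paste0("ffnn_e_", fam, "_b")]], "+"))
    G <- biaffine_score(Hs, He, pp[[paste0("biaff_U_", fam)]],
                        pp[[paste0("biaff_b_", fam)]])
    field <- c(ent = "entity", sho = "sub_head_obj_head",
               sto = "sub_tail_obj_tail")[[fam]]
    expect_equal(fw$matrices[[field]], G, tolerance = 1e-10)
  }
  # determinism under fixed parameters
  expect_identical(fw$matrices, model_forward(toks, pp, mc)$matrices)
})

test_that("attention ablation scores the raw encoder output", {
  mc_off <- tiny_model_config(use_global_pointer = FALSE, use_csa = FALSE)
  pp <- init_params(mc_off, seed = 8)
  toks <- c("a", "b", "c")
  fw <- model_forward(toks, pp, mc_off)
  ec <- encoder_config("lookup", d = mc_off$d,
                       gru_hidden = mc_off$gru_hidden, vocab = mc_off$vocab)
  H <- contextualize(embed_tokens(toks, ec, pp$emb), ec, pp)
  Hs <- tanh(sweep(H %*% pp$ffnn_s_ent_W, 2, pp$ffnn_s_ent_b, "+"))
  He <- tanh(sweep(H %*% pp$ffnn_e_ent_W, 2, pp$ffnn_e_ent_b, "+"))
  expect_equal(fw$matrices$entity,
               biaffine_score(Hs, He, pp$biaff_U_ent, pp$biaff_b_ent),
               tolerance = 1e-10)
})

test_that("the shared matrix receives gradient and moves under training", {
  mc <- tiny_model_config(use_global_pointer = FALSE)
  s <- tiny_sentence()
  corp <- list(s)
  m0 <- init_params(mc, seed = 9)
  m <- train_model(corp, mc, train_config(batch_size = 1L, lr = 1e-2,
                                          epochs = 1L, seed = 9))
  expect_gt(max(abs(m$params$csa_C - m0$csa_C)), 0)
})
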