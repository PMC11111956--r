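#' Full model configuration
#'
#' Collects every dimension, ablation switch and architectural choice of the
#' joint extraction model: lookup embedding, BiGRU context layer,
#' common-sequence self-attention plus biaffine global-matrix scorer, rotary
#' global pointer head, additive fusion, and the training loss.
#'
#' @param schema An `re_schema` dimensioning the matrix channels.
#' @param vocab Character vector of known tokens for the lookup embedding.
#' @param d Embedding dimension.
#' @param gru_hidden Per-direction GRU width; encoder output is
#'   `2 * gru_hidden` when `use_bigru`.
#' @param n_slots Number of shared rows `n` of the common-sequence matrix
#'   `C`; 0 reduces the attention to vanilla self-attention.
#' @param p Width of the biaffine start/end representations (default: the
#'   encoder output dimension).
#' @param p_gp Per-channel global-pointer width; must be even (default:
#'   encoder output dimension, rounded down to even).
#' @param use_bigru,use_csa,use_bcssa,use_global_pointer Ablation switches:
#'   drop the BiGRU, the common-sequence attention (biaffine then scores raw
#'   encoder output), the whole biaffine branch, or the global pointer
#'   branch. At least one scoring branch must stay on.
#' @param csa_formulation `"slots"` (persistent key/value slots; default) or
#'   `"literal"` (project keys/values through `C`).
#' @param attn_scale `"sqrt_dk"` or `"dk"` score scaling.
#' @param share_ffnn Share one start/end FFNN pair across the three
#'   families instead of one pair per family.
#' @param untyped_entity_matrix Collapse the entity family to one untyped
#'   channel.
#' @param rotary_base Rotary angle base.
#' @param fusion `"sum"` (additive logits) or `"learned_gate"` (sigmoid-
#'   gated convex combination with learnable per-family gates).
#' @param loss `"multilabel_ce"` or `"bce"`.
#' @param max_len Maximum sentence length.
#' @return List of class `model_config`.
#' @export
model_config <- function(schema = default_vte_schema(),
                         vocab,
                         d = 32L, gru_hidden = 16L, n_slots = 4L,
                         p = NULL, p_gp = NULL,
                         use_bigru = TRUE, use_csa = TRUE,
                         use_bcssa = TRUE, use_global_pointer = TRUE,
                         csa_formulation = c("slots", "literal"),
                         attn_scale = c("sqrt_dk", "dk"),
                         share_ffnn = FALSE,
                         untyped_entity_matrix = FALSE,
                         rotary_base = 10000,
                         fusion = c("sum", "learned_gate"),
                         loss = c("multilabel_ce", "bce"),
                         max_len = 256L) {
  csa_formulation <- match.arg(csa_formulation)
  attn_scale <- match.arg(attn_scale)
  fusion <- match.arg(fusion)
  loss <- match.arg(loss)
  if (!use_bcssa && !use_global_pointer)
    stop("at least one scoring branch must be enabled")
  dh <- if (use_bigru) 2L * as.integer(gru_hidden) else as.integer(d)
  if (is.null(p)) p <- dh
  if (is.null(p_gp)) p_gp <- dh - (dh %% 2L)
  if (p_gp %% 2L != 0L) stop("p_gp must be even (rotary pairs dimensions)")
  entity_channels <- if (untyped_entity_matrix) "*" else schema$entity_types
  structure(list(schema = schema, vocab = vocab, d = as.integer(d),
                 gru_hidden = as.integer(gru_hidden), dh = dh,
                 n_slots = as.integer(n_slots), p = as.integer(p),
                 p_gp = as.integer(p_gp),
                 use_bigru = isTRUE(use_bigru), use_csa = isTRUE(use_csa),
                 use_bcssa = isTRUE(use_bcssa),
                 use_global_pointer = isTRUE(use_global_pointer),
                 csa_formulation = csa_formulation,
                 attn_scale = attn_scale,
                 share_ffnn = isTRUE(share_ffnn),
                 untyped_entity_matrix = isTRUE(untyped_entity_matrix),
                 entity_channels = entity_channels,
                 rotary_base = rotary_base, fusion = fusion, loss = loss,
                 max_len = as.integer(max_len)),
            class = "model_config")
}

.fam_channels <- function(config) {
  c(ent = length(config$entity_channels),
    sho = length(config$schema$relation_types),
    sto = length(config$schema$relation_types))
}

#' Initialize model parameters
#'
#' Gaussian initialization scaled by fan-in for weight matrices, zeros for
#' biases and the biaffine tensors' bias terms; deterministic given `seed`.
#'
#' @param config A `model_config`.
#' @param seed Integer seed.
#' @return Named list of parameter arrays.
#' @export
init_params <- function(config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rmat <- function(a, b, sd = 1 / sqrt(a))
    matrix(stats::rnorm(a * b, sd = sd), a, b)
  d <- config$d; g <- config$gru_hidden; dh <- config$dh
  p <- config$p; pg <- config$p_gp
  P <- list(emb = rmat(length(config$vocab) + 1L, d, sd = 0.5))
  if (config$use_bigru) {
    for (dir in c("f", "b")) {
      P[[paste0("gru_", dir, "_Wx")]] <- rmat(d, 3L * g)
      P[[paste0("gru_", dir, "_Wh")]] <- rmat(g, 3L * g)
      P[[paste0("gru_", dir, "_bx")]] <- numeric(3L * g)
      P[[paste0("gru_", dir, "_bh")]] <- numeric(3L * g)
    }
  }
  chans <- .fam_channels(config)
  if (config$use_bcssa) {
    if (config$use_csa) {
      P$csa_Wq <- rmat(dh, dh); P$csa_Wk <- rmat(dh, dh)
      P$csa_Wv <- rmat(dh, dh)
      P$csa_C <- rmat(max(config$n_slots, 0L), dh)
      if (config$n_slots == 0L) P$csa_C <- matrix(0, 0L, dh)
    }
    keys <- if (config$share_ffnn) "all" else names(chans)
    for (key in keys) {
      P[[paste0("ffnn_s_", key, "_W")]] <- rmat(dh, p)
      P[[paste0("ffnn_s_", key, "_b")]] <- numeric(p)
      P[[paste0("ffnn_e_", key, "_W")]] <- rmat(dh, p)
      P[[paste0("ffnn_e_", key, "_b")]] <- numeric(p)
    }
    for (fam in names(chans)) {
      P[[paste0("biaff_U_", fam)]] <-
        array(stats::rnorm((p + 1L)^2 * chans[[fam]], sd = 1 / (p + 1L)),
              dim = c(p + 1L, p + 1L, chans[[fam]]))
      P[[paste0("biaff_b_", fam)]] <- numeric(chans[[fam]])
    }
  }
  if (config$use_global_pointer) {
    for (fam in names(chans)) {
      cc <- chans[[fam]]
      P[[paste0("gp_Wq_", fam)]] <- rmat(dh, cc * pg)
      P[[paste0("gp_bq_", fam)]] <- numeric(cc * pg)
      P[[paste0("gp_Wk_", fam)]] <- rmat(dh, cc * pg)
      P[[paste0("gp_bk_", fam)]] <- numeric(cc * pg)
    }
  }
  if (config$fusion == "learned_gate" && config$use_bcssa &&
      config$use_global_pointer)
    P$fuse_gate <- c(entity = 0, sub_head_obj_head = 0,
                     sub_tail_obj_tail = 0)
  P
}

.fam2field <- c(ent = "entity", sho = "sub_head_obj_head",
                sto = "sub_tail_obj_tail")

#' Forward pass: token sequence to fused global matrices
#'
#' @param tokens Character vector of tokens (length `1..max_len`).
#' @param params Parameter list from [init_params()] or training.
#' @param config A `model_config`.
#' @param pos_offset Constant added to all rotary positions (used to probe
#'   the relative-position property; scores are invariant to it).
#' @param keep_cache Keep intermediate activations for backprop.
#' @return List with `matrices` (a `global_matrices`) and, when requested,
#'   `cache`.
#' @export
model_forward <- function(tokens, params, config, pos_offset = 0L,
                          keep_cache = FALSE) {
  s <- length(tokens)
  if (s < 1L || s > config$max_len)
    stop("sentence length must be in 1..", config$max_len)
  ids <- .token_ids(tokens, config$vocab)
  E <- params$emb[ids, , drop = FALSE]
  cache <- list(ids = ids, E = E, s = s)
  if (config$use_bigru) {
    bg <- .bigru_forward(E, params)
    H <- bg$H
    cache$bigru <- bg
  } else H <- E
  cache$H <- H
  chans <- .fam_channels(config)
  bcssa_m <- NULL
  if (config$use_bcssa) {
    if (config$use_csa) {
      csa <- .csa_forward(H, params, config$csa_formulation,
                          config$attn_scale)
      O <- csa$O
      cache$csa <- csa
    } else O <- H
    cache$O <- O
    fams <- list()
    for (fam in names(chans)) {
      key <- if (config$share_ffnn) "all" else fam
      bf <- .biaffine_forward(O, params, fam, key)
      fams[[fam]] <- bf
    }
    cache$biaff <- fams
    bcssa_m <- global_matrices(fams$ent$G, fams$sho$G, fams$sto$G,
                               config$entity_channels,
                               config$schema$relation_types)
  }
  gp_m <- NULL
  if (config$use_global_pointer) {
    positions <- (seq_len(s) - 1L) + pos_offset
    gpc <- list()
    for (fam in names(chans)) {
      fw <- .gp_family_forward(H, params[[paste0("gp_Wq_", fam)]],
                               params[[paste0("gp_bq_", fam)]],
                               params[[paste0("gp_Wk_", fam)]],
                               params[[paste0("gp_bk_", fam)]],
                               chans[[fam]], config$p_gp,
                               config$rotary_base, positions)
      gpc[[fam]] <- fw
    }
    cache$gp <- gpc
    gp_m <- global_matrices(gpc$ent$G, gpc$sho$G, gpc$sto$G,
                            config$entity_channels,
                            config$schema$relation_types)
  }
  gates <- if (!is.null(params$fuse_gate)) params$fuse_gate else
    c(entity = 0, sub_head_obj_head = 0, sub_tail_obj_tail = 0)
  final <- fuse_matrices(bcssa_m, gp_m, method = config$fusion,
                         gates = gates)
  cache$bcssa_m <- bcssa_m
  cache$gp_m <- gp_m
  out <- list(matrices = final)
  if (keep_cache) out$cache <- cache
  out
}

.acc_grads <- function(acc, new) {
  for (nm in names(new))
    acc[[nm]] <- if (is.null(acc[[nm]])) new[[nm]] else acc[[nm]] + new[[nm]]
  acc
}

#' Backward pass: matrix-cell gradients to parameter gradients
#'
#' @param dfinal Named list of gradient arrays w.r.t. the fused matrices
#'   (fields `entity`, `sub_head_obj_head`, `sub_tail_obj_tail`).
#' @param cache Cache from [model_forward()] with `keep_cache = TRUE`.
#' @param params Parameter list.
#' @param config A `model_config`.
#' @return Named list of gradients, same shapes as the parameters used.
#' @export
model_backward <- function(dfinal, cache, params, config) {
  grads <- list()
  both <- config$use_bcssa && config$use_global_pointer
  gated <- config$fusion == "learned_gate" && both
  d_bcssa <- d_gp <- dfinal
  if (gated) {
    gate_grad <- params$fuse_gate * 0
    for (fam in names(.fam2field)) {
      f <- .fam2field[[fam]]
      gsig <- 1 / (1 + exp(-params$fuse_gate[[f]]))
      d_bcssa[[f]] <- dfinal[[f]] * gsig
      d_gp[[f]] <- dfinal[[f]] * (1 - gsig)
      gate_grad[[f]] <- sum(dfinal[[f]] *
                              (cache$bcssa_m[[f]] - cache$gp_m[[f]])) *
        gsig * (1 - gsig)
    }
    grads$fuse_gate <- gate_grad
  }
  s <- cache$s
  dH <- matrix(0, s, ncol(cache$H))
  if (config$use_bcssa) {
    dO <- matrix(0, s, ncol(cache$O))
    for (fam in names(cache$biaff)) {
      bb <- .biaffine_backward(d_bcssa[[.fam2field[[fam]]]],
                               cache$biaff[[fam]], params)
      grads <- .acc_grads(grads, bb$grads)
      dO <- dO + bb$dO
    }
    if (config$use_csa) {
      cb <- .csa_backward(dO, cache$csa, params)
      grads <- .acc_grads(grads, cb$grads)
      dH <- dH + cb$dH
    } else dH <- dH + dO
  }
  if (config$use_global_pointer) {
    for (fam in names(cache$gp)) {
      gb <- .gp_family_backward(d_gp[[.fam2field[[fam]]]], cache$gp[[fam]],
                                params[[paste0("gp_Wq_", fam)]],
                                params[[paste0("gp_Wk_", fam)]])
      g <- list(); g[[paste0("gp_Wq_", fam)]] <- gb$dWq
      g[[paste0("gp_bq_", fam)]] <- gb$dbq
      g[[paste0("gp_Wk_", fam)]] <- gb$dWk
      g[[paste0("gp_bk_", fam)]] <- gb$dbk
      grads <- .acc_grads(grads, g)
      dH <- dH + gb$dH
    }
  }
  if (config$use_bigru) {
    bb <- .bigru_backward(dH, cache$bigru, params)
    grads <- .acc_grads(grads, bb$grads)
    dE <- bb$dE
  } else dE <- dH
  demb <- matrix(0, nrow(params$emb), ncol(params$emb))
  for (t in seq_len(s))
    demb[cache$ids[t], ] <- demb[cache$ids[t], ] + dE[t, ]
  grads$emb <- demb
  grads
}

#' Extract entities and triples from raw sentences with a trained model
#'
#' @param model A trained model (list with `params` and `config`, as
#'   returned by [train_model()]).
#' @param sentences List of `annotated_sentence` objects or character
#'   strings/token vectors.
#' @param threshold Decoding threshold.
#' @return List of `annotated_sentence` objects carrying predicted entities
#'   and triples.
#' @export
predict_sentences <- function(model, sentences, threshold = 0) {
  lapply(sentences, function(sent) {
    tokens <- if (inherits(sent, "annotated_sentence")) sent$tokens
    else if (length(sent) == 1L) strsplit(sent, "")[[1]] else sent
    M <- model_forward(tokens, model$params, model$config)$matrices
    decode_sentence(tokens, M, threshold)
  })
}
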