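#' Encoder configuration
#'
#' The encoder maps a token sequence to contextual vectors: an embedding
#' backend followed by an optional single-layer bidirectional GRU. The
#' `lookup` backend is a trainable embedding table over a closed character
#' vocabulary (unknown tokens map to a shared UNK row); it is the desk-scale
#' backend on which the whole pipeline trains on a CPU in minutes. A
#' pretrained contextual encoder is the production-faithful alternative; it
#' is pluggable via `embed_fn` (a function `tokens -> s x d matrix`) and is
#' not required by any computation in this package.
#'
#' @param backend `"lookup"` or `"pretrained"`.
#' @param d Embedding dimension.
#' @param gru_hidden Hidden size of each GRU direction; the BiGRU output
#'   dimension is `2 * gru_hidden`.
#' @param use_bigru Ablation switch; `FALSE` makes contextualization the
#'   identity.
#' @param vocab Character vector of known tokens (lookup backend).
#' @param embed_fn Optional embedding function (pretrained backend).
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(backend = c("lookup", "pretrained"), d = 32L,
                           gru_hidden = 16L, use_bigru = TRUE,
                           vocab = NULL, embed_fn = NULL) {
  backend <- match.arg(backend)
  stopifnot(d >= 1, gru_hidden >= 1)
  if (backend == "lookup" && is.null(vocab))
    stop("lookup backend requires a vocab")
  if (backend == "pretrained" && is.null(embed_fn))
    stop("pretrained backend requires an embed_fn")
  structure(list(backend = backend, d = as.integer(d),
                 gru_hidden = as.integer(gru_hidden),
                 use_bigru = isTRUE(use_bigru), vocab = vocab,
                 embed_fn = embed_fn),
            class = "encoder_config")
}

# token ids: position in vocab, UNK -> length(vocab) + 1
.token_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- length(vocab) + 1L
  ids
}

#' Embed a token sequence
#'
#' @param tokens Nonempty character vector of tokens.
#' @param config An `encoder_config`.
#' @param emb Embedding table `(vocab size + 1) x d` (lookup backend); the
#'   final row is the UNK embedding.
#' @return Matrix `s x d`, one row per token.
#' @export
embed_tokens <- function(tokens, config, emb = NULL) {
  if (length(tokens) < 1L) stop("cannot embed an empty token sequence")
  if (config$backend == "pretrained") {
    out <- config$embed_fn(tokens)
    stopifnot(nrow(out) == length(tokens))
    return(out)
  }
  stopifnot(!is.null(emb))
  emb[.token_ids(tokens, config$vocab), , drop = FALSE]
}

# single-direction GRU forward over rows of E; returns hidden states and the
# caches backprop needs. Gate layout in the 3g columns: [z | r | n].
.gru_forward <- function(E, Wx, Wh, bx, bh) {
  s <- nrow(E); g <- ncol(Wh) / 3L
  zi <- 1:g; ri <- (g + 1):(2 * g); ni <- (2 * g + 1):(3 * g)
  A <- E %*% Wx
  A <- sweep(A, 2, bx, "+")
  H <- matrix(0, s, g); Z <- matrix(0, s, g); Rr <- matrix(0, s, g)
  Nn <- matrix(0, s, g); Mn <- matrix(0, s, g)
  h <- numeric(g)
  for (t in seq_len(s)) {
    m <- drop(h %*% Wh) + bh
    z <- 1 / (1 + exp(-(A[t, zi] + m[zi])))
    r <- 1 / (1 + exp(-(A[t, ri] + m[ri])))
    mn <- m[ni]
    n <- tanh(A[t, ni] + r * mn)
    hn <- (1 - z) * n + z * h
    Z[t, ] <- z; Rr[t, ] <- r; Nn[t, ] <- n; Mn[t, ] <- mn; H[t, ] <- h
    h <- hn
  }
  # H holds h_{t-1}; the output states are rows 2..s of H plus final h
  Hout <- rbind(H[-1, , drop = FALSE], h)
  list(H = Hout, Hprev = H, Z = Z, R = Rr, N = Nn, Mn = Mn, E = E)
}

.gru_backward <- function(dH, cache, Wx, Wh) {
  s <- nrow(dH); g <- ncol(dH)
  zi <- 1:g; ri <- (g + 1):(2 * g); ni <- (2 * g + 1):(3 * g)
  dA <- matrix(0, s, 3 * g)
  dM <- matrix(0, s, 3 * g)
  dh <- numeric(g)
  for (t in s:1) {
    dht <- dH[t, ] + dh
    z <- cache$Z[t, ]; r <- cache$R[t, ]; n <- cache$N[t, ]
    mn <- cache$Mn[t, ]; hp <- cache$Hprev[t, ]
    dz <- dht * (hp - n)
    dn <- dht * (1 - z)
    dh <- dht * z
    dnp <- dn * (1 - n^2)
    dmn <- dnp * r
    dr <- dnp * mn
    dzp <- dz * z * (1 - z)
    drp <- dr * r * (1 - r)
    dA[t, zi] <- dzp; dA[t, ri] <- drp; dA[t, ni] <- dnp
    dM[t, zi] <- dzp; dM[t, ri] <- drp; dM[t, ni] <- dmn
    dh <- dh + drop(dM[t, ] %*% t(Wh))
  }
  list(dWx = crossprod(cache$E, dA),
       dWh = crossprod(cache$Hprev, dM),
       dbx = colSums(dA),
       dbh = colSums(dM),
       dE = dA %*% t(Wx))
}

#' Contextualize embedded vectors with a bidirectional GRU
#'
#' Position `t` of the output concatenates the forward GRU state (a function
#' of tokens `1..t` only) and the backward GRU state (a function of tokens
#' `t..s` only). With `use_bigru = FALSE` this is the identity (the ablation
#' contract).
#'
#' @param E Matrix `s x d` of embedded tokens.
#' @param config An `encoder_config`.
#' @param params Named list holding `gru_f_Wx`, `gru_f_Wh`, `gru_f_bx`,
#'   `gru_f_bh` and the `gru_b_*` counterparts.
#' @return Matrix `s x (2 * gru_hidden)` (or `E` unchanged).
#' @export
contextualize <- function(E, config, params) {
  if (nrow(E) < 1L) stop("empty input")
  if (!config$use_bigru) return(E)
  .bigru_forward(E, params)$H
}

.bigru_forward <- function(E, params) {
  f <- .gru_forward(E, params$gru_f_Wx, params$gru_f_Wh,
                    params$gru_f_bx, params$gru_f_bh)
  Erev <- E[nrow(E):1, , drop = FALSE]
  b <- .gru_forward(Erev, params$gru_b_Wx, params$gru_b_Wh,
                    params$gru_b_bx, params$gru_b_bh)
  H <- cbind(f$H, b$H[nrow(E):1, , drop = FALSE])
  list(H = H, f = f, b = b)
}

.bigru_backward <- function(dH, cache, params) {
  s <- nrow(dH); g <- ncol(dH) / 2L
  dHf <- dH[, 1:g, drop = FALSE]
  dHb <- dH[, (g + 1):(2 * g), drop = FALSE][s:1, , drop = FALSE]
  gf <- .gru_backward(dHf, cache$f, params$gru_f_Wx, params$gru_f_Wh)
  gb <- .gru_backward(dHb, cache$b, params$gru_b_Wx, params$gru_b_Wh)
  list(grads = list(gru_f_Wx = gf$dWx, gru_f_Wh = gf$dWh,
                    gru_f_bx = gf$dbx, gru_f_bh = gf$dbh,
                    gru_b_Wx = gb$dWx, gru_b_Wh = gb$dWh,
                    gru_b_bx = gb$dbx, gru_b_bh = gb$dbh),
       dE = gf$dE + gb$dE[s:1, , drop = FALSE])
}
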