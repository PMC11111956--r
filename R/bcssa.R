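.softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  A <- exp(S - m)
  A / rowSums(A)
}

#' Common-sequence self-attention
#'
#' Scaled dot-product self-attention augmented with a learnable,
#' input-independent shared matrix `C` (`n x d`) that captures corpus-wide
#' features. In the default `"slots"` formulation `C` contributes `n`
#' persistent key/value slots: keys are `rbind(K, C)`, values `rbind(V, C)`,
#' so every query attends over the `s` tokens plus the `n` shared slots and
#' the output stays `s x d`. With `n = 0` the layer reduces exactly to
#' vanilla self-attention. The `"literal"` formulation instead projects keys
#' and values through `C` (`K %*% t(C)`, `V %*% t(C)`) and maps the attended
#' value back to `d` via `C`; it is retained as a best-effort reading of the
#' projected-key algebra but `"slots"` is the default.
#'
#' @param H Matrix `s x d` of input vectors.
#' @param params Named list with `csa_Wq`, `csa_Wk`, `csa_Wv` (`d x d`) and
#'   `csa_C` (`n x d`; zero-row matrix for `n = 0`).
#' @param formulation `"slots"` or `"literal"`.
#' @param attn_scale `"sqrt_dk"` (default, divides scores by `sqrt(d_k)`) or
#'   `"dk"` (divides by `d_k`).
#' @param return_attention If `TRUE`, attach the attention weight matrix as
#'   attribute `"attention"`.
#' @return Matrix `s x d`.
#' @export
common_sequence_attention <- function(H, params,
                                      formulation = c("slots", "literal"),
                                      attn_scale = c("sqrt_dk", "dk"),
                                      return_attention = FALSE) {
  formulation <- match.arg(formulation)
  attn_scale <- match.arg(attn_scale)
  fw <- .csa_forward(H, params, formulation, attn_scale)
  out <- fw$O
  if (return_attention) attr(out, "attention") <- fw$A
  out
}

.csa_forward <- function(H, params, formulation, attn_scale) {
  d <- ncol(H)
  if (ncol(params$csa_Wq) != d || nrow(params$csa_Wq) != d)
    stop("attention weight dimensions do not match input dimension ", d)
  if (nrow(params$csa_C) > 0 && ncol(params$csa_C) != d)
    stop("shared matrix column count must equal input dimension ", d)
  sc <- if (attn_scale == "sqrt_dk") sqrt(d) else d
  Q <- H %*% params$csa_Wq
  K <- H %*% params$csa_Wk
  V <- H %*% params$csa_Wv
  C <- params$csa_C
  if (formulation == "slots") {
    KC <- rbind(K, C); VC <- rbind(V, C)
    S <- Q %*% t(KC) / sc
    A <- .softmax_rows(S)
    O <- A %*% VC
    list(O = O, A = A, Q = Q, K = K, V = V, KC = KC, VC = VC, H = H,
         sc = sc, formulation = formulation)
  } else {
    Qc <- Q %*% t(C); Kc <- K %*% t(C); Vc <- V %*% t(C)
    S <- Qc %*% t(Kc) / sc
    A <- .softmax_rows(S)
    B <- A %*% Vc
    O <- B %*% C
    list(O = O, A = A, Q = Q, K = K, V = V, Qc = Qc, Kc = Kc, Vc = Vc,
         B = B, H = H, sc = sc, formulation = formulation)
  }
}

.softmax_rows_backward <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

.csa_backward <- function(dO, cache, params) {
  C <- params$csa_C
  n <- nrow(C)
  s <- nrow(cache$H)
  if (cache$formulation == "slots") {
    dA <- dO %*% t(cache$VC)
    dVC <- crossprod(cache$A, dO)
    dS <- .softmax_rows_backward(dA, cache$A) / cache$sc
    dQ <- dS %*% cache$KC
    dKC <- crossprod(dS, cache$Q)
    dK <- dKC[seq_len(s), , drop = FALSE]
    dV <- dVC[seq_len(s), , drop = FALSE]
    dC <- if (n > 0)
      dKC[s + seq_len(n), , drop = FALSE] +
        dVC[s + seq_len(n), , drop = FALSE]
    else C
  } else {
    dB <- dO %*% t(C)
    dC <- crossprod(cache$B, dO)
    dA <- dB %*% t(cache$Vc)
    dVc <- crossprod(cache$A, dB)
    dS <- .softmax_rows_backward(dA, cache$A) / cache$sc
    dQc <- dS %*% cache$Kc
    dKc <- crossprod(dS, cache$Qc)
    dQ <- dQc %*% C
    dK <- dKc %*% C
    dV <- dVc %*% C
    dC <- dC + crossprod(dQc, cache$Q) + crossprod(dKc, cache$K) +
      crossprod(dVc, cache$V)
  }
  dH <- dQ %*% t(params$csa_Wq) + dK %*% t(params$csa_Wk) +
    dV %*% t(params$csa_Wv)
  list(grads = list(csa_Wq = crossprod(cache$H, dQ),
                    csa_Wk = crossprod(cache$H, dK),
                    csa_Wv = crossprod(cache$H, dV),
                    csa_C = dC),
       dH = dH)
}

#' Biaffine pairwise span scoring
#'
#' Start and end token representations `h_s = tanh(O W_s + b_s)` and
#' `h_e = tanh(O W_e + b_e)` (width `p`) are combined by a biaffine form:
#' cell `(k, i, j) = [h_s(i); 1]^T U_k [h_e(j); 1] + b_k` for each channel
#' `k`; the appended 1 realizes the `(p+1)`-sized bilinear tensor, so linear
#' terms in either argument are absorbed into `U`.
#'
#' @param Hs,He Matrices `s x p` of start/end representations.
#' @param U Array `(p+1, p+1, c)` of bilinear weights.
#' @param b Numeric vector of `c` channel biases.
#' @return Array `(c, s, s)` of scores.
#' @export
biaffine_score <- function(Hs, He, U, b) {
  s <- nrow(Hs); p1 <- ncol(Hs) + 1L; cc <- length(b)
  stopifnot(all(dim(U) == c(p1, p1, cc)))
  Hs1 <- cbind(Hs, 1); He1 <- cbind(He, 1)
  U2 <- matrix(U, nrow = p1)              # p1 x (p1 * c)
  Tm <- Hs1 %*% U2                        # s x (p1 * c)
  G <- array(0, dim = c(cc, s, s))
  for (k in seq_len(cc)) {
    cols <- ((k - 1L) * p1 + 1L):(k * p1)
    G[k, , ] <- Tm[, cols, drop = FALSE] %*% t(He1) + b[k]
  }
  G
}

# forward with cache, weights taken from params by family key
.biaffine_forward <- function(O, params, fam, ffnn_key) {
  Ws <- params[[paste0("ffnn_s_", ffnn_key, "_W")]]
  bs <- params[[paste0("ffnn_s_", ffnn_key, "_b")]]
  We <- params[[paste0("ffnn_e_", ffnn_key, "_W")]]
  be <- params[[paste0("ffnn_e_", ffnn_key, "_b")]]
  U <- params[[paste0("biaff_U_", fam)]]
  b <- params[[paste0("biaff_b_", fam)]]
  Hs <- tanh(sweep(O %*% Ws, 2, bs, "+"))
  He <- tanh(sweep(O %*% We, 2, be, "+"))
  G <- biaffine_score(Hs, He, U, b)
  list(G = G, Hs = Hs, He = He, O = O, U = U, fam = fam,
       ffnn_key = ffnn_key)
}

.biaffine_backward <- function(dG, cache, params) {
  Hs <- cache$Hs; He <- cache$He; U <- cache$U
  s <- nrow(Hs); p1 <- ncol(Hs) + 1L; cc <- dim(dG)[1]
  Hs1 <- cbind(Hs, 1); He1 <- cbind(He, 1)
  U2 <- matrix(U, nrow = p1)
  Tm <- Hs1 %*% U2
  dT <- matrix(0, s, p1 * cc)
  dHe1 <- matrix(0, s, p1)
  db <- numeric(cc)
  for (k in seq_len(cc)) {
    cols <- ((k - 1L) * p1 + 1L):(k * p1)
    dGk <- matrix(dG[k, , ], s, s)
    dT[, cols] <- dGk %*% He1
    dHe1 <- dHe1 + crossprod(dGk, Tm[, cols, drop = FALSE])
    db[k] <- sum(dGk)
  }
  dU2 <- crossprod(Hs1, dT)
  dHs1 <- dT %*% t(U2)
  dHs <- dHs1[, -p1, drop = FALSE] * (1 - Hs^2)
  dHe <- dHe1[, -p1, drop = FALSE] * (1 - He^2)
  Ws <- params[[paste0("ffnn_s_", cache$ffnn_key, "_W")]]
  We <- params[[paste0("ffnn_e_", cache$ffnn_key, "_W")]]
  grads <- list()
  grads[[paste0("biaff_U_", cache$fam)]] <- array(dU2, dim = dim(U))
  grads[[paste0("biaff_b_", cache$fam)]] <- db
  grads[[paste0("ffnn_s_", cache$ffnn_key, "_W")]] <- crossprod(cache$O, dHs)
  grads[[paste0("ffnn_s_", cache$ffnn_key, "_b")]] <- colSums(dHs)
  grads[[paste0("ffnn_e_", cache$ffnn_key, "_W")]] <- crossprod(cache$O, dHe)
  grads[[paste0("ffnn_e_", cache$ffnn_key, "_b")]] <- colSums(dHe)
  list(grads = grads, dO = dHs %*% t(Ws) + dHe %*% t(We))
}
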