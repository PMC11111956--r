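#' Rotary position rotation of row vectors
#'
#' Applies the rotary position transform to each row of `X`: dimensions are
#' paired `(1,2), (3,4), ...` and pair `m` of the row at position `t` is
#' rotated by angle `t * base^(-2(m-1)/p)`. Dot products between rotated
#' queries and keys then depend only on the position difference, never on
#' absolute position.
#'
#' @param X Matrix `s x p`, `p` even.
#' @param positions Integer vector of 0-based token positions (length `s`).
#' @param base Rotary angle base (default 10000).
#' @return Matrix `s x p` of rotated rows.
#' @export
rotary_rotate <- function(X, positions = seq_len(nrow(X)) - 1L,
                          base = 10000) {
  p <- ncol(X)
  if (p %% 2L != 0L) stop("rotary dimension must be even")
  half <- p / 2L
  theta <- base^(-2 * (seq_len(half) - 1) / p)
  ang <- outer(positions, theta)
  cosm <- cos(ang); sinm <- sin(ang)
  odd <- seq(1L, p, 2L); even <- seq(2L, p, 2L)
  R <- X
  R[, odd] <- X[, odd] * cosm - X[, even] * sinm
  R[, even] <- X[, odd] * sinm + X[, even] * cosm
  R
}

.rotary_rotate_backward <- function(dR, positions, base) {
  p <- ncol(dR); half <- p / 2L
  theta <- base^(-2 * (seq_len(half) - 1) / p)
  ang <- outer(positions, theta)
  cosm <- cos(ang); sinm <- sin(ang)
  odd <- seq(1L, p, 2L); even <- seq(2L, p, 2L)
  dX <- dR
  dX[, odd] <- dR[, odd] * cosm + dR[, even] * sinm
  dX[, even] <- -dR[, odd] * sinm + dR[, even] * cosm
  dX
}

# forward pass of the global pointer head for one family.
# Wq, Wk: d x (c*p); bq, bk: c*p. Returns (c, s, s) scores and cache.
.gp_family_forward <- function(H, Wq, bq, Wk, bk, cc, p, base,
                               positions, use_rotary = TRUE) {
  s <- nrow(H)
  Qg <- sweep(H %*% Wq, 2, bq, "+")
  Kg <- sweep(H %*% Wk, 2, bk, "+")
  rotQ <- Qg; rotK <- Kg
  G <- array(0, dim = c(cc, s, s))
  for (k in seq_len(cc)) {
    cols <- ((k - 1L) * p + 1L):(k * p)
    if (use_rotary) {
      rotQ[, cols] <- rotary_rotate(Qg[, cols, drop = FALSE],
                                    positions, base)
      rotK[, cols] <- rotary_rotate(Kg[, cols, drop = FALSE],
                                    positions, base)
    }
    G[k, , ] <- rotQ[, cols, drop = FALSE] %*%
      t(rotK[, cols, drop = FALSE])
  }
  list(G = G, rotQ = rotQ, rotK = rotK, H = H, cc = cc, p = p,
       base = base, positions = positions, use_rotary = use_rotary)
}

.gp_family_backward <- function(dG, cache, Wq, Wk) {
  s <- nrow(cache$H); cc <- cache$cc; p <- cache$p
  dQg <- matrix(0, s, cc * p); dKg <- matrix(0, s, cc * p)
  for (k in seq_len(cc)) {
    cols <- ((k - 1L) * p + 1L):(k * p)
    dGk <- matrix(dG[k, , ], s, s)
    dRotQ <- dGk %*% cache$rotK[, cols, drop = FALSE]
    dRotK <- crossprod(dGk, cache$rotQ[, cols, drop = FALSE])
    if (cache$use_rotary) {
      dQg[, cols] <- .rotary_rotate_backward(dRotQ, cache$positions,
                                             cache$base)
      dKg[, cols] <- .rotary_rotate_backward(dRotK, cache$positions,
                                             cache$base)
    } else {
      dQg[, cols] <- dRotQ
      dKg[, cols] <- dRotK
    }
  }
  list(dWq = crossprod(cache$H, dQg), dbq = colSums(dQg),
       dWk = crossprod(cache$H, dKg), dbk = colSums(dKg),
       dH = dQg %*% t(Wq) + dKg %*% t(Wk))
}

#' Global pointer span/pair scoring
#'
#' Scores every token pair directly from the encoder output: per family and
#' channel, linear query/key maps (`d -> p`) are applied to each position,
#' rotary position rotations are applied, and cell `(k, i, j)` is the dot
#' product of the rotated query at `i` with the rotated key at `j`. By the
#' rotary property the scores are functions of `j - i` and the content
#' vectors only.
#'
#' @param H Matrix `s x d` of encoder outputs.
#' @param params Named list with `gp_Wq_<fam>`, `gp_bq_<fam>`, `gp_Wk_<fam>`,
#'   `gp_bk_<fam>` for the families `ent`, `sho`, `sto`.
#' @param entity_types,relation_types Channel labels.
#' @param p Per-channel query/key width (even).
#' @param base Rotary angle base.
#' @param positions 0-based positions (default `0:(s-1)`); shifting all
#'   positions by a constant leaves the scores unchanged.
#' @param use_rotary If `FALSE`, skip the rotation (identity positions).
#' @return A `global_matrices` of scores.
#' @export
global_pointer_score <- function(H, params, entity_types, relation_types,
                                 p, base = 10000,
                                 positions = seq_len(nrow(H)) - 1L,
                                 use_rotary = TRUE) {
  if (nrow(H) < 1L) stop("empty input")
  fams <- list(ent = length(entity_types), sho = length(relation_types),
               sto = length(relation_types))
  out <- list()
  for (fam in names(fams)) {
    fw <- .gp_family_forward(H, params[[paste0("gp_Wq_", fam)]],
                             params[[paste0("gp_bq_", fam)]],
                             params[[paste0("gp_Wk_", fam)]],
                             params[[paste0("gp_bk_", fam)]],
                             fams[[fam]], p, base, positions, use_rotary)
    out[[fam]] <- fw$G
  }
  global_matrices(out$ent, out$sho, out$sto, entity_types, relation_types)
}
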