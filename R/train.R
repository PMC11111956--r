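#' Training configuration
#'
#' Defaults follow the reference training regime: maximum sentence length
#' 256 tokens, batch size 16, learning rate 1e-4, 100 epochs. For the
#' desk-scale lookup-embedding model trained from scratch a larger learning
#' rate (1e-3) is appropriate, since nothing is pretrained; pass it
#' explicitly.
#'
#' @param batch_size Sentences per optimizer step.
#' @param lr Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param clip Global gradient-norm clip.
#' @param patience Early-stopping patience in epochs without validation-F1
#'   improvement (`Inf` disables early stopping).
#' @param verbose Print one line per epoch.
#' @return List of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, lr = 1e-4, epochs = 100L,
                         seed = 42L, clip = 1.0, patience = Inf,
                         verbose = FALSE) {
  stopifnot(batch_size >= 1, lr > 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 clip = clip, patience = patience,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

.adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.clip_grads <- function(grads, clip) {
  if (!is.finite(clip) || clip <= 0) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (total > clip)
    grads <- lapply(grads, function(g) g * (clip / total))
  grads
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`, on whatever scale (fraction or percent)
#' the inputs share; 0 when both inputs are 0.
#'
#' @param precision,recall Precision and recall.
#' @return F1 on the same scale.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Triple-level precision, recall and F1
#'
#' @param TP,FP,FN Counts of true positives, false positives, false
#'   negatives.
#' @return List with the counts and `precision`, `recall`, `f1` as
#'   percentages; zero denominators yield 0 by convention.
#' @export
triple_metrics <- function(TP, FP, FN) {
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  list(TP = TP, FP = FP, FN = FN,
       precision = 100 * P, recall = 100 * R,
       f1 = 100 * f1_score(P, R))
}

.triple_keys <- function(sentence, typed = TRUE) {
  tr <- sentence_triples(sentence)
  if (nrow(tr) == 0) return(character())
  if (typed)
    paste(tr$sub_start, tr$sub_end, tr$sub_type, tr$relation,
          tr$obj_start, tr$obj_end, tr$obj_type, sep = "|")
  else
    paste(tr$sub_start, tr$sub_end, tr$relation,
          tr$obj_start, tr$obj_end, sep = "|")
}

#' Evaluate predicted against gold triples
#'
#' Exact-match evaluation: a predicted triple counts as a true positive iff
#' its subject span and type, relation, and object span and type all equal a
#' gold triple of the same sentence; each gold triple matches at most one
#' prediction. With `typed = FALSE` entity types are ignored in matching
#' (the convention when the entity family is untyped).
#'
#' @param predicted,gold Aligned lists of `annotated_sentence` objects.
#' @param typed Include entity types in the match.
#' @return A [triple_metrics()] list.
#' @export
evaluate_triples <- function(predicted, gold, typed = TRUE) {
  stopifnot(length(predicted) == length(gold))
  TP <- FP <- FN <- 0L
  for (i in seq_along(gold)) {
    pk <- unique(.triple_keys(predicted[[i]], typed))
    gk <- unique(.triple_keys(gold[[i]], typed))
    tp <- length(intersect(pk, gk))
    TP <- TP + tp
    FP <- FP + length(pk) - tp
    FN <- FN + length(gk) - tp
  }
  triple_metrics(TP, FP, FN)
}

#' Train the joint extraction model
#'
#' Mini-batch Adam over the chosen matrix-cell loss. Gold annotations are
#' encoded once into sign-valued label matrices; each step averages
#' per-sentence gradients over the batch, clips the global gradient norm,
#' and updates all parameters. When a validation corpus is given, triple F1
#' is computed each epoch and the best-scoring parameters are kept
#' (checkpoint-best-by-validation-F1); training stops early after
#' `patience` epochs without improvement. Deterministic given the seed
#' (single-threaded R arithmetic).
#'
#' @param corpus Nonempty list of schema-valid `annotated_sentence`.
#' @param config A `model_config`.
#' @param tcfg A `train_config`.
#' @param val_corpus Optional validation corpus.
#' @param log_file Optional path; one JSON line per epoch is appended.
#' @return List of class `tripletag_model` with `params` (best by
#'   validation F1 if a validation corpus was given, else final), `config`,
#'   `log` (per-epoch data frame) and `best_epoch`.
#' @export
train_model <- function(corpus, config, tcfg = train_config(),
                        val_corpus = NULL, log_file = NULL) {
  if (!length(corpus)) stop("empty corpus")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tcfg$seed)
  params <- init_params(config, seed = tcfg$seed)
  state <- list(t = 0L, m = list(), v = list())
  labels <- lapply(corpus, encode_gold, schema = config$schema,
                   untyped_entity = config$untyped_entity_matrix)
  loss_grad <- if (config$loss == "multilabel_ce") .mce_loss_grad
  else .bce_loss_grad
  n <- length(corpus)
  log <- data.frame(epoch = integer(), loss = numeric(),
                    val_precision = numeric(), val_recall = numeric(),
                    val_f1 = numeric())
  best_f1 <- -Inf; best_params <- params; best_epoch <- NA_integer_
  since_best <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (b0 in seq(1L, n, by = tcfg$batch_size)) {
      idx <- ord[b0:min(b0 + tcfg$batch_size - 1L, n)]
      bgrads <- list()
      for (i in idx) {
        fw <- model_forward(corpus[[i]]$tokens, params, config,
                            keep_cache = TRUE)
        lg <- loss_grad(fw$matrices, labels[[i]])
        if (!is.finite(lg$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (sentence ", i, ")")
        epoch_loss <- epoch_loss + lg$loss
        g <- model_backward(lg$grad, fw$cache, params, config)
        bgrads <- .acc_grads(bgrads, g)
      }
      bgrads <- lapply(bgrads, function(g) g / length(idx))
      bgrads <- .clip_grads(bgrads, tcfg$clip)
      st <- .adam_step(params, bgrads, state, tcfg$lr)
      params <- st$params; state <- st$state
    }
    epoch_loss <- epoch_loss / n
    vp <- vr <- vf <- NA_real_
    if (!is.null(val_corpus)) {
      preds <- predict_sentences(list(params = params, config = config),
                                 val_corpus)
      m <- evaluate_triples(preds, val_corpus,
                            typed = !config$untyped_entity_matrix)
      vp <- m$precision; vr <- m$recall; vf <- m$f1
      if (vf > best_f1) {
        best_f1 <- vf; best_params <- params; best_epoch <- epoch
        since_best <- 0L
      } else since_best <- since_best + 1L
    }
    log[nrow(log) + 1L, ] <- list(epoch, epoch_loss, vp, vr, vf)
    if (!is.null(log_file))
      cat(jsonlite::toJSON(list(epoch = epoch, loss = epoch_loss,
                                val_precision = vp, val_recall = vr,
                                val_f1 = vf), auto_unbox = TRUE,
                           na = "null"),
          "\n", sep = "", file = log_file, append = TRUE)
    if (tcfg$verbose)
      cat(sprintf("epoch %3d  loss %.4f  val F1 %s\n", epoch, epoch_loss,
                  ifelse(is.na(vf), "-", sprintf("%.1f", vf))))
    # stop once validation is perfect or patience is exhausted
    if (!is.null(val_corpus) &&
        (since_best >= tcfg$patience || best_f1 >= 100))
      break
  }
  structure(list(params = if (is.null(val_corpus)) params else best_params,
                 config = config, log = log,
                 best_epoch = if (is.null(val_corpus)) nrow(log)
                 else best_epoch),
            class = "tripletag_model")
}

#' @export
print.tripletag_model <- function(x, ...) {
  cat("<tripletag_model> ", nrow(x$log), " epochs trained", sep = "")
  if (!is.na(x$best_epoch) && length(x$log$val_f1) &&
      any(!is.na(x$log$val_f1)))
    cat("; best val F1 ", sprintf("%.1f", max(x$log$val_f1, na.rm = TRUE)),
        " at epoch ", x$best_epoch, sep = "")
  cat("\n")
  invisible(x)
}
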