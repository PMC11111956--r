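#' Read an annotated corpus from JSONL
#'
#' One JSON object per line with keys `text`, `entities` (objects with
#' `start`, `end_exclusive`, `type`) and `triples` (objects with
#' `subject_idx`, `relation`, `object_idx`, 0-based indices into
#' `entities`). On-disk spans are 0-based half-open; they are converted to
#' the in-memory 0-based inclusive convention here and nowhere else.
#'
#' @param path Path to a JSONL file.
#' @param schema An `re_schema` used to validate every sentence.
#' @param max_len Maximum sentence length accepted.
#' @param signature Signature handling passed to [validate_sentence()].
#' @return List of `annotated_sentence` objects.
#' @export
read_corpus <- function(path, schema, max_len = 256L, signature = "warn") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) stop("line ", i, ": malformed JSON (",
                               conditionMessage(e), ")", call. = FALSE))
    ent <- if (length(rec$entities)) data.frame(
      start = vapply(rec$entities, function(e) as.integer(e$start), 0L),
      end = vapply(rec$entities, function(e)
        as.integer(e$end_exclusive) - 1L, 0L),
      type = vapply(rec$entities, function(e) as.character(e$type), ""),
      stringsAsFactors = FALSE
    ) else NULL
    tri <- if (length(rec$triples)) data.frame(
      sub = vapply(rec$triples, function(t)
        as.integer(t$subject_idx) + 1L, 0L),
      relation = vapply(rec$triples, function(t)
        as.character(t$relation), ""),
      obj = vapply(rec$triples, function(t)
        as.integer(t$object_idx) + 1L, 0L),
      stringsAsFactors = FALSE
    ) else NULL
    sent <- tryCatch(
      annotated_sentence(rec$text, ent, tri),
      error = function(e) stop("line ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    tryCatch(
      validate_sentence(sent, schema, max_len = max_len,
                        signature = signature),
      error = function(e) stop("line ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    out[[i]] <- sent
  }
  out
}

#' Write an annotated corpus to JSONL
#'
#' Inverse of [read_corpus()]: spans are serialized 0-based half-open under
#' keys `start`/`end_exclusive`, triples as 0-based `subject_idx`/
#' `object_idx` into the entity list, with a deterministic field order.
#'
#' @param sentences List of `annotated_sentence` objects.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_corpus <- function(sentences, path) {
  lines <- vapply(sentences, function(s) {
    ent <- lapply(seq_len(nrow(s$entities)), function(i) list(
      start = s$entities$start[i],
      end_exclusive = s$entities$end[i] + 1L,
      type = s$entities$type[i]))
    tri <- lapply(seq_len(nrow(s$triples)), function(i) list(
      subject_idx = s$triples$sub[i] - 1L,
      relation = s$triples$relation[i],
      object_idx = s$triples$obj[i] - 1L))
    jsonlite::toJSON(list(text = paste(s$tokens, collapse = ""),
                          entities = ent, triples = tri),
                     auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
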