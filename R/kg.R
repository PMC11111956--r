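#' Collect all triples of a corpus into one table
#'
#' @param sentences List of `annotated_sentence` (gold or predicted).
#' @return Data frame in the [sentence_triples()] layout, one row per triple
#'   occurrence (duplicates preserved; they become edge support counts).
#' @export
corpus_triples <- function(sentences) {
  do.call(rbind, lapply(sentences, sentence_triples))
}

#' Build a typed knowledge graph from extracted triples
#'
#' Nodes are deduplicated by (surface, type); directed edges are
#' deduplicated by (subject node, relation, object node) with a support
#' count equal to the input multiplicity. Node identifiers are assigned in
#' sorted (surface, type) order, so they are stable across runs for the same
#' content.
#'
#' @param triples Data frame with columns `sub_surface`, `sub_type`,
#'   `relation`, `obj_surface`, `obj_type` (extra columns ignored), e.g.
#'   from [corpus_triples()].
#' @return Object of class `knowledge_graph` with `nodes` (columns `id`,
#'   `surface`, `type`) and `edges` (columns `source_id`, `target_id`,
#'   `relation`, `support`).
#' @export
build_kg <- function(triples) {
  if (is.null(triples) || nrow(triples) == 0) {
    return(structure(list(
      nodes = data.frame(id = character(), surface = character(),
                         type = character(), stringsAsFactors = FALSE),
      edges = data.frame(source_id = character(), target_id = character(),
                         relation = character(), support = integer(),
                         stringsAsFactors = FALSE)),
      class = "knowledge_graph"))
  }
  nodes <- unique(rbind(
    data.frame(surface = triples$sub_surface, type = triples$sub_type,
               stringsAsFactors = FALSE),
    data.frame(surface = triples$obj_surface, type = triples$obj_type,
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$surface, nodes$type), , drop = FALSE]
  nodes <- data.frame(id = paste0("n", seq_len(nrow(nodes))),
                      surface = nodes$surface, type = nodes$type,
                      stringsAsFactors = FALSE)
  nid <- function(surface, type)
    nodes$id[match(paste(surface, type, sep = "\r"),
                   paste(nodes$surface, nodes$type, sep = "\r"))]
  ek <- data.frame(source_id = nid(triples$sub_surface, triples$sub_type),
                   target_id = nid(triples$obj_surface, triples$obj_type),
                   relation = triples$relation, stringsAsFactors = FALSE)
  key <- paste(ek$source_id, ek$relation, ek$target_id, sep = "\r")
  tab <- table(key)
  uniq <- ek[!duplicated(key), , drop = FALSE]
  uniq$support <- as.integer(tab[paste(uniq$source_id, uniq$relation,
                                       uniq$target_id, sep = "\r")])
  uniq <- uniq[order(uniq$source_id, uniq$relation, uniq$target_id), ,
               drop = FALSE]
  rownames(uniq) <- NULL
  structure(list(nodes = nodes, edges = uniq), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Export a knowledge graph as bulk-import CSV files
#'
#' Writes `nodes.csv` (columns `id`, `surface`, `type`) and `edges.csv`
#' (columns `source_id`, `target_id`, `relation`, `support`) in the layout
#' used for graph-database bulk import, UTF-8, deterministic sorted row
#' order.
#'
#' @param kg A `knowledge_graph`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly the two file paths.
#' @export
export_kg_csv <- function(kg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  np <- file.path(out_dir, "nodes.csv")
  ep <- file.path(out_dir, "edges.csv")
  utils::write.csv(kg$nodes, np, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(kg$edges, ep, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(nodes = np, edges = ep))
}

#' Read a knowledge graph back from exported CSV files
#'
#' Inverse of [export_kg_csv()].
#'
#' @param dir Directory holding `nodes.csv` and `edges.csv`.
#' @return A `knowledge_graph`.
#' @export
read_kg_csv <- function(dir) {
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           fileEncoding = "UTF-8")
  edges <- utils::read.csv(file.path(dir, "edges.csv"),
                           stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (nrow(edges)) {
    edges$support <- as.integer(edges$support)
    edges[] <- lapply(edges, function(x)
      if (is.factor(x)) as.character(x) else x)
  } else {
    edges <- data.frame(source_id = character(), target_id = character(),
                        relation = character(), support = integer(),
                        stringsAsFactors = FALSE)
  }
  if (!nrow(nodes))
    nodes <- data.frame(id = character(), surface = character(),
                        type = character(), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "knowledge_graph")
}
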