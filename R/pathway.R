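#' Construct and validate a signaling pathway DAG
#'
#' The pathway is a directed acyclic graph whose nodes are signaling proteins
#' (kinases, phosphotransferases, response regulators) and whose single sink
#' is the transcription factor whose direct regulon anchors the analysis.
#' Nodes carry three pieces of metadata:
#'
#' * `regulon`: the name of the perturbation contrast / regulon measured for
#'   this node (`NA` for nodes without expression data);
#' * `mode`: `"deletion"` (knockout of a dispensable gene; weak effects,
#'   relaxed thresholds) or `"depletion"` (conditional shutoff of an essential
#'   gene; strong effects, strict thresholds), `NA` otherwise;
#' * `hidden`: `TRUE` for postulated regulators without a measured regulon.
#'
#' Every non-hidden node other than the sink must name a regulon source.
#'
#' @param nodes data frame with columns `name` and optionally `regulon`,
#'   `mode`, `hidden`.
#' @param edges data frame with columns `from`, `to`.
#' @param sink name of the sink node.
#' @return A `pathway_graph` object.
#' @export
pathway_graph <- function(nodes, edges, sink) {
  if (is.character(nodes)) nodes <- data.frame(name = nodes)
  rf_require_cols(nodes, "name", "pathway nodes")
  nodes$name <- as.character(nodes$name)
  if (is.null(nodes$regulon)) nodes$regulon <- NA_character_
  if (is.null(nodes$mode)) nodes$mode <- NA_character_
  if (is.null(nodes$hidden)) nodes$hidden <- FALSE
  nodes$hidden <- isTRUE_vec(nodes$hidden)
  if (anyDuplicated(nodes$name))
    rf_validation_error("duplicate node names in pathway")
  rf_require_cols(edges, c("from", "to"), "pathway edges")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  unknown <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(unknown))
    rf_validation_error(sprintf("edge references unknown node(s): %s",
                                paste(unique(unknown), collapse = ", ")))
  if (!sink %in% nodes$name)
    rf_validation_error(sprintf("sink node '%s' not among nodes", sink))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes["name"])
  if (!igraph::is_dag(g)) {
    # name one cycle for the error message
    fas <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, fas[1])
    rf_validation_error(sprintf(
      "pathway is not a DAG: cycle through edge %s -> %s",
      ends[1, 1], ends[1, 2]))
  }
  bad <- nodes$name[!nodes$hidden & is.na(nodes$regulon) & nodes$name != sink]
  if (length(bad))
    rf_validation_error(sprintf(
      "non-hidden node(s) without a regulon source: %s",
      paste(bad, collapse = ", ")))
  structure(list(nodes = nodes[c("name", "regulon", "mode", "hidden")],
                 edges = edges[c("from", "to")],
                 sink = sink),
            class = "pathway_graph")
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(as.character(x)) %in% c("true", "yes", "1")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d nodes, %d edges, sink = %s\n",
              nrow(x$nodes), nrow(x$edges), x$sink))
  hid <- x$nodes$name[x$nodes$hidden]
  if (length(hid)) cat("  hidden nodes:", paste(hid, collapse = ", "), "\n")
  apply(x$edges, 1, function(e) cat(sprintf("  %s -> %s\n", e[1], e[2])))
  invisible(x)
}

pathway_igraph <- function(pathway) {
  igraph::graph_from_data_frame(pathway$edges, directed = TRUE,
                                vertices = pathway$nodes["name"])
}

#' Topological order of a pathway graph
#' @param pathway a `pathway_graph`.
#' @return Character vector of node names, sources first.
#' @export
topological_order <- function(pathway) {
  names(igraph::topo_sort(pathway_igraph(pathway), mode = "out"))
}

pathway_predecessors <- function(pathway, node) {
  pathway$edges$from[pathway$edges$to == node]
}

pathway_successors <- function(pathway, node) {
  pathway$edges$to[pathway$edges$from == node]
}

pathway_sources <- function(pathway) {
  setdiff(pathway$nodes$name, pathway$edges$to)
}

#' Read a pathway configuration file
#'
#' YAML with keys `sink`, `nodes` (list of maps with `name` and optional
#' `regulon`, `mode`, `hidden`) and `edges` (list of two-element lists or
#' `"A -> B"` strings).
#'
#' @param path YAML file.
#' @return A [pathway_graph()].
#' @export
read_pathway_config <- function(path) {
  if (!file.exists(path)) rf_io_error(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$nodes) || is.null(cfg$edges) || is.null(cfg$sink))
    rf_format_error("pathway config needs keys: nodes, edges, sink")
  nodes <- do.call(rbind, lapply(cfg$nodes, function(n) {
    data.frame(name = n$name,
               regulon = n$regulon %||% NA_character_,
               mode = n$mode %||% NA_character_,
               hidden = isTRUE(n$hidden),
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(cfg$edges, function(e) {
    if (is.character(e) && length(e) == 1L)
      e <- trimws(strsplit(e, "->", fixed = TRUE)[[1]])
    if (length(e) != 2L)
      rf_format_error("each edge must be [from, to] or 'from -> to'")
    data.frame(from = e[[1]], to = e[[2]], stringsAsFactors = FALSE)
  }))
  pathway_graph(nodes, edges, cfg$sink)
}

#' Write a pathway configuration file
#' @param pathway a `pathway_graph`.
#' @param path output YAML path.
#' @export
write_pathway_config <- function(pathway, path) {
  nodes <- lapply(seq_len(nrow(pathway$nodes)), function(i) {
    n <- pathway$nodes[i, ]
    out <- list(name = n$name)
    if (!is.na(n$regulon)) out$regulon <- n$regulon
    if (!is.na(n$mode)) out$mode <- n$mode
    if (n$hidden) out$hidden <- TRUE
    out
  })
  edges <- lapply(seq_len(nrow(pathway$edges)), function(i)
    sprintf("%s -> %s", pathway$edges$from[i], pathway$edges$to[i]))
  yaml::write_yaml(list(sink = pathway$sink, nodes = nodes, edges = edges),
                   path)
  invisible(path)
}
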