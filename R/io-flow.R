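#' Write flow-analysis outputs (TSV and DOT)
#'
#' The TSV lists one row per quantity in long form: `record_type`
#' (`node_input`, `missing_input` or `edge_flux`), `from`, `to`, the gene
#' count and the percentage at full precision. The DOT graph labels each
#' edge with its flux percentage and sets the pen width proportional to the
#' flux, so that line thickness reflects the fraction of the total signal
#' carried; nodes with unexplained input get a dashed oval feeding into them
#' labelled with the missing percentage.
#'
#' @param flow a `flow_result` from [quantify_flow()].
#' @param tsv_path output TSV path (or `NULL` to skip).
#' @param dot_path output DOT path (or `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_flow_outputs <- function(flow, tsv_path = NULL, dot_path = NULL) {
  if (!is.null(tsv_path)) rf_write_tsv(flow_as_table(flow), tsv_path)
  if (!is.null(dot_path)) {
    ok <- tryCatch({
      writeLines(flow_as_dot(flow), dot_path)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) rf_io_error(sprintf("cannot write to: %s", dot_path))
  }
  invisible(c(tsv_path, dot_path))
}

flow_as_table <- function(flow) {
  n <- flow$nodes; e <- flow$edges
  rbind(
    data.frame(record_type = "node_input", from = n$node, to = NA_character_,
               genes = n$genes, pct = n$input_pct, stringsAsFactors = FALSE),
    data.frame(record_type = "missing_input",
               from = n$node[!is.na(n$missing_pct)], to = NA_character_,
               genes = n$missing_genes[!is.na(n$missing_pct)],
               pct = n$missing_pct[!is.na(n$missing_pct)],
               stringsAsFactors = FALSE),
    data.frame(record_type = "edge_flux", from = e$from, to = e$to,
               genes = e$genes, pct = e$flux_pct, stringsAsFactors = FALSE))
}

#' Read back a flow table written by [write_flow_outputs()]
#' @param path TSV path.
#' @return Data frame with columns `record_type`, `from`, `to`, `genes`,
#'   `pct`.
#' @export
read_flow_table <- function(path) {
  df <- rf_read_tsv(path)
  rf_require_cols(df, c("record_type", "from", "to", "genes", "pct"),
                  basename(path))
  df
}

flow_as_dot <- function(flow) {
  pen <- function(p) 0.5 + 5 * p / 100
  lines <- c("digraph flow {", "  rankdir=TB;",
             "  node [shape=box];")
  for (i in seq_len(nrow(flow$nodes))) {
    n <- flow$nodes[i, ]
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\\n%.0f%%\"];",
                              n$node, n$node, n$input_pct))
  }
  for (i in seq_len(nrow(flow$edges))) {
    e <- flow$edges[i, ]
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%.0f%%\", penwidth=%.2f];",
      e$from, e$to, e$flux_pct, pen(e$flux_pct)))
  }
  miss <- flow$nodes[!is.na(flow$nodes$missing_pct) &
                     flow$nodes$missing_pct > 0, ]
  for (i in seq_len(nrow(miss))) {
    n <- miss[i, ]
    h <- sprintf("missing_%s", n$node)
    lines <- c(lines,
               sprintf("  \"%s\" [shape=oval, style=dashed, label=\"?\\n%.0f%%\"];",
                       h, n$missing_pct),
               sprintf("  \"%s\" -> \"%s\" [label=\"%.0f%%\", penwidth=%.2f, style=dashed];",
                       h, n$node, n$missing_pct, pen(n$missing_pct)))
  }
  c(lines, "}")
}
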