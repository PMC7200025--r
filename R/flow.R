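#' Percentage overlap between two regulons
#'
#' `100 * |a intersect b| / |denominator set|`, where the denominator is the
#' first regulon (default — "the overlap of a with b"), the second, or their
#' union.
#'
#' @param a,b `regulon` objects.
#' @param denominator `"first"`, `"second"` or `"union"`.
#' @return A list with `pct`, `n_overlap`, `n_denominator` and the
#'   overlapping `members`.
#' @export
overlap_fraction <- function(a, b, denominator = c("first", "second", "union")) {
  denominator <- match.arg(denominator)
  den <- switch(denominator,
                first = a$members,
                second = b$members,
                union = union(a$members, b$members))
  if (length(den) == 0)
    rf_validation_error("undefined overlap: denominator regulon is empty")
  ov <- intersect(a$members, b$members)
  list(pct = 100 * length(ov) / length(den),
       n_overlap = length(ov), n_denominator = length(den),
       members = ov)
}

# Resolve regulons for unmeasured (hidden) pathway nodes by set algebra:
# R = (union of nearest measured ancestors) intersect
#     (union of nearest measured descendants).
# "Nearest measured" follows paths through other unmeasured nodes.
resolve_node_sets <- function(pathway, regulons) {
  nodes <- pathway$nodes$name
  measured <- nodes[nodes %in% names(regulons)]
  sets <- lapply(regulons, function(r) r$members)
  nearest_measured <- function(node, direction) {
    seen <- character(0); frontier <- node; found <- character(0)
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(n)
        if (direction == "up") pathway_predecessors(pathway, n)
        else pathway_successors(pathway, n))))
      nb <- setdiff(nb, seen)
      seen <- c(seen, nb)
      found <- c(found, intersect(nb, measured))
      frontier <- setdiff(nb, measured)
    }
    unique(found)
  }
  for (node in setdiff(nodes, measured)) {
    up <- unique(unlist(sets[nearest_measured(node, "up")]))
    down <- unique(unlist(sets[nearest_measured(node, "down")]))
    sets[[node]] <- intersect(up, down)
  }
  sets
}

#' Quantify information flow through a pathway DAG by regulon overlap
#'
#' With `D` the member set of the direct (sink) regulon, normalized to 100%:
#'
#' * node input: `input(X) = 100 * |R_X intersect D| / |D|`
#' * edge flux: `flux(X -> Y) = 100 * |R_X intersect R_Y intersect D| / |D|`
#' * missing input:
#'   `missing(Y) = 100 * |(R_Y intersect D) \ union of predecessor regulons| / |D|`
#'   (undefined for source nodes and omitted, i.e. `NA`).
#'
#' Because regulons overlap, the sum of the fluxes into a node can exceed its
#' input. All percentages are multiples of `100/|D|`; gene counts are
#' reported alongside and the underlying gene lists are retained for audit.
#' Nodes without a measured regulon (hidden/postulated regulators) are
#' resolved by set algebra as the intersection of their nearest measured
#' ancestors' union with their nearest measured descendants' union.
#'
#' @param pathway a [pathway_graph()].
#' @param regulons named list of `regulon` objects, one per measured node
#'   (names are node names).
#' @param direct the direct regulon (the reference set `D`).
#' @return A `flow_result` with data frames `nodes` (input/missing) and
#'   `edges` (flux), the reference size, and per-item gene lists.
#' @export
quantify_flow <- function(pathway, regulons, direct) {
  D <- direct$members
  if (length(D) == 0) rf_validation_error("direct regulon is empty")
  need <- pathway$nodes$name[!pathway$nodes$hidden &
                             !is.na(pathway$nodes$regulon)]
  missing_reg <- setdiff(need, names(regulons))
  if (length(missing_reg))
    rf_config_error(sprintf("no regulon supplied for node(s): %s",
                            paste(missing_reg, collapse = ", ")))
  if (!pathway$sink %in% names(regulons))
    rf_config_error(sprintf(
      "no regulon supplied for sink '%s': pass the total (union) regulon",
      pathway$sink))
  sets <- resolve_node_sets(pathway, regulons)
  nodes <- pathway$nodes$name
  sources <- pathway_sources(pathway)

  node_genes <- lapply(sets[nodes], function(s) intersect(s, D))
  names(node_genes) <- nodes
  input_pct <- vapply(node_genes, function(g) 100 * length(g) / length(D), 0)

  edges <- pathway$edges
  edge_genes <- lapply(seq_len(nrow(edges)), function(i)
    intersect(intersect(sets[[edges$from[i]]], sets[[edges$to[i]]]), D))
  flux_pct <- vapply(edge_genes, function(g) 100 * length(g) / length(D), 0)

  missing_genes <- lapply(nodes, function(y) {
    if (y %in% sources) return(NULL)
    preds <- pathway_predecessors(pathway, y)
    setdiff(node_genes[[y]], unique(unlist(sets[preds])))
  })
  names(missing_genes) <- nodes
  missing_pct <- vapply(nodes, function(y) {
    if (y %in% sources) NA_real_
    else 100 * length(missing_genes[[y]]) / length(D)
  }, 0)

  structure(list(
    reference = direct,
    reference_size = length(D),
    nodes = data.frame(node = nodes,
                       genes = lengths(node_genes),
                       input_pct = unname(input_pct),
                       missing_genes = vapply(nodes, function(y)
                         if (y %in% sources) NA_integer_
                         else length(missing_genes[[y]]), 0L),
                       missing_pct = unname(missing_pct),
                       is_source = nodes %in% sources,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = edges$from, to = edges$to,
                       genes = lengths(edge_genes),
                       flux_pct = flux_pct,
                       stringsAsFactors = FALSE),
    node_gene_sets = node_genes,
    edge_gene_sets = stats::setNames(edge_genes,
                                     paste(edges$from, edges$to, sep = "->")),
    missing_gene_sets = missing_genes,
    pathway = pathway),
    class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result normalized to %d direct-regulon genes\n",
              x$reference_size))
  cat("node inputs (% of direct regulon):\n")
  n <- x$nodes
  for (i in seq_len(nrow(n)))
    cat(sprintf("  %-10s input %3.0f%%%s\n", n$node[i], n$input_pct[i],
                if (is.na(n$missing_pct[i])) "" else
                  sprintf(", missing %3.0f%%", n$missing_pct[i])))
  cat("edge fluxes:\n")
  e <- x$edges
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s -> %s: %3.0f%%\n", e$from[i], e$to[i], e$flux_pct[i]))
  invisible(x)
}

#' @export
summary.flow_result <- function(object, ...) {
  # integer percentages for reporting; full precision stays in the object
  list(reference_size = object$reference_size,
       node_input_pct = stats::setNames(round(object$nodes$input_pct),
                                        object$nodes$node),
       missing_input_pct = stats::setNames(round(object$nodes$missing_pct),
                                           object$nodes$node),
       edge_flux_pct = stats::setNames(round(object$edges$flux_pct),
                                       paste(object$edges$from,
                                             object$edges$to, sep = "->")))
}

#' Augment a pathway with hidden input nodes where input is unexplained
#'
#' For every node `Y` whose missing-input percentage exceeds
#' `threshold_pct`, a hidden node `missing_Y` is added with an edge into
#' `Y`. The naming is deterministic.
#'
#' @param flow a `flow_result`.
#' @param threshold_pct minimum missing-input percentage (default 0,
#'   i.e. any unexplained input).
#' @return The augmented [pathway_graph()]; the attached percentages are in
#'   `attr(, "hidden_input_pct")`.
#' @export
infer_hidden_inputs <- function(flow, threshold_pct = 0) {
  if (threshold_pct < 0) rf_validation_error("threshold_pct must be >= 0")
  pathway <- flow$pathway
  n <- flow$nodes
  target <- n$node[!is.na(n$missing_pct) & n$missing_pct > threshold_pct]
  if (!length(target)) {
    attr(pathway, "hidden_input_pct") <- stats::setNames(numeric(0),
                                                         character(0))
    return(pathway)
  }
  hidden <- sprintf("missing_%s", target)
  nodes <- rbind(pathway$nodes,
                 data.frame(name = hidden, regulon = NA_character_,
                            mode = NA_character_, hidden = TRUE,
                            stringsAsFactors = FALSE))
  edges <- rbind(pathway$edges,
                 data.frame(from = hidden, to = target,
                            stringsAsFactors = FALSE))
  out <- pathway_graph(nodes, edges, pathway$sink)
  attr(out, "hidden_input_pct") <- stats::setNames(
    n$missing_pct[match(target, n$node)], hidden)
  out
}

#' Build per-node regulons for the information-flux analysis
#'
#' Deletion-mutant nodes showed only moderate transcriptional changes, so the
#' flux analysis also counts their genes left out of the strict regulons
#' because of a too-high p-value: deletion nodes use fold-change-only
#' regulons (p filter off, no operon augmentation), while depletion nodes use
#' the full strict policy with operon augmentation. Every flux regulon is a
#' superset of the corresponding strict regulon.
#'
#' @param records_by_node named list of `differential_table`s, one per node.
#' @param modes named character vector, `"deletion"` or `"depletion"` per
#'   node.
#' @param operons an [operon_map()] or `NULL` (used for depletion nodes).
#' @return Named list of `regulon` objects.
#' @export
build_flux_regulons <- function(records_by_node, modes, operons = NULL) {
  unknown <- setdiff(names(records_by_node), names(modes))
  if (length(unknown))
    rf_config_error(sprintf("no mode given for node(s): %s",
                            paste(unknown, collapse = ", ")))
  out <- lapply(names(records_by_node), function(node) {
    mode <- modes[[node]]
    if (is.na(mode))
      rf_config_error(sprintf("node %s has no contrast mode", node))
    policy <- switch(mode,
      deletion = threshold_policy(min_rpkm = 25, min_abs_log2fc = 0.5,
                                  max_p = 0.25, apply_p_filter = FALSE,
                                  apply_operon_augmentation = FALSE),
      depletion = depletion_policy(),
      rf_config_error(sprintf("unknown mode '%s' for node %s", mode, node)))
    call_regulon(records_by_node[[node]], policy, operons = operons,
                 node = node)
  })
  stats::setNames(out, names(records_by_node))
}
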