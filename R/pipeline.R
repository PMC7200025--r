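#' Load pipeline inputs from a run configuration file
#'
#' The run config is YAML with keys `pathway` (pathway YAML path),
#' `expression` (map of condition name to long-TSV path, one per perturbed
#' node), `peaks`, `annotation` (GFF3), and optionally `operons`. Paths are
#' resolved relative to the config file. Every referenced file must exist at
#' load time.
#'
#' @param path YAML run configuration.
#' @return A named list of loaded inputs suitable for [run_pipeline()].
#' @export
load_run_inputs <- function(path) {
  if (!file.exists(path)) rf_io_error(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
                         else file.path(base, p)
  for (key in c("pathway", "peaks", "annotation")) {
    if (is.null(cfg[[key]]))
      rf_config_error(sprintf("run config is missing key: %s", key))
  }
  need <- c(resolve(cfg$pathway), resolve(cfg$peaks), resolve(cfg$annotation),
            unlist(lapply(cfg$expression, resolve)),
            resolve(cfg$operons))
  absent <- need[!file.exists(need)]
  if (length(absent))
    rf_io_error(sprintf("input file(s) missing: %s",
                        paste(absent, collapse = ", ")))
  pathway <- read_pathway_config(resolve(cfg$pathway))
  conds <- pathway$nodes$regulon[!is.na(pathway$nodes$regulon)]
  missing_expr <- setdiff(conds, names(cfg$expression))
  if (length(missing_expr)) {
    node <- pathway$nodes$name[match(missing_expr[1], pathway$nodes$regulon)]
    rf_config_error(sprintf(
      "no expression file for contrast '%s' (node %s)", missing_expr[1], node))
  }
  list(pathway = pathway,
       expression = stats::setNames(
         lapply(cfg$expression, function(p) read_expression_table(resolve(p))),
         names(cfg$expression)),
       peaks = read_peak_table(resolve(cfg$peaks),
                               dialect = cfg$peak_dialect %||% "tabular"),
       annotation = read_annotation(resolve(cfg$annotation)),
       operons = if (!is.null(cfg$operons))
         read_operon_table(resolve(cfg$operons)) else NULL)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rf_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)), "rf_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates: per-node differential statistics and regulon calling
#' (strict and flux policies), peak filtering and gene assignment, direct
#' regulon construction, information-flow quantification and hidden-input
#' inference. All intermediates are persisted under `out_dir` in a fixed
#' layout (`regulons/`, `binding/`, `flow/`, `report.tsv`, `run_log.yaml`)
#' so that every reported number can be recomputed from the on-disk files by
#' the corresponding module function. Timestamps appear only in the log.
#'
#' @param data named list with `pathway`, `expression` (named list of
#'   [expression_table()] keyed by mutant condition), `peaks`, `annotation`,
#'   and optionally `operons` — either loaded via [load_run_inputs()] or a
#'   `cascade_sim` from [simulate_cascade()].
#' @param out_dir output directory (created).
#' @param wt_condition wild-type condition name (default `"wt"`).
#' @param pseudocount for [compute_differential()].
#' @param min_fold_enrichment,max_q peak filter settings.
#' @param upstream_cap upstream assignment cap (default `Inf`).
#' @param hidden_threshold_pct threshold for [infer_hidden_inputs()].
#' @return Invisibly, a list with the called regulons (strict and flux), the
#'   direct regulon, the binding assignment and the `flow_result`.
#' @export
run_pipeline <- function(data, out_dir, wt_condition = "wt",
                         pseudocount = 1, min_fold_enrichment = 2,
                         max_q = 0.05, upstream_cap = Inf,
                         hidden_threshold_pct = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("regulons", "binding", "flow"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  pw <- data$pathway
  perturbed <- pw$nodes[!is.na(pw$nodes$regulon), ]

  records <- list(); strict <- list(); modes <- character(0)
  for (i in seq_len(nrow(perturbed))) {
    node <- perturbed$name[i]
    cond <- perturbed$regulon[i]
    mode <- perturbed$mode[i]
    tab <- data$expression[[cond]]
    if (is.null(tab))
      rf_config_error(sprintf(
        "no expression table for contrast '%s' (node %s)", cond, node))
    records[[node]] <- run_stage(
      sprintf("differential:%s", node),
      compute_differential(tab, c(cond, wt_condition),
                           pseudocount = pseudocount))
    policy <- if (identical(mode, "depletion")) depletion_policy()
              else deletion_policy()
    strict[[node]] <- run_stage(
      sprintf("call_regulon:%s", node),
      call_regulon(records[[node]], policy, operons = data$operons,
                   node = node))
    modes[node] <- mode
  }
  flux <- run_stage("build_flux_regulons",
                    build_flux_regulons(records, modes,
                                        operons = data$operons))

  # total (sink) regulon: union of the depletion-contrast regulons
  depl <- names(modes)[modes == "depletion"]
  if (!length(depl))
    rf_config_error("pathway defines no depletion node: cannot form the total regulon")
  total <- Reduce(function(a, b) union_regulon(a, b, name = "total"),
                  strict[depl])
  total$node <- "total"

  filtered <- run_stage("filter_peaks",
                        filter_peaks(data$peaks, min_fold_enrichment, max_q))
  assignments <- run_stage("assign_peaks",
                           assign_peaks(filtered, data$annotation,
                                        operons = data$operons,
                                        upstream_cap = upstream_cap))
  direct <- run_stage("direct_regulon",
                      direct_regulon(total, assignments, name = "direct"))
  if (length(direct$members) == 0)
    rf_validation_error("direct regulon is empty: no bound gene is regulated")

  flux[[pw$sink]] <- total
  flow <- run_stage("quantify_flow", quantify_flow(pw, flux, direct))
  augmented <- infer_hidden_inputs(flow, hidden_threshold_pct)

  # persist intermediates
  for (node in names(strict))
    write_regulon(strict[[node]],
                  file.path(out_dir, "regulons",
                            sprintf("%s_strict.tsv", node)))
  for (node in names(flux))
    write_regulon(flux[[node]],
                  file.path(out_dir, "regulons", sprintf("%s_flux.tsv", node)))
  write_regulon(total, file.path(out_dir, "regulons", "total.tsv"))
  write_regulon(direct, file.path(out_dir, "regulons", "direct.tsv"))
  write_peak_table(filtered, file.path(out_dir, "binding", "peaks_filtered.tsv"))
  rf_write_tsv(as.data.frame(assignments),
               file.path(out_dir, "binding", "assignments.tsv"))
  write_flow_outputs(flow, tsv_path = file.path(out_dir, "flow", "flow.tsv"),
                     dot_path = file.path(out_dir, "flow", "flow.dot"))
  write_pathway_config(augmented,
                       file.path(out_dir, "flow", "pathway_augmented.yaml"))

  # report: regulon sizes, pairwise overlaps, missing-input table
  sizes <- data.frame(
    record_type = "regulon_size",
    name = c(names(strict), "total", "direct",
             paste0(names(flux), "_flux")),
    value = c(vapply(strict, length, 0L), length(total$members),
              length(direct$members), vapply(flux, length, 0L)),
    stringsAsFactors = FALSE)
  all_regs <- c(strict, list(total = total, direct = direct))
  pairs <- utils::combn(names(all_regs), 2)
  overlaps <- data.frame(
    record_type = "overlap_pct",
    name = paste(pairs[1, ], pairs[2, ], sep = "|"),
    value = apply(pairs, 2, function(p) {
      a <- all_regs[[p[1]]]
      if (length(a$members) == 0) return(NA_real_)
      overlap_fraction(a, all_regs[[p[2]]], "first")$pct
    }),
    stringsAsFactors = FALSE)
  missing_tab <- data.frame(
    record_type = "missing_input_pct",
    name = flow$nodes$node[!is.na(flow$nodes$missing_pct)],
    value = flow$nodes$missing_pct[!is.na(flow$nodes$missing_pct)],
    stringsAsFactors = FALSE)
  rf_write_tsv(rbind(sizes, overlaps, missing_tab),
               file.path(out_dir, "report.tsv"))

  # machine-readable log of every threshold actually applied
  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    wt_condition = wt_condition,
    pseudocount = pseudocount,
    peak_filter = list(min_fold_enrichment = min_fold_enrichment,
                       max_q = max_q),
    upstream_cap = if (is.finite(upstream_cap)) upstream_cap else "none",
    hidden_threshold_pct = hidden_threshold_pct,
    policies = lapply(strict, function(r) unclass(r$policy)),
    strict_vs_flux_diff = lapply(names(strict), function(n)
      list(node = n,
           flux_only = setdiff(flux[[n]]$members, strict[[n]]$members))))
  names(log$strict_vs_flux_diff) <- names(strict)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))

  invisible(list(records = records, strict = strict, flux = flux,
                 total = total, direct = direct, assignments = assignments,
                 filtered_peaks = filtered, flow = flow,
                 augmented_pathway = augmented, out_dir = out_dir))
}
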