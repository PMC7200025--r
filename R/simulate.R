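#' Default study-style pathway topology
#'
#' The two-component cascade used as the default simulation scaffold: two
#' sensor kinases (DivJ, PleC; deletion contrasts) feed the single-domain
#' response regulator DivK and a postulated parallel regulator; both feed
#' DivL, from where the signal passes through the essential CckA-ChpT
#' phosphorelay (depletion contrasts) to the sink transcription factor CtrA.
#' DivL and the parallel regulator have no measured regulon and are marked
#' hidden.
#'
#' @return A [pathway_graph()].
#' @export
default_pathway <- function() {
  nodes <- data.frame(
    name    = c("DivJ", "PleC", "DivK", "RegX", "DivL", "CckA", "ChpT", "CtrA"),
    regulon = c("divJ_del", "pleC_del", "divK_del", NA, NA,
                "cckA_depl", "chpT_depl", NA),
    mode    = c("deletion", "deletion", "deletion", NA, NA,
                "depletion", "depletion", NA),
    hidden  = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c("DivJ", "PleC", "DivJ", "PleC", "DivK", "RegX", "DivL", "CckA",
             "ChpT"),
    to   = c("DivK", "DivK", "RegX", "RegX", "DivL", "DivL", "CckA", "ChpT",
             "CtrA"),
    stringsAsFactors = FALSE)
  pathway_graph(nodes, edges, sink = "CtrA")
}

#' Configuration for the synthetic cascade generator
#'
#' The defaults emulate the study design the pipeline was built for: a
#' few-thousand-gene genome with a ~90-gene direct (sink) regulon, two
#' biological replicates per condition with log-normal RPKM noise, strong
#' depletion and weaker deletion perturbations, ChIP peaks planted upstream
#' of every direct-regulon gene plus decoys, and random operons over runs of
#' adjacent genes.
#'
#' @param n_genes genome size (default 3000).
#' @param direct_regulon_size number of sink-regulon genes (default 94).
#' @param pathway a [pathway_graph()]; default [default_pathway()].
#' @param edge_transmission named vector of per-edge transmission
#'   probabilities (names `"from->to"`); unnamed scalar applies to all edges
#'   (default 1).
#' @param node_exogenous_fraction named vector of per-node exogenous input
#'   fractions of the direct regulon (default none). Ignored for source
#'   nodes, which always carry the full direct-regulon universe.
#' @param effect_log2_mean,effect_log2_sd distribution of perturbation
#'   effect magnitudes on the log2 scale (defaults 3 and 0.5: responses well
#'   above the 1.3 depletion threshold).
#' @param deletion_effect_scale multiplier applied to effects in deletion
#'   contrasts (default 0.5: weaker knockout responses, still above the 0.5
#'   deletion threshold).
#' @param replicate_noise_sd log2-scale noise between biological replicates
#'   (default 0.15, about an 11% coefficient of variation — tight replicates
#'   are required by the paired design, which has a single degree of
#'   freedom at two replicates).
#' @param n_replicates biological replicates per condition (default 2).
#' @param baseline_log_rpkm_mean,baseline_log_rpkm_sd log2-RPKM baseline
#'   distribution (defaults 8 and 1.5). Direct-regulon genes are floored at
#'   robustly detectable expression (log2 RPKM of at least 6.64, i.e. 4x the
#'   abundance cutoff) so the planted signal is assayable.
#' @param decoy_peak_count ChIP peaks planted away from the direct regulon
#'   (default 100; half of them fail the enrichment/q filters).
#' @param operon_gene_fraction fraction of genes grouped into operons
#'   (default 0.3).
#' @param seed RNG seed.
#' @return A `cascade_sim_config` list.
#' @export
cascade_sim_config <- function(n_genes = 3000,
                               direct_regulon_size = 94,
                               pathway = default_pathway(),
                               edge_transmission = 1,
                               node_exogenous_fraction = numeric(0),
                               effect_log2_mean = 3,
                               effect_log2_sd = 0.5,
                               deletion_effect_scale = 0.5,
                               replicate_noise_sd = 0.15,
                               n_replicates = 2,
                               baseline_log_rpkm_mean = 8,
                               baseline_log_rpkm_sd = 1.5,
                               decoy_peak_count = 100,
                               operon_gene_fraction = 0.3,
                               seed = 1) {
  if (direct_regulon_size > n_genes)
    rf_config_error("direct regulon larger than genome")
  if (n_replicates < 2)
    rf_config_error("need at least 2 replicates for the paired design")
  edge_keys <- paste(pathway$edges$from, pathway$edges$to, sep = "->")
  if (is.null(names(edge_transmission))) {
    if (length(edge_transmission) != 1)
      rf_config_error("edge_transmission must be a scalar or named by edge")
    edge_transmission <- stats::setNames(rep(edge_transmission,
                                             length(edge_keys)), edge_keys)
  } else {
    tr <- stats::setNames(rep(1, length(edge_keys)), edge_keys)
    unknown <- setdiff(names(edge_transmission), edge_keys)
    if (length(unknown))
      rf_config_error(sprintf("edge_transmission names not in pathway: %s",
                              paste(unknown, collapse = ", ")))
    tr[names(edge_transmission)] <- edge_transmission
    edge_transmission <- tr
  }
  if (any(edge_transmission < 0 | edge_transmission > 1))
    rf_config_error("transmission probabilities must be in [0, 1]")
  if (any(node_exogenous_fraction < 0 | node_exogenous_fraction > 1))
    rf_config_error("exogenous fractions must be in [0, 1]")
  structure(list(n_genes = n_genes,
                 direct_regulon_size = direct_regulon_size,
                 pathway = pathway,
                 edge_transmission = edge_transmission,
                 node_exogenous_fraction = node_exogenous_fraction,
                 effect_log2_mean = effect_log2_mean,
                 effect_log2_sd = effect_log2_sd,
                 deletion_effect_scale = deletion_effect_scale,
                 replicate_noise_sd = replicate_noise_sd,
                 n_replicates = n_replicates,
                 baseline_log_rpkm_mean = baseline_log_rpkm_mean,
                 baseline_log_rpkm_sd = baseline_log_rpkm_sd,
                 decoy_peak_count = decoy_peak_count,
                 operon_gene_fraction = operon_gene_fraction,
                 seed = seed),
            class = "cascade_sim_config")
}

# deterministic synthetic genome: one contig, 900 bp genes spaced 300 bp,
# alternating strands -- simple enough for hand-checked peak assignment
synthetic_annotation <- function(n_genes) {
  start <- (seq_len(n_genes) - 1) * 1200 + 301
  gene_annotation(data.frame(
    locus_tag = sprintf("g%04d", seq_len(n_genes)),
    contig = "chr",
    start = start,
    end = start + 899,
    strand = rep(c("+", "-"), length.out = n_genes),
    stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic cascade dataset
#'
#' Signal genes (the direct-regulon universe `D`) are planted at every
#' source node of the pathway; a gene carried by node `X` crosses edge
#' `X -> Y` independently with the edge's transmission probability, and
#' non-source nodes additionally receive exogenous genes (drawn from `D`
#' outside what their predecessors deliver) per their configured fraction.
#' The true regulon of a node is the set of its genes that eventually reach
#' the sink. Perturbing a node shifts the log2 expression of exactly those
#' genes by a signed per-gene effect (direction coherent across contrasts,
#' magnitude from the effect distribution, scaled down for deletion
#' contrasts); replicate RPKM values are log-normal around condition means.
#' A ChIP peak passing the default filters is planted in the upstream
#' intergenic region (summit 75 bp from the gene boundary, strand-aware) of
#' every `D` gene; decoy peaks are planted elsewhere, half of them failing
#' the filters. Operons group random runs of adjacent genes. Everything is
#' reproducible from the seed.
#'
#' @param config a [cascade_sim_config()].
#' @param out_dir if non-`NULL`, write all generated files there (expression
#'   TSV per contrast, peak table, GFF3 annotation, operon table, pathway
#'   YAML and a `truth/` directory).
#' @return A `cascade_sim` list: `truth` (per-node carried/true/exogenous
#'   sets, per-edge transmitted sets, the planted direct regulon and the
#'   implied true `flow_result`), `expression` (one [expression_table()] per
#'   contrast), `peaks`, `annotation`, `operons`, `pathway`, `config`.
#' @export
simulate_cascade <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  pw <- config$pathway
  n_genes <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n_genes))
  annotation <- synthetic_annotation(n_genes)

  D <- sort(sample(genes, config$direct_regulon_size))

  # operons: random runs of 2-4 adjacent genes covering about the requested
  # fraction of the genome
  operons <- list()
  i <- 1L; covered <- 0L
  target <- round(config$operon_gene_fraction * n_genes)
  while (i <= n_genes - 1L && covered < target) {
    if (stats::runif(1) < config$operon_gene_fraction / 3) {
      len <- sample(2:4, 1)
      len <- min(len, n_genes - i + 1L)
      operons[[sprintf("op%04d", length(operons) + 1L)]] <- genes[i:(i + len - 1L)]
      covered <- covered + len
      i <- i + len
    } else i <- i + 1L
  }
  operons <- if (length(operons)) operon_map(operons) else NULL

  # propagate gene memberships source -> sink
  topo <- topological_order(pw)
  sources <- pathway_sources(pw)
  carried <- stats::setNames(vector("list", length(topo)), topo)
  exogenous <- stats::setNames(vector("list", length(topo)), topo)
  passed <- list()  # per edge "from->to"
  for (node in topo) {
    inbound <- character(0)
    for (pred in pathway_predecessors(pw, node)) {
      key <- paste(pred, node, sep = "->")
      pr <- config$edge_transmission[[key]]
      src <- carried[[pred]]
      keep <- src[stats::runif(length(src)) < pr]
      passed[[key]] <- keep
      inbound <- union(inbound, keep)
    }
    if (node %in% sources) {
      carried[[node]] <- D
      exogenous[[node]] <- character(0)
    } else {
      frac <- config$node_exogenous_fraction[node]
      exo <- character(0)
      if (!is.na(frac) && length(frac) && frac > 0) {
        pool <- setdiff(D, inbound)
        n_exo <- min(round(frac * length(D)), length(pool))
        exo <- sample(pool, n_exo)
      }
      exogenous[[node]] <- exo
      carried[[node]] <- union(inbound, exo)
    }
  }
  # true regulon of X = genes at X that eventually reach the sink
  reach <- stats::setNames(vector("list", length(topo)), topo)
  for (node in rev(topo)) {
    if (node == pw$sink) { reach[[node]] <- carried[[node]]; next }
    acc <- character(0)
    for (succ in pathway_successors(pw, node)) {
      key <- paste(node, succ, sep = "->")
      acc <- union(acc, intersect(passed[[key]], reach[[succ]]))
    }
    reach[[node]] <- acc
  }

  # per-gene coherent effect direction; per-(gene, node) magnitudes
  sign_of <- stats::setNames(sample(c(-1, 1), n_genes, replace = TRUE), genes)
  baseline <- stats::rnorm(n_genes, config$baseline_log_rpkm_mean,
                           config$baseline_log_rpkm_sd)
  names(baseline) <- genes
  is_D <- genes %in% D
  baseline[is_D] <- pmax(baseline[is_D], log2(4 * 25))

  n_rep <- config$n_replicates
  noise <- function(n) stats::rnorm(n, 0, config$replicate_noise_sd)
  wt_log2 <- matrix(rep(baseline, n_rep), ncol = n_rep) + noise(n_genes * n_rep)

  perturbable <- pw$nodes[!is.na(pw$nodes$regulon), ]
  expression <- list()
  for (i in seq_len(nrow(perturbable))) {
    node <- perturbable$name[i]
    cond <- perturbable$regulon[i]
    scale <- if (identical(perturbable$mode[i], "deletion"))
      config$deletion_effect_scale else 1
    affected <- genes %in% reach[[node]]
    magnitude <- pmax(abs(stats::rnorm(n_genes, config$effect_log2_mean,
                                       config$effect_log2_sd)), 0.05) * scale
    shift <- ifelse(affected, sign_of * magnitude, 0)
    mut_log2 <- matrix(rep(baseline + shift, n_rep), ncol = n_rep) +
      noise(n_genes * n_rep)
    long <- rbind(
      data.frame(gene_id = rep(genes, n_rep),
                 condition = cond,
                 replicate = rep(seq_len(n_rep), each = n_genes),
                 rpkm = 2^as.vector(mut_log2),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = rep(genes, n_rep),
                 condition = "wt",
                 replicate = rep(seq_len(n_rep), each = n_genes),
                 rpkm = 2^as.vector(wt_log2),
                 stringsAsFactors = FALSE))
    expression[[cond]] <- expression_table(long)
  }

  # peaks upstream of every direct-regulon gene, plus decoys
  ann_D <- annotation[match(D, annotation$locus_tag), ]
  summit1 <- ifelse(ann_D$strand == "+", ann_D$start - 75, ann_D$end + 75)
  planted <- data.frame(
    contig = "chr",
    start = summit1 - 1 - 75,
    end = summit1 - 1 + 76,
    summit = summit1 - 1,
    fold_enrichment = stats::runif(length(D), 2.5, 25),
    q_value = stats::runif(length(D), 1e-6, 0.049),
    stringsAsFactors = FALSE)
  decoys <- NULL
  if (config$decoy_peak_count > 0) {
    contig_len <- max(annotation$end) + 300
    ds <- sort(sample(200:(contig_len - 200), config$decoy_peak_count))
    fail <- seq_len(config$decoy_peak_count) %% 2 == 0
    decoys <- data.frame(
      contig = "chr",
      start = ds - 75, end = ds + 76, summit = ds,
      fold_enrichment = ifelse(fail, stats::runif(length(ds), 0.5, 2),
                               stats::runif(length(ds), 2.5, 25)),
      q_value = ifelse(fail, stats::runif(length(ds), 0.05, 0.5),
                       stats::runif(length(ds), 1e-6, 0.049)),
      stringsAsFactors = FALSE)
  }
  peaks <- peak_table(rbind(planted, decoys))

  truth_regulons <- lapply(topo, function(n) regulon(n, reach[[n]]))
  names(truth_regulons) <- topo
  direct_true <- regulon("direct", D)
  measured <- union(pw$nodes$name[!is.na(pw$nodes$regulon)], pw$sink)
  true_flow <- quantify_flow(pw, truth_regulons[measured], direct_true)

  truth <- list(direct = D, carried = carried, true_sets = reach,
                exogenous = exogenous, transmitted = passed,
                flow = true_flow, baseline_log2 = baseline,
                effect_sign = sign_of)

  out <- structure(list(truth = truth, expression = expression,
                        peaks = peaks, annotation = annotation,
                        operons = operons, pathway = pw, config = config),
                   class = "cascade_sim")
  if (!is.null(out_dir)) write_cascade_sim(out, out_dir)
  out
}

# write every generated file in the formats the readers consume
write_cascade_sim <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(sim$expression))
    write_expression_table(sim$expression[[cond]],
                           file.path(out_dir, sprintf("expression_%s.tsv", cond)))
  write_peak_table(sim$peaks, file.path(out_dir, "peaks.tsv"))
  write_annotation(sim$annotation, file.path(out_dir, "annotation.gff3"))
  if (!is.null(sim$operons))
    write_operon_table(sim$operons, file.path(out_dir, "operons.tsv"))
  write_pathway_config(sim$pathway, file.path(out_dir, "pathway.yaml"))
  truth_dir <- file.path(out_dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  rf_write_tsv(data.frame(gene_id = sim$truth$direct),
               file.path(truth_dir, "direct_regulon.tsv"))
  sets <- sim$truth$true_sets
  rf_write_tsv(data.frame(
    node = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE)),
    file.path(truth_dir, "true_regulons.tsv"))
  write_flow_outputs(sim$truth$flow,
                     tsv_path = file.path(truth_dir, "true_flow.tsv"))
  invisible(out_dir)
}

#' Simulate a protein-decay time course
#'
#' Per-biomass signal `signal0 * 2^(-t / t_half) / growth_factor(t)` with
#' optional exponential growth dilution (`growth_factor(t) = 2^(t / Td)`)
#' and multiplicative log-normal noise. The noiseless truth is stored in
#' `attr(, "truth")`.
#'
#' @param t_half half-life in minutes (`Inf` for a stable protein).
#' @param timepoints minutes, starting at 0.
#' @param signal0 initial signal (default 100).
#' @param growth_doubling_time culture doubling time in minutes, or `NULL`
#'   for no growth.
#' @param noise_sd standard deviation of multiplicative (log) noise.
#' @return A [decay_dataset()] carrying growth factors when growth applies.
#' @export
simulate_decay <- function(t_half, timepoints, signal0 = 100,
                           growth_doubling_time = NULL, noise_sd = 0) {
  if (t_half <= 0) rf_validation_error("t_half must be positive (or Inf)")
  true_total <- signal0 * 2^(-timepoints / t_half)
  gf <- if (is.null(growth_doubling_time)) rep(1, length(timepoints))
        else 2^(timepoints / growth_doubling_time)
  obs <- true_total / gf
  if (noise_sd > 0) {
    eps <- stats::rnorm(length(timepoints), 0, noise_sd)
    eps[1] <- 0  # anchor the t = 0 reference point
    obs <- obs * exp(eps)
  }
  out <- decay_dataset(timepoints, obs,
                       if (is.null(growth_doubling_time)) NULL else gf)
  attr(out, "truth") <- list(t_half = t_half, signal0 = signal0,
                             total = true_total)
  out
}
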