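#' Threshold policy for regulon calling
#'
#' A perturbation regulon is the set of genes whose expression changes when a
#' regulator is deleted or depleted, under three filters: an abundance filter
#' (maximum RPKM across the contrast strictly greater than `min_rpkm`), a
#' fold-change filter (`|log2FC| >= min_abs_log2fc`, inclusive) and a paired
#' t-test filter (`p <= max_p`, inclusive). Depletion contrasts (conditional
#' shutoff of an essential regulator; strong effects) use the strict defaults
#' 1.3 / 0.05; deletion contrasts (knockout of a dispensable regulator; weak
#' effects) use the relaxed 0.5 / 0.25. Operon augmentation — counting genes
#' that share an operon with a regulated gene as part of the regulon — is on
#' for depletion contrasts by default.
#'
#' @param min_rpkm abundance cutoff (strictly greater than), default 25.
#' @param min_abs_log2fc minimum absolute log2 fold change (inclusive).
#' @param max_p maximum paired t-test p-value (inclusive).
#' @param apply_p_filter apply the p-value filter?
#' @param apply_operon_augmentation add co-operonic genes of regulated genes?
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(min_rpkm = 25, min_abs_log2fc = 1.3,
                             max_p = 0.05, apply_p_filter = TRUE,
                             apply_operon_augmentation = FALSE) {
  if (min_rpkm < 0) rf_validation_error("min_rpkm must be >= 0")
  if (min_abs_log2fc < 0) rf_validation_error("min_abs_log2fc must be >= 0")
  if (max_p <= 0 || max_p > 1) rf_validation_error("max_p must be in (0, 1]")
  structure(list(min_rpkm = min_rpkm, min_abs_log2fc = min_abs_log2fc,
                 max_p = max_p, apply_p_filter = apply_p_filter,
                 apply_operon_augmentation = apply_operon_augmentation),
            class = "threshold_policy")
}

#' @rdname threshold_policy
#' @export
depletion_policy <- function() {
  threshold_policy(min_rpkm = 25, min_abs_log2fc = 1.3, max_p = 0.05,
                   apply_p_filter = TRUE, apply_operon_augmentation = TRUE)
}

#' @rdname threshold_policy
#' @export
deletion_policy <- function() {
  threshold_policy(min_rpkm = 25, min_abs_log2fc = 0.5, max_p = 0.25,
                   apply_p_filter = TRUE, apply_operon_augmentation = FALSE)
}

#' Per-gene differential statistics for a paired contrast
#'
#' For each gene, per-replicate-pair log ratios are computed as
#' `d_i = log2(mutant_i + pseudocount) - log2(wildtype_i + pseudocount)`;
#' the reported `log2fc` is their mean and the p-value comes from a two-sided
#' paired t-test on the `d_i` (computed directly from the t statistic,
#' `t = mean(d) / (sd(d)/sqrt(n))`, with `n - 1` degrees of freedom — with
#' the two-replicate design this is 1 df, which is supported). Degenerate
#' cases: if all `d_i` are equal and non-zero the p-value is 0; if all are
#' zero it is 1 (limit behaviour of the statistic). `max_rpkm` is the largest
#' RPKM of the gene across all samples of the contrast, so that a gene fully
#' silenced in the mutant is still assessable.
#'
#' @param table an [expression_table()].
#' @param contrast length-2 character vector `c(mutant, wildtype)` of
#'   condition names.
#' @param pseudocount added to RPKM before log transform (default 1).
#' @return A data frame of class `differential_table` with columns `gene_id`,
#'   `log2fc`, `p_value`, `max_rpkm`, `n_pairs`.
#' @export
compute_differential <- function(table, contrast, pseudocount = 1) {
  stopifnot(length(contrast) == 2)
  if (pseudocount < 0) rf_validation_error("pseudocount must be >= 0")
  mut <- contrast[1]; wt <- contrast[2]
  present <- unique(table$condition)
  if (!all(c(mut, wt) %in% present))
    rf_config_error(sprintf("condition(s) absent from table: %s",
                            paste(setdiff(c(mut, wt), present), collapse = ", ")))
  sub <- table[table$condition %in% c(mut, wt), ]
  reps_m <- sort(unique(sub$replicate[sub$condition == mut]))
  reps_w <- sort(unique(sub$replicate[sub$condition == wt]))
  if (!identical(reps_m, reps_w))
    rf_validation_error(sprintf(
      "pairing error: replicate indices differ between %s and %s", mut, wt))
  reps <- reps_m
  n <- length(reps)
  genes <- sort(unique(sub$gene_id))
  get_mat <- function(cond) {
    m <- matrix(NA_real_, length(genes), n,
                dimnames = list(genes, as.character(reps)))
    s <- sub[sub$condition == cond, ]
    m[cbind(match(s$gene_id, genes), match(s$replicate, reps))] <- s$rpkm
    m
  }
  M <- get_mat(mut); W <- get_mat(wt)
  d <- log2(M + pseudocount) - log2(W + pseudocount)
  log2fc <- rowMeans(d)
  max_rpkm <- pmax(apply(M, 1, max), apply(W, 1, max))
  if (n >= 2) {
    sdd <- apply(d, 1, stats::sd)
    tstat <- log2fc / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    zero_var <- sdd == 0
    p[zero_var & log2fc != 0] <- 0
    p[zero_var & log2fc == 0] <- 1
  } else {
    warning("fewer than 2 replicate pairs: p-values undefined (NA); ",
            "only usable with apply_p_filter = FALSE")
    p <- rep(NA_real_, length(genes))
  }
  out <- data.frame(gene_id = genes, log2fc = unname(log2fc),
                    p_value = unname(p), max_rpkm = unname(max_rpkm),
                    n_pairs = n, stringsAsFactors = FALSE)
  attr(out, "contrast") <- c(mutant = mut, wildtype = wt)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Annotate differential records with pass/fail flags under a policy
#'
#' @param records a `differential_table`.
#' @param policy a [threshold_policy()].
#' @return The records with logical columns `pass_abundance` (max RPKM
#'   strictly above the cutoff), `pass_fc` (inclusive) and `pass_p`
#'   (inclusive; `TRUE` when the filter is disabled).
#' @export
apply_policy <- function(records, policy) {
  records$pass_abundance <- records$max_rpkm > policy$min_rpkm
  records$pass_fc <- abs(records$log2fc) >= policy$min_abs_log2fc
  if (policy$apply_p_filter) {
    if (anyNA(records$p_value))
      rf_validation_error(
        "p-values undefined (fewer than 2 replicate pairs) but apply_p_filter is on")
    records$pass_p <- records$p_value <= policy$max_p
  } else {
    records$pass_p <- TRUE
  }
  records
}

#' Call a regulon from differential records
#'
#' Differential members are genes passing all enabled filters of the policy.
#' With operon augmentation on, every gene sharing an operon with a
#' differential member is added with provenance `"operon"`; the augmentation
#' is a closure (applying it twice changes nothing — operon co-members of
#' augmented genes are already in the same operon).
#'
#' @param records a `differential_table` from [compute_differential()].
#' @param policy a [threshold_policy()].
#' @param operons an [operon_map()] or `NULL`.
#' @param node name for the regulon (the perturbed regulator).
#' @return A `regulon` object.
#' @export
call_regulon <- function(records, policy, operons = NULL, node = "node") {
  records <- apply_policy(records, policy)
  diff_genes <- records$gene_id[records$pass_abundance & records$pass_fc &
                                records$pass_p]
  members <- diff_genes
  provenance <- stats::setNames(rep("differential", length(diff_genes)),
                                diff_genes)
  if (isTRUE(policy$apply_operon_augmentation) && !is.null(operons)) {
    idx <- operon_index(operons)
    hit_ops <- unique(idx[intersect(diff_genes, names(idx))])
    aug <- setdiff(unlist(operons[hit_ops], use.names = FALSE), diff_genes)
    if (length(aug)) {
      members <- c(members, aug)
      provenance <- c(provenance,
                      stats::setNames(rep("operon", length(aug)), aug))
    }
  }
  regulon(node = node, members = members, provenance = provenance,
          table = records, policy = policy)
}

#' Construct a regulon object
#'
#' @param node name of the regulator.
#' @param members character vector of gene ids.
#' @param provenance named character vector tagging each member
#'   (`"differential"`/`"operon"`, or `"direct"`/`"operon"` for direct
#'   regulons); defaults to `"differential"` for all.
#' @param table optional per-gene statistics table.
#' @param policy optional [threshold_policy()] used.
#' @return A `regulon` object.
#' @export
regulon <- function(node, members, provenance = NULL, table = NULL,
                    policy = NULL) {
  members <- unique(as.character(members))
  if (is.null(provenance))
    provenance <- stats::setNames(rep("differential", length(members)),
                                  members)
  provenance <- provenance[members]
  structure(list(node = node, members = members, provenance = provenance,
                 table = table, policy = policy),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  tab <- table(factor(x$provenance))
  cat(sprintf("regulon '%s': %d genes (%s)\n", x$node, length(x$members),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
length.regulon <- function(x) length(x$members)

#' @export
as.data.frame.regulon <- function(x, ...) {
  df <- data.frame(node = x$node, gene_id = x$members,
                   provenance = unname(x$provenance),
                   stringsAsFactors = FALSE)
  if (!is.null(x$table)) {
    i <- match(df$gene_id, x$table$gene_id)
    df$log2fc <- x$table$log2fc[i]
    df$p_value <- x$table$p_value[i]
    df$max_rpkm <- x$table$max_rpkm[i]
  }
  df
}

#' Union of two regulons
#'
#' Set union of members; on provenance conflict, `"differential"` (or
#' `"direct"`) evidence wins over `"operon"`.
#'
#' @param a,b `regulon` objects.
#' @param name name for the union regulon.
#' @return A `regulon`.
#' @export
union_regulon <- function(a, b, name = paste(a$node, b$node, sep = "+")) {
  members <- union(a$members, b$members)
  rank <- function(p) ifelse(p %in% c("differential", "direct"), 2L, 1L)
  prov <- stats::setNames(rep(NA_character_, length(members)), members)
  for (r in list(a, b)) {
    take <- is.na(prov[r$members]) |
      rank(r$provenance) > rank(prov[r$members])
    prov[r$members[take]] <- r$provenance[take]
  }
  regulon(node = name, members = members, provenance = prov)
}

#' Write a regulon as TSV
#' @param x a `regulon`.
#' @param path output path.
#' @export
write_regulon <- function(x, path) rf_write_tsv(as.data.frame(x), path)

#' Read a regulon from TSV
#'
#' Expects columns `node`, `gene_id`, `provenance` (optional extra statistic
#' columns are kept in the table slot).
#'
#' @param path file path.
#' @param node override the node name (default: taken from the file).
#' @return A `regulon`.
#' @export
read_regulon <- function(path, node = NULL) {
  df <- rf_read_tsv(path)
  rf_require_cols(df, "gene_id", basename(path))
  node <- node %||% (if ("node" %in% names(df)) df$node[1] else
                       sub("\\.tsv$", "", basename(path)))
  prov <- if ("provenance" %in% names(df))
    stats::setNames(as.character(df$provenance), df$gene_id)
  else NULL
  regulon(node = node, members = as.character(df$gene_id), provenance = prov,
          table = if (any(c("log2fc", "p_value") %in% names(df))) df else NULL)
}
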