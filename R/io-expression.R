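#' Construct and validate an expression table
#'
#' An expression table holds normalized per-gene expression (RPKM, reads per
#' kilobase of transcript per million mapped reads) for a set of samples, each
#' sample identified by a condition name and a replicate index. The table must
#' be rectangular: every gene has a value in every sample.
#'
#' @param df data frame with columns `gene_id`, `condition`, `replicate`
#'   (positive integer) and `rpkm` (non-negative).
#' @return A validated `expr_table` (a data frame).
#' @export
expression_table <- function(df) {
  rf_require_cols(df, c("gene_id", "condition", "replicate", "rpkm"),
                  "expression table")
  df$gene_id   <- as.character(df$gene_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.integer(df$replicate)
  df$rpkm      <- as.numeric(df$rpkm)
  if (anyNA(df$rpkm))
    rf_validation_error("expression table contains non-numeric rpkm values")
  bad <- which(df$rpkm < 0)
  if (length(bad))
    rf_validation_error(sprintf(
      "negative rpkm at row %d (gene %s, condition %s, replicate %d)",
      bad[1], df$gene_id[bad[1]], df$condition[bad[1]], df$replicate[bad[1]]))
  if (any(df$replicate < 1L))
    rf_validation_error("replicate indices must be positive integers")
  key <- paste(df$gene_id, df$condition, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    rf_validation_error("duplicate (gene, condition, replicate) cells")
  # rectangular: every gene present in every sample
  samp <- unique(paste(df$condition, df$replicate, sep = "\r"))
  tab <- table(df$gene_id)
  if (length(unique(as.integer(tab))) > 1L || any(tab != length(samp)))
    rf_validation_error("expression table is not rectangular: some genes are missing samples")
  rownames(df) <- NULL
  class(df) <- c("expr_table", "data.frame")
  df
}

#' Read an expression table from TSV
#'
#' @param path path to a tab-separated file.
#' @param dialect `"long"` (columns `gene_id`, `condition`, `replicate`,
#'   `rpkm`) or `"wide"` (a `gene_id` column plus one column per sample named
#'   `<condition>_<replicate>`).
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  df <- rf_read_tsv(path)
  if (dialect == "long") {
    rf_require_cols(df, c("gene_id", "condition", "replicate", "rpkm"),
                    basename(path))
    extra <- setdiff(names(df), c("gene_id", "condition", "replicate", "rpkm"))
    if (length(extra))
      warning(sprintf("ignoring unknown column(s): %s",
                      paste(extra, collapse = ", ")))
    expression_table(df[c("gene_id", "condition", "replicate", "rpkm")])
  } else {
    rf_require_cols(df, "gene_id", basename(path))
    samples <- setdiff(names(df), "gene_id")
    m <- regmatches(samples, regexec("^(.*)_([0-9]+)$", samples))
    bad <- samples[vapply(m, length, 1L) == 0L]
    if (length(bad))
      rf_format_error(sprintf(
        "wide sample column(s) not of the form <condition>_<replicate>: %s",
        paste(bad, collapse = ", ")))
    long <- do.call(rbind, lapply(seq_along(samples), function(i) {
      data.frame(gene_id = df$gene_id,
                 condition = m[[i]][2],
                 replicate = as.integer(m[[i]][3]),
                 rpkm = as.numeric(df[[samples[i]]]),
                 stringsAsFactors = FALSE)
    }))
    expression_table(long)
  }
}

#' Write an expression table to TSV (long dialect)
#' @param x an `expr_table`.
#' @param path output path.
#' @export
write_expression_table <- function(x, path) {
  rf_write_tsv(as.data.frame(x)[c("gene_id", "condition", "replicate", "rpkm")],
               path)
}
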