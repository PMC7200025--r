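#' Construct and validate a ChIP peak table
#'
#' Peaks are stored with 0-based half-open coordinates (BED convention);
#' `summit` is an absolute 0-based position inside `[start, end)`. Readers
#' convert 1-based inputs at the boundary so that no other code needs to know
#' which dialect a file used.
#'
#' @param df data frame with columns `contig`, `start`, `end`, `summit`,
#'   `fold_enrichment`, `q_value`. Extra columns are carried through.
#' @return A validated `peak_table` (a data frame).
#' @export
peak_table <- function(df) {
  rf_require_cols(df, c("contig", "start", "end", "summit",
                        "fold_enrichment", "q_value"), "peak table")
  df$contig <- as.character(df$contig)
  for (col in c("start", "end", "summit", "fold_enrichment", "q_value"))
    df[[col]] <- as.numeric(df[[col]])
  bad <- which(df$start >= df$end)
  if (length(bad))
    rf_validation_error(sprintf("peak %d has start >= end (%g >= %g)",
                                bad[1], df$start[bad[1]], df$end[bad[1]]))
  bad <- which(df$summit < df$start | df$summit >= df$end)
  if (length(bad))
    rf_validation_error(sprintf(
      "peak %d has summit %g outside its interval [%g, %g)",
      bad[1], df$summit[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  if (any(df$fold_enrichment <= 0))
    rf_validation_error("fold_enrichment must be positive")
  if (any(df$q_value < 0 | df$q_value > 1))
    rf_validation_error("q_value must lie in [0, 1]")
  rownames(df) <- NULL
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Read a ChIP peak table
#'
#' Two dialects are supported. `"tabular"` is a named-column TSV with 1-based
#' inclusive coordinates (columns `contig`, `start`, `end`, `summit`,
#' `fold_enrichment`, `q_value`), the form in which peak-caller summaries are
#' usually exported; coordinates are converted to 0-based half-open on read.
#' `"bed6plus"` is headerless BED6 plus three extra columns
#' (`fold_enrichment`, `q_value`, summit offset relative to `start`), already
#' 0-based half-open.
#'
#' @param path file path.
#' @param dialect `"tabular"` or `"bed6plus"`.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, dialect = c("tabular", "bed6plus")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    df <- rf_read_tsv(path)
    rf_require_cols(df, c("contig", "start", "end", "summit",
                          "fold_enrichment", "q_value"), basename(path))
    if (nrow(df) == 0)
      return(peak_table(df))
    # 1-based inclusive -> 0-based half-open
    df$start  <- as.numeric(df$start) - 1
    df$summit <- as.numeric(df$summit) - 1
    peak_table(df)
  } else {
    if (!file.exists(path)) rf_io_error(sprintf("file not found: %s", path))
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(raw) == 0 || ncol(raw) < 9)
      rf_format_error("bed6plus requires 9 columns: BED6 + fold_enrichment, q_value, summit offset")
    df <- data.frame(contig = as.character(raw[[1]]),
                     start = as.numeric(raw[[2]]),
                     end = as.numeric(raw[[3]]),
                     name = as.character(raw[[4]]),
                     fold_enrichment = as.numeric(raw[[7]]),
                     q_value = as.numeric(raw[[8]]),
                     summit = as.numeric(raw[[2]]) + as.numeric(raw[[9]]),
                     stringsAsFactors = FALSE)
    peak_table(df)
  }
}

#' Write a peak table
#'
#' `"tabular"` writes 1-based inclusive coordinates; `"bed6plus"` writes BED
#' (0-based half-open, summit as an offset from `start`).
#'
#' @param x a `peak_table`.
#' @param path output path.
#' @param dialect output dialect.
#' @export
write_peak_table <- function(x, path, dialect = c("tabular", "bed6plus")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    out <- as.data.frame(x)
    out$start <- out$start + 1
    out$summit <- out$summit + 1
    rf_write_tsv(out[c("contig", "start", "end", "summit",
                       "fold_enrichment", "q_value")], path)
  } else {
    out <- data.frame(x$contig, x$start, x$end,
                      name = sprintf("peak_%d", seq_len(nrow(x))),
                      score = 0L, strand = ".",
                      x$fold_enrichment, x$q_value, x$summit - x$start)
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) rf_io_error(sprintf("cannot write to: %s", path))
    invisible(path)
  }
}
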