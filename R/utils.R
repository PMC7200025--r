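# Internal helpers: classed conditions so callers (and the CLI) can
# distinguish validation problems from computation failures.

rf_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "regulonflow_error")))
}

rf_format_error     <- function(msg) rf_stop(msg, "rf_format_error")
rf_validation_error <- function(msg) rf_stop(msg, "rf_validation_error")
rf_config_error     <- function(msg) rf_stop(msg, "rf_config_error")
rf_io_error         <- function(msg) rf_stop(msg, "rf_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV conventions: no quoting surprises, "." decimal separator only.
rf_read_tsv <- function(path) {
  if (!file.exists(path)) rf_io_error(sprintf("file not found: %s", path))
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

rf_write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) rf_io_error(sprintf("cannot write to: %s", path))
  invisible(path)
}

rf_require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    rf_format_error(sprintf("%s is missing required column(s): %s",
                            what, paste(missing, collapse = ", ")))
  invisible(TRUE)
}
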