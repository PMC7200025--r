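#' Construct and validate a gene annotation table
#'
#' Gene coordinates follow the GFF3 convention: 1-based inclusive `start` and
#' `end` with `start <= end`, strand `"+"` or `"-"`. Locus tags must be
#' unique.
#'
#' @param df data frame with columns `locus_tag`, `contig`, `start`, `end`,
#'   `strand`.
#' @param contig_lengths optional named vector of contig lengths used to check
#'   that coordinates are in range.
#' @return A validated `gene_annotation` (a data frame).
#' @export
gene_annotation <- function(df, contig_lengths = NULL) {
  rf_require_cols(df, c("locus_tag", "contig", "start", "end", "strand"),
                  "gene annotation")
  df$locus_tag <- as.character(df$locus_tag)
  df$contig <- as.character(df$contig)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$strand <- as.character(df$strand)
  if (anyDuplicated(df$locus_tag))
    rf_validation_error("duplicate locus_tags in annotation")
  if (any(df$start > df$end))
    rf_validation_error("gene with start > end")
  if (any(df$start < 1))
    rf_validation_error("gene coordinates are 1-based; start must be >= 1")
  if (!all(df$strand %in% c("+", "-")))
    rf_validation_error("strand must be '+' or '-'")
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[df$contig]
    if (any(!is.na(len) & df$end > len))
      rf_validation_error("gene end beyond contig length")
  }
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read gene annotation from GFF3
#'
#' Features of type `gene` are used (all features if none are typed `gene`);
#' the locus tag is taken from the `locus_tag` attribute, falling back to
#' `ID`.
#'
#' @param path path to a GFF3 file.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) rf_io_error(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  if ("gene" %in% as.character(gr$type)) gr <- gr[gr$type == "gene"]
  tags <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag)
          else as.character(gr$ID)
  if (is.null(tags) || anyNA(tags))
    rf_format_error("GFF3 features lack locus_tag/ID attributes")
  gene_annotation(data.frame(
    locus_tag = tags,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE))
}

#' Write gene annotation to GFF3
#' @param x a `gene_annotation`.
#' @param path output path.
#' @export
write_annotation <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$contig,
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    strand = x$strand,
    type = "gene",
    ID = x$locus_tag,
    locus_tag = x$locus_tag)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Construct and validate an operon map
#'
#' @param operons named list; each element is the ordered character vector of
#'   locus tags in one operon. Operons must have at least two genes and be
#'   disjoint.
#' @return A validated `operon_map` (a named list).
#' @export
operon_map <- function(operons) {
  if (is.null(names(operons)) || any(names(operons) == ""))
    rf_validation_error("every operon needs an operon_id name")
  operons <- lapply(operons, as.character)
  if (any(vapply(operons, length, 1L) < 2L))
    rf_validation_error("operons must contain at least 2 genes")
  all_genes <- unlist(operons, use.names = FALSE)
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup))
    rf_validation_error(sprintf("gene(s) listed in two operons: %s",
                                paste(unique(dup), collapse = ", ")))
  structure(operons, class = "operon_map")
}

#' Read an operon table
#'
#' Expects a two-column TSV: `operon_id` and a comma-separated `genes` column
#' (DOOR-style export).
#'
#' @param path file path.
#' @return An [operon_map()].
#' @export
read_operon_table <- function(path) {
  df <- rf_read_tsv(path)
  rf_require_cols(df, c("operon_id", "genes"), basename(path))
  ops <- strsplit(as.character(df$genes), ",[ ]*")
  names(ops) <- as.character(df$operon_id)
  operon_map(ops)
}

#' Write an operon table
#' @param x an `operon_map`.
#' @param path output path.
#' @export
write_operon_table <- function(x, path) {
  rf_write_tsv(data.frame(operon_id = names(x),
                          genes = vapply(x, paste, "", collapse = ","),
                          stringsAsFactors = FALSE), path)
}

# operon lookup: named vector gene -> operon_id
operon_index <- function(operons) {
  if (is.null(operons)) return(character(0))
  genes <- unlist(operons, use.names = FALSE)
  stats::setNames(rep(names(operons), vapply(operons, length, 1L)), genes)
}
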