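# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# long expression table from a named list: values[[gene]][[condition]] is a
# vector of replicate RPKMs
make_expr <- function(values) {
  rows <- list()
  for (g in names(values)) {
    for (cond in names(values[[g]])) {
      v <- values[[g]][[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, condition = cond, replicate = seq_along(v), rpkm = v,
        stringsAsFactors = FALSE)
    }
  }
  expression_table(do.call(rbind, rows))
}

# annotation from a compact spec: list of c(tag, strand, start, end)
make_genes <- function(..., contig = "chr") {
  specs <- list(...)
  gene_annotation(data.frame(
    locus_tag = vapply(specs, `[[`, "", 1),
    contig = contig,
    start = as.numeric(vapply(specs, `[[`, "", 3)),
    end = as.numeric(vapply(specs, `[[`, "", 4)),
    strand = vapply(specs, `[[`, "", 2),
    stringsAsFactors = FALSE))
}

make_peaks <- function(summits, contig = "chr", fe = 5, q = 0.001,
                       halfwidth = 50) {
  peak_table(data.frame(
    contig = rep_len(contig, length(summits)),
    start = summits - halfwidth, end = summits + halfwidth + 1,
    summit = summits,
    fold_enrichment = rep_len(fe, length(summits)),
    q_value = rep_len(q, length(summits)),
    stringsAsFactors = FALSE))
}

# a small linear pathway with every node measured, sink last
make_chain_pathway <- function(names, modes = NULL) {
  n <- length(names)
  modes <- modes %||% rep("deletion", n)
  nodes <- data.frame(name = names,
                      regulon = paste0(tolower(names), "_mut"),
                      mode = modes, hidden = FALSE,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = names[-n], to = names[-1],
                      stringsAsFactors = FALSE)
  pathway_graph(nodes, edges, sink = names[n])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent per-gene enumeration oracle for flow quantities: loops over
# genes one by one, no set operations
flow_oracle <- function(pathway, sets, D) {
  in_set <- function(g, s) any(g == s)
  input <- sapply(pathway$nodes$name, function(x) {
    cnt <- 0
    for (g in D) if (in_set(g, sets[[x]])) cnt <- cnt + 1
    100 * cnt / length(D)
  })
  flux <- numeric(nrow(pathway$edges))
  for (i in seq_len(nrow(pathway$edges))) {
    x <- pathway$edges$from[i]; y <- pathway$edges$to[i]
    cnt <- 0
    for (g in D)
      if (in_set(g, sets[[x]]) && in_set(g, sets[[y]])) cnt <- cnt + 1
    flux[i] <- 100 * cnt / length(D)
  }
  sources <- setdiff(pathway$nodes$name, pathway$edges$to)
  missing <- sapply(pathway$nodes$name, function(y) {
    if (y %in% sources) return(NA_real_)
    preds <- pathway$edges$from[pathway$edges$to == y]
    cnt <- 0
    for (g in D) {
      if (!in_set(g, sets[[y]])) next
      covered <- FALSE
      for (p in preds) if (in_set(g, sets[[p]])) covered <- TRUE
      if (!covered) cnt <- cnt + 1
    }
    100 * cnt / length(D)
  })
  list(input = input, flux = flux, missing = missing)
}

# character-level brute-force motif scanner (single strand)
motif_oracle_scan <- function(seq_chr, left, spacer, right) {
  chars <- strsplit(seq_chr, "")[[1]]
  w <- nchar(left) + spacer + nchar(right)
  hits <- integer(0)
  if (length(chars) < w) return(hits)
  lh <- strsplit(left, "")[[1]]; rh <- strsplit(right, "")[[1]]
  for (i in seq_len(length(chars) - w + 1)) {
    ok <- TRUE
    for (j in seq_along(lh)) if (chars[i + j - 1] != lh[j]) { ok <- FALSE; break }
    if (ok) for (j in seq_along(rh))
      if (chars[i + nchar(left) + spacer + j - 1] != rh[j]) { ok <- FALSE; break }
    if (ok) hits <- c(hits, i)
  }
  hits
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
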