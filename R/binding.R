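#' Filter ChIP peaks by fold enrichment and q-value
#'
#' Retains peaks with fold enrichment strictly greater than
#' `min_fold_enrichment` and q-value at most `max_q`, preserving input order.
#'
#' @param peaks a [peak_table()].
#' @param min_fold_enrichment strict lower bound (default 2).
#' @param max_q inclusive upper bound on the FDR q-value (default 0.05).
#' @return The retained subset, still a `peak_table`.
#' @export
filter_peaks <- function(peaks, min_fold_enrichment = 2, max_q = 0.05) {
  keep <- peaks$fold_enrichment > min_fold_enrichment & peaks$q_value <= max_q
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(peaks)
  out
}

#' Classify peaks as genic or intergenic by summit position
#'
#' A peak is genic iff its summit falls within some gene's closed interval
#' `[start, end]` (1-based), intergenic otherwise.
#'
#' @param peaks a [peak_table()] (0-based summits; converted internally).
#' @param annotation a [gene_annotation()].
#' @return Character vector `"genic"`/`"intergenic"`, one per peak.
#' @export
classify_peaks <- function(peaks, annotation) {
  if (nrow(peaks) == 0) return(character(0))
  pos <- peaks$summit + 1  # 0-based -> 1-based
  lvl <- union(peaks$contig, annotation$contig)
  q <- GenomicRanges::GRanges(factor(peaks$contig, levels = lvl),
                              IRanges::IRanges(pos, width = 1))
  s <- GenomicRanges::GRanges(factor(annotation$contig, levels = lvl),
                              IRanges::IRanges(annotation$start,
                                               annotation$end))
  hit <- IRanges::overlapsAny(q, s)
  ifelse(hit, "genic", "intergenic")
}

#' Assign ChIP peaks to genes
#'
#' Assignment is by peak summit. A summit inside a gene gives that gene
#' `in_gene` evidence (a summit inside two overlapping genes hits both). A
#' summit in an intergenic interval gives `upstream` evidence to each
#' flanking gene whose upstream region contains the summit — strand-aware: a
#' `+` gene's upstream region is the intergenic interval before its start, a
#' `-` gene's the interval after its end. A summit between two convergent
#' genes (both pointing toward it) is assigned to neither; between divergent
#' genes it is upstream of both. With `upstream_cap` set, upstream evidence
#' further requires the summit to lie within that many bases of the gene
#' boundary. Finally, every co-operonic gene of a gene with direct
#' (`upstream`/`in_gene`) evidence receives `operon` evidence naming the
#' partner that carries the direct evidence.
#'
#' @param peaks a filtered [peak_table()].
#' @param annotation a [gene_annotation()].
#' @param operons an [operon_map()] or `NULL`.
#' @param upstream_cap maximum distance (bases) from summit to gene boundary
#'   for upstream evidence; `Inf` (default) accepts the whole intergenic
#'   interval.
#' @return A data frame of class `binding_assignment` with columns
#'   `gene_id`, `peak_id`, `mode` (`upstream`/`in_gene`/`operon`) and
#'   `partner` (the direct-evidence gene, for `operon` rows).
#' @export
assign_peaks <- function(peaks, annotation, operons = NULL,
                         upstream_cap = Inf) {
  empty <- data.frame(gene_id = character(0), peak_id = character(0),
                      mode = character(0), partner = character(0),
                      stringsAsFactors = FALSE)
  rows <- list(empty)
  if (nrow(peaks) > 0) {
    peak_id <- sprintf("%s:%g-%g", peaks$contig, peaks$start, peaks$end)
    known <- peaks$contig %in% annotation$contig
    if (any(!known)) {
      warning(sprintf("skipping %d peak(s) on contig(s) absent from annotation: %s",
                      sum(!known),
                      paste(unique(peaks$contig[!known]), collapse = ", ")))
    }
    pos <- peaks$summit + 1  # 1-based summit position
    lvl <- unique(annotation$contig)
    idx_known <- which(known)
    q <- GenomicRanges::GRanges(
      factor(peaks$contig[idx_known], levels = lvl),
      IRanges::IRanges(pos[idx_known], width = 1))
    s <- GenomicRanges::GRanges(factor(annotation$contig, levels = lvl),
                                IRanges::IRanges(annotation$start,
                                                 annotation$end))
    ov <- GenomicRanges::findOverlaps(q, s)
    ov <- S4Vectors::Hits(idx_known[S4Vectors::queryHits(ov)],
                          S4Vectors::subjectHits(ov),
                          nrow(peaks), nrow(annotation), sort.by.query = TRUE)
    if (length(ov))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = annotation$locus_tag[S4Vectors::subjectHits(ov)],
        peak_id = peak_id[S4Vectors::queryHits(ov)],
        mode = "in_gene", partner = NA_character_,
        stringsAsFactors = FALSE)
    genic <- seq_len(nrow(peaks)) %in% S4Vectors::queryHits(ov)
    for (i in which(!genic & known)) {
      ctg <- peaks$contig[i]; p <- pos[i]
      genes <- annotation[annotation$contig == ctg, ]
      genes <- genes[order(genes$start), ]
      # left flank: nearest gene ending before the summit
      left <- genes[genes$end < p, ]
      if (nrow(left)) {
        g <- left[which.max(left$end), ]
        if (g$strand == "-" && (p - g$end) <= upstream_cap)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g$locus_tag, peak_id = peak_id[i],
            mode = "upstream", partner = NA_character_,
            stringsAsFactors = FALSE)
      }
      right <- genes[genes$start > p, ]
      if (nrow(right)) {
        g <- right[which.min(right$start), ]
        if (g$strand == "+" && (g$start - p) <= upstream_cap)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g$locus_tag, peak_id = peak_id[i],
            mode = "upstream", partner = NA_character_,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(operons) && nrow(out)) {
    idx <- operon_index(operons)
    direct <- unique(out$gene_id)
    hit <- intersect(direct, names(idx))
    op_rows <- lapply(hit, function(g) {
      partners <- setdiff(operons[[idx[[g]]]], direct)
      if (!length(partners)) return(NULL)
      pk <- out$peak_id[out$gene_id == g][1]
      data.frame(gene_id = partners, peak_id = pk, mode = "operon",
                 partner = g, stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, op_rows))
  }
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("binding_assignment", "data.frame")
  out
}

#' Genes carrying any binding evidence
#' @param assignments a `binding_assignment`.
#' @return Character vector of gene ids.
#' @export
bound_genes <- function(assignments) unique(assignments$gene_id)

#' Consensus motif with two half-sites and a fixed spacer
#'
#' @param left_halfsite,right_halfsite nucleotide strings over `{A,C,G,T}`.
#' @param spacer_length number of arbitrary bases between the half-sites.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(left_halfsite, spacer_length, right_halfsite) {
  for (h in c(left_halfsite, right_halfsite)) {
    if (nchar(h) == 0 || grepl("[^ACGT]", h))
      rf_validation_error("half-sites must be non-empty strings over A,C,G,T")
  }
  if (spacer_length < 0) rf_validation_error("spacer_length must be >= 0")
  structure(list(left_halfsite = left_halfsite,
                 spacer_length = as.integer(spacer_length),
                 right_halfsite = right_halfsite),
            class = "motif_spec")
}

#' The CtrA-family consensus binding motif TTAA-N7-TTAAC
#' @return A [motif_spec()].
#' @export
ctra_motif <- function() motif_spec("TTAA", 7L, "TTAAC")

motif_length <- function(motif)
  nchar(motif$left_halfsite) + motif$spacer_length +
    nchar(motif$right_halfsite)

#' Scan a sequence for a half-site/spacer consensus motif
#'
#' Finds all (possibly overlapping) occurrences of
#' `left_halfsite . N{spacer} . right_halfsite`. Half-site positions must
#' match exactly; an `N` in the sequence never matches a half-site base but
#' is accepted in the spacer (whose bases are arbitrary). With
#' `both_strands = TRUE` the reverse complement is scanned as well and minus
#' hits are reported in forward coordinates (1-based position of the
#' occurrence's leftmost base).
#'
#' @param sequence character string or [Biostrings::DNAString] over
#'   `{A,C,G,T,N}`.
#' @param motif a [motif_spec()].
#' @param both_strands scan both strands? Default `TRUE`.
#' @return Data frame with columns `position` (1-based) and `strand`.
#' @export
scan_motif <- function(sequence, motif, both_strands = TRUE) {
  seq_chr <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", seq_chr))
    rf_validation_error("sequence must be over A,C,G,T,N")
  pat <- paste0("(?=", motif$left_halfsite,
                "[ACGTN]{", motif$spacer_length, "}",
                motif$right_halfsite, ")")
  find <- function(s) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  fwd <- find(seq_chr)
  out <- data.frame(position = fwd,
                    strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
    rev_hits <- find(rc)
    if (length(rev_hits)) {
      L <- nchar(seq_chr); w <- motif_length(motif)
      out <- rbind(out, data.frame(
        position = L - (rev_hits + w - 1) + 1,
        strand = rep("-", length(rev_hits)),
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the direct regulon by intersecting regulation with binding
#'
#' The direct regulon is the intersection of a (typically operon-augmented)
#' total regulon with the set of genes that carry binding evidence. Each
#' member's provenance records whether its binding evidence is direct
#' (`upstream`/`in_gene` -> `"direct"`) or only operon-mediated
#' (`"operon"`).
#'
#' @param total_regulon a `regulon`.
#' @param assignments a `binding_assignment` from [assign_peaks()].
#' @param name name for the resulting regulon.
#' @return A `regulon` whose provenance tags are `"direct"`/`"operon"`.
#' @export
direct_regulon <- function(total_regulon, assignments, name = "direct") {
  members <- intersect(total_regulon$members, bound_genes(assignments))
  direct_ev <- unique(assignments$gene_id[assignments$mode %in%
                                          c("upstream", "in_gene")])
  prov <- stats::setNames(
    ifelse(members %in% direct_ev, "direct", "operon"), members)
  regulon(node = name, members = members, provenance = prov,
          table = total_regulon$table)
}
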