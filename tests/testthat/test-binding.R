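test_that("peak filtering applies strict fold-enrichment and inclusive q cutoffs", {
  pk <- peak_table(data.frame(
    contig = "chr",
    start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
    summit = c(25, 125, 225, 325),
    fold_enrichment = c(2.0, 3.5, 2.01, 10),
    q_value = c(0.01, 0.06, 0.05, 0.001)))
  kept <- filter_peaks(pk)
  # fe = 2.0 is removed (strictly > 2), q = 0.06 is removed, q = 0.05 kept
  expect_equal(kept$summit, c(225, 325))

  set.seed(3)
  rnd <- peak_table(data.frame(
    contig = "chr", start = seq(0, 990, 10), end = seq(5, 995, 10),
    summit = seq(2, 992, 10),
    fold_enrichment = stats::runif(100, 0.5, 5),
    q_value = stats::runif(100, 0, 0.2)))
  kept <- filter_peaks(rnd, 2, 0.05)
  # brute-force row-by-row oracle
  oracle <- integer(0)
  for (i in seq_len(nrow(rnd)))
    if (rnd$fold_enrichment[i] > 2 && rnd$q_value[i] <= 0.05)
      oracle <- c(oracle, i)
  expect_equal(kept$summit, rnd$summit[oracle])
})

test_that("upstream assignment is strand-aware over intergenic intervals", {
  # tandem + genes: the interval holds A's downstream end and B's promoter
  ann <- make_genes(c("A", "+", 1001, 2000), c("B", "+", 3001, 4000))
  asg <- assign_peaks(make_peaks(2499), ann)  # summit position 2500 (1-based)
  expect_equal(asg$gene_id, "B")
  expect_equal(asg$mode, "upstream")

  # divergent genes: the interval is upstream of both
  ann <- make_genes(c("A", "-", 1001, 2000), c("B", "+", 3001, 4000))
  asg <- assign_peaks(make_peaks(2499), ann)
  expect_setequal(asg$gene_id, c("A", "B"))

  # convergent genes point toward the summit: assigned to neither
  ann <- make_genes(c("A", "+", 1001, 2000), c("B", "-", 3001, 4000))
  asg <- assign_peaks(make_peaks(2499), ann)
  expect_equal(nrow(asg), 0)

  # no peaks -> empty assignment
  expect_equal(nrow(assign_peaks(make_peaks(numeric(0)), ann)), 0)
})

test_that("summits inside genes give in_gene evidence; operons propagate it", {
  ann <- make_genes(c("A", "+", 1001, 2000), c("B", "+", 3001, 4000),
                    c("C", "+", 5001, 6000))
  ops <- operon_map(list(op1 = c("B", "C")))
  asg <- assign_peaks(make_peaks(1499), ann, operons = ops)
  expect_equal(asg$mode[asg$gene_id == "A"], "in_gene")

  asg <- assign_peaks(make_peaks(2899), ann, operons = ops)  # upstream of B
  expect_setequal(asg$gene_id, c("B", "C"))
  expect_equal(asg$mode[asg$gene_id == "C"], "operon")
  expect_equal(asg$partner[asg$gene_id == "C"], "B")
})

test_that("upstream_cap truncates the assignable upstream interval", {
  ann <- make_genes(c("A", "+", 1001, 2000), c("B", "+", 5001, 6000))
  far <- make_peaks(2999)   # 2000 bp from B's start
  near <- make_peaks(4899)  # 101 bp from B's start
  expect_equal(nrow(assign_peaks(far, ann, upstream_cap = 500)), 0)
  expect_equal(assign_peaks(near, ann, upstream_cap = 500)$gene_id, "B")
})

test_that("peaks on unknown contigs are skipped with a warning", {
  ann <- make_genes(c("A", "+", 1001, 2000))
  pk <- make_peaks(c(500), contig = "plasmid")
  expect_warning(asg <- assign_peaks(pk, ann), "plasmid")
  expect_equal(nrow(asg), 0)
})

test_that("genic/intergenic classification matches exhaustive membership", {
  ann <- make_genes(c("A", "+", 1001, 2000), c("B", "-", 3001, 4000))
  expect_equal(classify_peaks(make_peaks(1499), ann), "genic")
  expect_equal(classify_peaks(make_peaks(2499), ann), "intergenic")

  set.seed(5)
  summits <- sample(0:4500, 200)
  labels <- classify_peaks(make_peaks(summits, halfwidth = 10), ann)
  for (i in seq_along(summits)) {
    pos <- summits[i] + 1
    inside <- FALSE
    for (j in seq_len(nrow(ann)))
      if (pos >= ann$start[j] && pos <= ann$end[j]) inside <- TRUE
    expect_equal(labels[i], if (inside) "genic" else "intergenic")
  }
})

test_that("motif scanning finds half-site/spacer occurrences on both strands", {
  m <- ctra_motif()
  hits <- scan_motif("TTAAGCTGCTATTAAC", m)
  expect_equal(hits$position, 1)
  expect_equal(hits$strand, "+")

  expect_equal(nrow(scan_motif(strrep("A", 50), m)), 0)

  # N never matches a half-site base, but is accepted in the spacer
  expect_equal(nrow(scan_motif("TTAAGCTGCTATTANC", m)), 0)
  expect_equal(nrow(scan_motif("TTAAGCTNCTATTAAC", m, both_strands = FALSE)), 1)

  # a plus-strand hit appears as a minus-strand hit on the reverse complement
  rc <- revcomp_chr("TTAAGCTGCTATTAAC")
  hits_rc <- scan_motif(rc, m)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$position, 1)
})

test_that("double-strand scans equal the brute-force oracle and are strand-symmetric", {
  m <- ctra_motif()
  set.seed(19)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                      prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    # seed a couple of guaranteed sites
    sub <- function(x, at, rep) paste0(substr(x, 1, at - 1), rep,
                                       substr(x, at + nchar(rep), nchar(x)))
    s <- sub(s, 40, "TTAACGCGCGCTTAAC")
    s <- sub(s, 200, revcomp_chr("TTAAACGTACGTTAAC"))
    hits <- scan_motif(s, m)

    fwd <- motif_oracle_scan(s, "TTAA", 7, "TTAAC")
    rc <- revcomp_chr(s)
    rev_rc <- motif_oracle_scan(rc, "TTAA", 7, "TTAAC")
    rev_fwd <- sort(nchar(s) - (rev_rc + 16 - 1) + 1)
    expect_equal(hits$position[hits$strand == "+"], fwd)
    expect_equal(sort(hits$position[hits$strand == "-"]), rev_fwd)

    # total hit count is invariant under reverse complement
    expect_equal(nrow(scan_motif(rc, m)), nrow(hits))
  }
})

test_that("direct regulon is the intersection of regulation and binding", {
  asg <- structure(data.frame(
    gene_id = c("g1", "g2", "g3"),
    peak_id = "p", mode = c("upstream", "in_gene", "operon"),
    partner = c(NA, NA, "g2"), stringsAsFactors = FALSE),
    class = c("binding_assignment", "data.frame"))

  expect_equal(length(direct_regulon(regulon("t", c("g8", "g9")), asg)$members), 0)

  total <- regulon("t", c("g1", "g3"))
  d <- direct_regulon(total, asg)
  expect_setequal(d$members, c("g1", "g3"))
  expect_equal(unname(d$provenance["g1"]), "direct")
  expect_equal(unname(d$provenance["g3"]), "operon")

  # subset and monotonicity invariants on random inputs
  set.seed(23)
  pool <- paste0("g", 1:40)
  for (i in 1:20) {
    tot <- regulon("t", sample(pool, 15))
    bound <- sample(pool, 20)
    a2 <- structure(data.frame(gene_id = bound, peak_id = "p",
                               mode = "upstream", partner = NA,
                               stringsAsFactors = FALSE),
                    class = c("binding_assignment", "data.frame"))
    d <- direct_regulon(tot, a2)
    expect_true(all(d$members %in% tot$members))
    bigger <- regulon("t2", union(tot$members, sample(pool, 5)))
    expect_true(all(d$members %in% direct_regulon(bigger, a2)$members))
  }
})

test_that("planted peaks are recovered exactly on the synthetic genome", {
  cfg <- cascade_sim_config(n_genes = 120, direct_regulon_size = 25,
                            decoy_peak_count = 0, operon_gene_fraction = 0,
                            seed = 91)
  sim <- simulate_cascade(cfg)
  kept <- filter_peaks(sim$peaks)
  expect_equal(nrow(kept), 25)  # every planted peak passes the filters
  # summits sit 75 bp from the target gene boundary; a 150 bp cap makes the
  # divergent-promoter partner (225 bp away) unreachable, so recovery is exact
  asg <- assign_peaks(kept, sim$annotation, upstream_cap = 150)
  expect_setequal(bound_genes(asg), sim$truth$direct)
  expect_true(all(asg$mode == "upstream"))
})
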