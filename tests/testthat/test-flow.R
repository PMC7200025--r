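test_that("overlap fractions handle identity, disjointness and denominators", {
  a <- regulon("a", paste0("g", 1:10))
  b <- regulon("b", paste0("g", 6:25))
  expect_equal(overlap_fraction(a, a)$pct, 100)
  expect_equal(overlap_fraction(a, regulon("z", paste0("h", 1:5)))$pct, 0)
  expect_equal(overlap_fraction(a, b, "first")$pct, 50)    # 5 of 10
  expect_equal(overlap_fraction(a, b, "second")$pct, 25)   # 5 of 20
  expect_equal(overlap_fraction(a, b, "union")$pct, 20)    # 5 of 25
  expect_setequal(overlap_fraction(a, b)$members, paste0("g", 6:10))
  expect_error(overlap_fraction(regulon("e", character(0)), b, "first"),
               "empty", class = "rf_validation_error")
})

test_that("flow on a fan-in matches hand enumeration, fluxes may exceed input", {
  D <- paste0("g", 1:10)
  pw <- pathway_graph(
    data.frame(name = c("A", "B", "Y"),
               regulon = c("a_mut", "b_mut", NA),
               mode = c("deletion", "deletion", NA),
               hidden = FALSE),
    data.frame(from = c("A", "B"), to = c("Y", "Y")),
    sink = "Y")
  regs <- list(A = regulon("A", D[1:6]), B = regulon("B", D[5:8]),
               Y = regulon("Y", D))
  flow <- quantify_flow(pw, regs, regulon("direct", D))
  e <- flow$edges
  expect_equal(e$flux_pct[e$from == "A"], 60)
  expect_equal(e$flux_pct[e$from == "B"], 40)
  n <- flow$nodes
  expect_equal(n$input_pct[n$node == "Y"], 100)
  expect_equal(n$missing_pct[n$node == "Y"], 20)
  # overlapping predecessor regulons: the accounted inputs sum beyond 100%
  expect_equal(sum(e$flux_pct) + n$missing_pct[n$node == "Y"], 120)
  expect_gt(sum(e$flux_pct) + n$missing_pct[n$node == "Y"],
            n$input_pct[n$node == "Y"])
  # sources have no missing-input value
  expect_true(all(is.na(n$missing_pct[n$node %in% c("A", "B")])))
})

test_that("chain with identical regulons transmits everything", {
  D <- paste0("g", 1:10)
  pw <- make_chain_pathway(c("X", "Y"))
  flow <- quantify_flow(pw, list(X = regulon("X", D), Y = regulon("Y", D)),
                        regulon("direct", D))
  expect_equal(flow$nodes$input_pct, c(100, 100))
  expect_equal(flow$edges$flux_pct, 100)
  expect_equal(flow$nodes$missing_pct[2], 0)
})

test_that("flow equals per-gene enumeration on random small instances", {
  set.seed(101)
  for (rep in 1:25) {
    n_nodes <- sample(2:5, 1)
    names_v <- LETTERS[1:n_nodes]
    # random DAG: chain backbone plus forward extras
    edges <- data.frame(from = names_v[-n_nodes], to = names_v[-1])
    if (n_nodes > 2) {
      for (i in 1:(n_nodes - 2)) {
        j <- sample((i + 1):n_nodes, 1)
        edges <- rbind(edges, data.frame(from = names_v[i], to = names_v[j]))
      }
      edges <- unique(edges)
    }
    pw <- pathway_graph(
      data.frame(name = names_v, regulon = paste0(names_v, "_m"),
                 mode = "deletion", hidden = FALSE),
      edges, sink = names_v[n_nodes])
    genes <- paste0("g", 1:sample(5:20, 1))
    sets <- lapply(names_v, function(x) sample(genes, sample(1:length(genes), 1)))
    names(sets) <- names_v
    D <- sample(genes, max(2, length(genes) %/% 2))
    regs <- lapply(names_v, function(x) regulon(x, sets[[x]]))
    names(regs) <- names_v
    flow <- quantify_flow(pw, regs, regulon("direct", D))
    oracle <- flow_oracle(pw, sets, D)
    expect_equal(flow$nodes$input_pct, unname(oracle$input[flow$nodes$node]))
    expect_equal(flow$edges$flux_pct, oracle$flux)
    expect_equal(flow$nodes$missing_pct, unname(oracle$missing[flow$nodes$node]))

    # FlowResult invariants
    expect_true(all(flow$nodes$input_pct >= 0 & flow$nodes$input_pct <= 100))
    expect_true(all(flow$edges$flux_pct >= 0 & flow$edges$flux_pct <= 100))
    # every percentage is a multiple of 100/|D|
    unit <- 100 / length(D)
    allpct <- c(flow$nodes$input_pct, flow$edges$flux_pct,
                flow$nodes$missing_pct[!is.na(flow$nodes$missing_pct)])
    expect_true(all(abs(allpct / unit - round(allpct / unit)) < 1e-9))
    # union inequality: input(Y) <= missing(Y) + sum of incoming fluxes
    for (y in names_v[names_v %in% pw$edges$to]) {
      influx <- sum(flow$edges$flux_pct[flow$edges$to == y])
      miss <- flow$nodes$missing_pct[flow$nodes$node == y]
      inp <- flow$nodes$input_pct[flow$nodes$node == y]
      expect_lte(inp, miss + influx + 1e-9)
      preds <- pw$edges$from[pw$edges$to == y]
      pred_sets <- lapply(preds, function(p) intersect(sets[[p]], D))
      disjoint <- sum(lengths(pred_sets)) ==
        length(unique(unlist(pred_sets)))
      if (disjoint) expect_equal(inp, miss + influx)
    }
  }
})

test_that("missing input shrinks when a predecessor regulon grows", {
  D <- paste0("g", 1:20)
  pw <- make_chain_pathway(c("X", "Y"))
  miss_with <- function(x_set) {
    flow <- quantify_flow(pw, list(X = regulon("X", x_set),
                                   Y = regulon("Y", D)),
                          regulon("direct", D))
    flow$nodes$missing_pct[flow$nodes$node == "Y"]
  }
  m1 <- miss_with(D[1:5])
  m2 <- miss_with(D[1:12])
  expect_lt(m2, m1)
  # edge flux is monotone in the endpoint regulons
  flux_with <- function(x_set) {
    flow <- quantify_flow(pw, list(X = regulon("X", x_set),
                                   Y = regulon("Y", D)),
                          regulon("direct", D))
    flow$edges$flux_pct
  }
  expect_lt(flux_with(D[1:5]), flux_with(D[1:12]))
})

test_that("unmeasured nodes resolve to ancestor-union intersect descendant-union", {
  D <- paste0("g", 1:12)
  nodes <- data.frame(name = c("A", "B", "H", "C"),
                      regulon = c("a", "b", NA, "c"),
                      mode = c("deletion", "deletion", NA, "deletion"),
                      hidden = c(FALSE, FALSE, TRUE, FALSE))
  edges <- data.frame(from = c("A", "B", "H"), to = c("H", "H", "C"))
  pw <- pathway_graph(nodes, edges, sink = "C")
  regs <- list(A = regulon("A", D[1:4]), B = regulon("B", D[3:8]),
               C = regulon("C", D[2:10]))
  flow <- quantify_flow(pw, regs, regulon("direct", D))
  expected_H <- intersect(union(D[1:4], D[3:8]), D[2:10])  # g2..g8
  expect_equal(flow$nodes$input_pct[flow$nodes$node == "H"],
               100 * length(expected_H) / 12)
})

test_that("hidden-input inference attaches one node per unexplained input", {
  D <- paste0("g", 1:10)
  pw <- make_chain_pathway(c("X", "Y"))
  full <- quantify_flow(pw, list(X = regulon("X", D), Y = regulon("Y", D)),
                        regulon("direct", D))
  unchanged <- infer_hidden_inputs(full)
  expect_equal(nrow(unchanged$nodes), 2)

  leaky <- quantify_flow(pw, list(X = regulon("X", D[1:8]),
                                  Y = regulon("Y", D)),
                         regulon("direct", D))
  aug <- infer_hidden_inputs(leaky)
  expect_true("missing_Y" %in% aug$nodes$name)
  expect_true(aug$nodes$hidden[aug$nodes$name == "missing_Y"])
  expect_equal(unname(attr(aug, "hidden_input_pct")["missing_Y"]), 20)
  # a threshold above the missing percentage suppresses the node
  expect_equal(nrow(infer_hidden_inputs(leaky, threshold_pct = 25)$nodes), 2)
})

test_that("flux regulons drop the p filter for deletion nodes and are supersets", {
  rec <- data.frame(gene_id = c("g1", "g2"),
                    log2fc = c(0.6, 2), p_value = c(0.4, 0.01),
                    max_rpkm = 100, n_pairs = 2)
  strict <- call_regulon(rec, deletion_policy(), node = "DivJ")
  expect_false("g1" %in% strict$members)  # p too high for the strict regulon

  flux <- build_flux_regulons(list(DivJ = rec), c(DivJ = "deletion"))
  expect_true("g1" %in% flux$DivJ$members)  # counted in the flux analysis

  # depletion nodes: flux regulon equals the ordinary augmented regulon
  ops <- operon_map(list(op = c("g2", "g3")))
  f2 <- build_flux_regulons(list(CckA = rec), c(CckA = "depletion"),
                            operons = ops)
  s2 <- call_regulon(rec, depletion_policy(), operons = ops, node = "CckA")
  expect_setequal(f2$CckA$members, s2$members)

  # monotonicity over random tables: flux regulon contains the strict one
  set.seed(31)
  for (i in 1:10) {
    r <- data.frame(gene_id = paste0("g", 1:50),
                    log2fc = stats::rnorm(50, 0, 1),
                    p_value = stats::runif(50),
                    max_rpkm = stats::rlnorm(50, log(50), 1), n_pairs = 2)
    fx <- build_flux_regulons(list(N = r), c(N = "deletion"))$N
    st <- call_regulon(r, deletion_policy(), node = "N")
    expect_true(all(st$members %in% fx$members))
  }
})
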