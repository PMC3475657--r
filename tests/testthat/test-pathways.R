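demo_segments <- function(n_points = 401) {
  m <- demo_ladder_model()
  tr <- run_protocol(m, default_protocol(), n_points = n_points)
  tot <- total_net_flux(flux_density(tr, m))
  list(model = m, segs = attr(tr, "segments"),
       seg_totals = attr(tot, "segment_totals"))
}

test_that("producers and collectors follow occupancy changes", {
  d <- demo_segments()
  cls <- classify_states(d$seg_totals[[1]], d$segs[[1]])
  # saturating activation from the L = 0 equilibrium: only the initially
  # occupied unliganded pair can lose probability
  expect_true(all(cls$state[cls$role == "producer"] %in% c("C0", "O0")))
  expect_true("O4" %in% cls$state[cls$role == "collector"])

  # classification matches direct inspection of delta P
  P <- as.matrix(d$segs[[1]][, d$model$states$label])
  delta <- P[nrow(P), ] - P[1, ]
  expect_equal(cls$delta_P, unname(delta))
  expect_identical(cls$role, unname(ifelse(delta < -1e-4, "producer",
                                           ifelse(delta > 1e-4, "collector", "passthrough"))))

  # conservation: produced equals collected up to pass-through storage
  expect_lt(abs(attr(cls, "produced") - attr(cls, "collected")), 10 * 1e-4)
})

test_that("flux graphs of detailed-balance relaxations are acyclic as built", {
  d <- demo_segments()
  cls <- classify_states(d$seg_totals[[1]], d$segs[[1]])
  g <- expect_no_warning(build_flux_graph(
    d$seg_totals[[1]],
    producers = cls$state[cls$role == "producer"],
    collectors = cls$state[cls$role == "collector"]))
  expect_equal(g$cancelled_cycles, 0L)
  expect_true(all(g$edges$weight > 0))
  # divergence bookkeeping sums to zero over all nodes
  expect_lt(abs(sum(g$nodes$divergence)), 1e-9)
})

test_that("tiny artificial cycles are cancelled, large ones rejected", {
  ed <- tibble::tibble(
    from = c("A", "B", "B", "C", "A"),
    to = c("B", "C", "A", "D", "D"),
    weight = c(1, 0.9995, 5e-4, 1, 0.5)
  )
  expect_warning(g <- flux_graph(ed), "Cancelling")
  expect_null(gatingflux:::find_directed_cycle(g$edges))
  # the A->B->A two-cycle lost its bottleneck 5e-4 from both edges
  expect_equal(g$edges$weight[g$edges$from == "A" & g$edges$to == "B"], 1 - 5e-4)

  ed_big <- ed
  ed_big$weight[3] <- 0.5
  expect_error(suppressWarnings(flux_graph(ed_big)), "acyclic")
})

test_that("forced decompositions give the expected pathways", {
  # single chain: one pathway carrying the common weight
  chain <- flux_graph(tibble::tibble(from = c("C0", "O0"), to = c("O0", "O1"),
                                     weight = c(0.4, 0.4)))
  dec <- decompose_pathways(chain)
  expect_equal(dec$pathways$path, "C0>O0>O1")
  expect_equal(dec$pathways$weight, 0.4)
  expect_lt(dec$residual, 1e-15)

  # diamond with unequal arms: widest first
  diamond <- flux_graph(tibble::tibble(
    from = c("S", "A", "S", "B"), to = c("A", "T", "B", "T"),
    weight = c(0.7, 0.7, 0.3, 0.3)))
  dec2 <- decompose_pathways(diamond)
  expect_equal(dec2$pathways$path, c("S>A>T", "S>B>T"))
  expect_equal(dec2$pathways$weight, c(0.7, 0.3))
})

test_that("decomposition matches the exhaustive enumeration oracle", {
  for (seed in 1:8) {
    ed <- random_conserved_dag(seed, n_nodes = 7, n_paths = 5)
    dec <- decompose_pathways(flux_graph(ed))
    oracle <- enumerate_decompose(ed, order = "widest")
    expect_equal(dec$pathways$weight, oracle$weights, tolerance = 1e-12)
    expect_identical(dec$pathways$steps, oracle$paths)
  }
})

test_that("pathway weights cover every edge regardless of extraction order", {
  for (seed in 11:16) {
    ed <- random_conserved_dag(seed, n_nodes = 8, n_paths = 6)
    dec <- decompose_pathways(flux_graph(ed))
    s1 <- edge_sums(dec$pathways$steps, dec$pathways$weight, ed)
    expect_equal(s1, ed$weight, tolerance = 1e-9)
    expect_lt(max(abs(dec$edge_accounting$leftover)), 1e-9 * max(ed$weight))
    # a different extraction order changes pathways but not edge coverage
    alt <- enumerate_decompose(ed, order = "lex")
    s2 <- edge_sums(alt$paths, alt$weights, ed)
    expect_equal(s2, ed$weight, tolerance = 1e-9)
    # total flux decomposed equals total source outflow either way
    nodes <- sort(unique(c(ed$from, ed$to)))
    div <- vapply(nodes, function(s) sum(ed$weight[ed$to == s]) - sum(ed$weight[ed$from == s]), numeric(1))
    expect_equal(sum(dec$pathways$weight), sum(-div[div < 0]), tolerance = 1e-9)
    expect_equal(sum(alt$weights), sum(-div[div < 0]), tolerance = 1e-9)
    # extracted bottlenecks are non-increasing
    expect_true(all(diff(dec$pathways$weight) <= 1e-12))
  }
})

test_that("decomposition refuses cyclic input", {
  g <- flux_graph(tibble::tibble(from = "A", to = "B", weight = 1))
  g$edges <- tibble::tibble(from = c("A", "B"), to = c("B", "A"), weight = c(1, 1))
  expect_error(decompose_pathways(g), "cycle")
})

test_that("hysteresis index spans identical to disjoint isomerization usage", {
  d <- demo_segments()
  cls <- lapply(1:2, function(s) classify_states(d$seg_totals[[s]], d$segs[[s]]))
  decs <- lapply(1:2, function(s) {
    decompose_pathways(build_flux_graph(
      d$seg_totals[[s]],
      producers = cls[[s]]$state[cls[[s]]$role == "producer"],
      collectors = cls[[s]]$state[cls[[s]]$role == "collector"]))
  })
  expect_equal(hysteresis_report(decs[[1]], decs[[1]], d$model)$index, 0)

  # hand-built decompositions crossing disjoint isomerizations
  mk_dec <- function(nodes, w) {
    structure(list(pathways = tibble::tibble(
      rank = 1L, path = paste(nodes, collapse = ">"),
      steps = list(nodes), weight = w)), class = "pathway_decomposition")
  }
  d1 <- mk_dec(c("C1", "O1"), 0.5)
  d2 <- mk_dec(c("O4", "C4"), 0.5)
  expect_equal(hysteresis_report(d1, d2, d$model)$index, 1)

  rep <- hysteresis_report(decs[[1]], decs[[2]], d$model)
  expect_gt(rep$index, 0)
  expect_lte(rep$index, 1)
})
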