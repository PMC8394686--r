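test_that("causal_graph validates nodes and edges", {
  expect_error(causal_graph(c("a", "a")), "unique")
  expect_error(causal_graph("a", data.frame(source = "a", target = "a")),
               "self-loops")
  expect_error(causal_graph("a", data.frame(source = "a", target = "b")),
               "not among nodes")
  expect_error(causal_graph(c("a", "b"),
                            data.frame(source = c("a", "a"),
                                       target = c("b", "b"))),
               "duplicate")
  g <- causal_graph(c("a", "b"), data.frame(source = "a", target = "b"))
  expect_s3_class(g, "causal_graph")
  expect_true(is.na(g$edges$weight))
})

test_that("out-degree counts outgoing edges and sums to the edge count", {
  g <- benchmark_graph()
  expect_identical(out_degree(g, "1"), 3L)
  expect_identical(out_degree(g, "2"), 3L)
  expect_identical(out_degree(g, "3"), 1L)   # only 3 -> 4
  expect_identical(out_degree(g, "4"), 0L)   # isolated as a source
  expect_error(out_degree(g, "99"), "unknown node")
  for (seed in 1:10) {
    set.seed(seed)
    nodes <- letters[1:6]
    pairs <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$s != pairs$t, ]
    pick <- pairs[sample(nrow(pairs), sample(0:15, 1)), ]
    gr <- causal_graph(nodes, data.frame(source = pick$s, target = pick$t))
    expect_identical(sum(out_degree(gr)), nrow(gr$edges))
    expect_identical(sum(in_degree(gr)), nrow(gr$edges))
  }
})

test_that("important nodes are the maximal out-degree set", {
  expect_setequal(important_nodes(benchmark_graph()), c("1", "2"))
  # paper-style 5-node subgraph once node 1 is hidden: node 2 leads
  g5 <- causal_graph(as.character(2:6), data.frame(
    source = c("2", "2", "2", "3", "3"),
    target = c("3", "4", "5", "4", "6")))
  expect_identical(important_nodes(g5), "2")
  expect_identical(important_nodes(
    causal_graph(c("a", "b"), data.frame(source = "a", target = "b"))), "a")
  # empty edge set: nobody is important
  expect_identical(important_nodes(causal_graph(letters[1:3])), character(0))
})

test_that("two_cycles finds exactly the reciprocal pairs", {
  g <- causal_graph(as.character(2:5), data.frame(
    source = c("3", "4", "2"), target = c("4", "3", "4")))
  expect_equal(two_cycles(g), matrix(c("3", "4"), 1, 2,
                                     dimnames = list(NULL, c("node1", "node2"))))
  acyclic <- causal_graph(letters[1:4], data.frame(
    source = c("a", "b", "c"), target = c("b", "c", "d")))
  expect_identical(nrow(two_cycles(acyclic)), 0L)
  g2 <- causal_graph(c("4", "5"), data.frame(source = c("4", "5"),
                                             target = c("5", "4")))
  expect_equal(unname(two_cycles(g2)), matrix(c("4", "5"), 1, 2))
})

test_that("white-noise scans usually stop after step 0 with no important node", {
  # a finite-sample false edge can occasionally appear, so check the typical
  # outcome over several panels
  outcomes <- sapply(1:6, function(s) {
    set.seed(100 + s)
    panel <- ts_panel(matrix(rnorm(4 * 1000), 1000, 4))
    rep <- subnetwork_scan(panel, scan_config(method = "rpdc", order = 2))
    ev <- hidden_hub_evidence(rep)
    c(stopped = length(rep$steps) == 1 &&
        length(rep$steps[[1]]$important_nodes) == 0,
      flag = ev$flag)
  })
  # with 12 ordered pairs at a ~5% per-pair rate, a false edge (and hence a
  # removal step) is not rare, but reciprocal false pairs are
  expect_gte(sum(outcomes["stopped", ]), 2)
  expect_lte(sum(outcomes["flag", ]), 1)
})

test_that("scans shrink the channel set and never resurrect omitted nodes", {
  set.seed(23)
  panel <- benchmark_panel(T = 1500)
  rep <- subnetwork_scan(panel, scan_config(method = "rpdc", order = 2,
                                            depth = 3))
  sizes <- vapply(rep$steps, function(st) length(st$graph$nodes), integer(1))
  expect_true(all(diff(sizes) < 0))
  for (st in rep$steps) {
    expect_length(intersect(st$omitted, st$graph$nodes), 0)
    # feedback pairs are drawn from that step's graph
    expect_true(all(as.character(st$feedback_pairs) %in% st$graph$nodes))
  }
  # determinism of the full scan
  rep2 <- subnetwork_scan(panel, scan_config(method = "rpdc", order = 2,
                                             depth = 3))
  expect_identical(lapply(rep$steps, `[[`, "graph"),
                   lapply(rep2$steps, `[[`, "graph"))
})

test_that("hidden-hub evidence combines feedback pairs across steps", {
  mk_step <- function(nodes, edges, fb) list(
    omitted = character(0),
    graph = causal_graph(nodes, edges),
    important_nodes = character(0),
    feedback_pairs = fb)
  fb34 <- matrix(c("3", "4"), 1, 2, dimnames = list(NULL, c("node1", "node2")))
  fb45 <- matrix(c("4", "5"), 1, 2, dimnames = list(NULL, c("node1", "node2")))
  none <- matrix(character(0), 0, 2,
                 dimnames = list(NULL, c("node1", "node2")))
  report <- structure(list(steps = list(
    mk_step(as.character(3:6),
            data.frame(source = c("3", "4"), target = c("4", "3")), fb34),
    mk_step(as.character(4:6),
            data.frame(source = c("4", "5"), target = c("5", "4")), fb45)),
    method = "rpdc", config = scan_config(), error = NULL),
    class = "scan_report")
  ev <- hidden_hub_evidence(report)
  expect_true(ev$flag)
  expect_identical(ev$common_nodes, "4")       # intersect across steps
  expect_identical(ev$union_nodes, c("3", "4", "5"))
  # single feedback step: union equals the pair itself
  report1 <- report
  report1$steps[[2]]$feedback_pairs <- none
  ev1 <- hidden_hub_evidence(report1)
  expect_true(ev1$flag)
  expect_identical(ev1$common_nodes, c("3", "4"))
  # no feedback anywhere
  report0 <- report
  report0$steps[[1]]$feedback_pairs <- none
  report0$steps[[2]]$feedback_pairs <- none
  expect_false(hidden_hub_evidence(report0)$flag)
})
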