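edge_df <- function(...) {
  m <- matrix(c(...), ncol = 3L, byrow = TRUE)
  el <- data.frame(protein_a = m[, 1L], protein_b = m[, 2L],
                   score = as.numeric(m[, 3L]), stringsAsFactors = FALSE)
  class(el) <- c("edge_list", "data.frame")
  el
}

test_that("network filter is strictly greater-than and drops isolated nodes", {
  el <- edge_df("A", "B", 0.90,
                "B", "C", 0.80,
                "C", "D", 0.79)
  g <- build_network(el, 0.8)
  expect_equal(igraph::ecount(g), 1L)          # only the 0.90 edge survives
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  g0 <- build_network(el, 0)
  expect_equal(igraph::ecount(g0), 3L)
  expect_error(build_network(el, 0.95), "no edges exceed")
})

test_that("seed mapping reproduces the gene -> protein -> in-network funnel", {
  genes <- paste0("G", 1:9)
  prot <- sprintf("PR%02d", 1:27)
  map <- structure(split(prot, rep(genes, each = 3L)), class = "gene_protein_map")
  # network containing only 8 of the 27 proteins (plus a connector)
  in_net <- prot[1:8]
  el <- data.frame(protein_a = in_net, protein_b = "HUB", score = 0.95,
                   stringsAsFactors = FALSE)
  class(el) <- c("edge_list", "data.frame")
  g <- build_network(el, 0.8)
  seeds <- suppressMessages(map_seed_proteins(genes, map, g))
  expect_setequal(seeds, in_net)
  expect_message(map_seed_proteins(genes, map, g), "9 gene\\(s\\) -> 27 protein\\(s\\) -> 8")
  # absent gene contributes nothing; all-outside mapping is an error
  expect_message(map_seed_proteins(c(genes, "G99"), map, g), "unmapped: G99")
  far <- structure(list(GX = "ZZ1", GY = "ZZ2"), class = "gene_protein_map")
  expect_error(suppressMessages(map_seed_proteins(c("GX", "GY"), far, g)),
               "no mapped protein")
  expect_error(suppressMessages(
    map_seed_proteins("G1", structure(list(G1 = in_net[1L]),
                                      class = "gene_protein_map"), g)),
    "fewer than 2")
})

test_that("chain and disconnected seed pairs behave as stated", {
  el <- edge_df("A", "B", 0.9,
                "B", "C", 0.9,
                "X", "Y", 0.9)
  g <- build_network(el, 0.8)
  ps <- shortest_paths_among_seeds(g, c("A", "C"))
  expect_identical(ps$paths[["A|C"]], c("A", "B", "C"))
  ps2 <- shortest_paths_among_seeds(g, c("A", "X"))
  expect_null(ps2$paths[["A|X"]])
  expect_equal(length(ps2$nodes), 0L)
})

test_that("co-minimal paths resolve to the lexicographically smallest sequence", {
  # two parallel length-2 routes A-M-Z and A-B-Z: B beats M
  el <- edge_df("A", "M", 0.9,
                "M", "Z", 0.9,
                "A", "B", 0.9,
                "B", "Z", 0.9)
  g <- build_network(el, 0.8)
  ps <- shortest_paths_among_seeds(g, c("A", "Z"))
  expect_identical(ps$paths[["A|Z"]], c("A", "B", "Z"))
})

test_that("path lengths match exhaustive BFS on random graphs", {
  for (s in 1:20) {
    el <- random_edge_list(sample(6:12, 1L), 0.3, seed = 500 + s)
    g <- tryCatch(build_network(el, 0.8), error = function(e) NULL)
    if (is.null(g)) next
    nodes <- igraph::V(g)$name
    seeds <- sort(sample(nodes, min(4L, length(nodes))))
    if (length(seeds) < 2L) next
    ps <- shortest_paths_among_seeds(g, seeds)
    for (key in names(ps$paths)) {
      ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
      d <- oracle_bfs_dist(el[el$score > 0.8, ], ab[1L], nodes)[ab[2L]]
      p <- ps$paths[[key]]
      if (is.null(p)) {
        expect_true(is.infinite(d))
      } else {
        expect_equal(length(p) - 1L, unname(d))
        # every consecutive pair is a real edge of the filtered graph
        for (i in seq_len(length(p) - 1L)) {
          expect_true(igraph::are_adjacent(g, p[i], p[i + 1L]))
        }
      }
    }
  }
})

test_that("sub-network equals the union of stored paths", {
  for (s in 1:10) {
    el <- random_edge_list(10, 0.35, seed = 600 + s)
    g <- tryCatch(build_network(el, 0.8), error = function(e) NULL)
    if (is.null(g)) next
    nodes <- igraph::V(g)$name
    if (length(nodes) < 4L) next
    ps <- shortest_paths_among_seeds(g, sort(sample(nodes, 4L)))
    stored <- ps$paths[!vapply(ps$paths, is.null, logical(1))]
    if (length(stored) == 0L) next
    expect_setequal(ps$nodes, unique(unlist(stored)))
    expect_lte(nrow(ps$edges), sum(vapply(stored, length, 1L) - 1L))
  }
})

test_that("betweenness counts follow the star combinatorics", {
  for (m in 3:6) {
    leaves <- sprintf("L%d", seq_len(m))
    el <- data.frame(protein_a = "HB", protein_b = leaves, score = 0.9,
                     stringsAsFactors = FALSE)
    class(el) <- c("edge_list", "data.frame")
    g <- build_network(el, 0.8)
    ps <- shortest_paths_among_seeds(g, leaves)
    bt <- betweenness_counts(ps)
    expect_equal(bt$betweenness[bt$protein == "HB"], m * (m - 1L) / 2L)
    expect_true(all(bt$betweenness[bt$protein != "HB"] == 0L))
  }
})

test_that("endpoints are excluded but seeds count as intermediates elsewhere", {
  el <- edge_df("A", "B", 0.9,
                "B", "C", 0.9)
  g <- build_network(el, 0.8)
  ps <- shortest_paths_among_seeds(g, c("A", "B", "C"))
  bt <- betweenness_counts(ps)
  expect_equal(bt$betweenness[bt$protein == "B"], 1L)  # internal on A-C only
  expect_equal(bt$betweenness[bt$protein == "A"], 0L)
  expect_equal(bt$betweenness[bt$protein == "C"], 0L)
})

test_that("betweenness totals match path interior sizes on random graphs", {
  for (s in 1:10) {
    el <- random_edge_list(11, 0.3, seed = 700 + s)
    g <- tryCatch(build_network(el, 0.8), error = function(e) NULL)
    if (is.null(g)) next
    nodes <- igraph::V(g)$name
    if (length(nodes) < 5L) next
    ps <- shortest_paths_among_seeds(g, sort(sample(nodes, 5L)))
    stored <- ps$paths[!vapply(ps$paths, is.null, logical(1))]
    if (length(stored) == 0L) next
    bt <- betweenness_counts(ps)
    expect_equal(sum(bt$betweenness),
                 sum(vapply(stored, length, 1L) - 2L))
  }
})

test_that("SIF writer emits node1 pp node2 lines", {
  el <- edge_df("A", "B", 0.9, "B", "C", 0.9)
  g <- build_network(el, 0.8)
  ps <- shortest_paths_among_seeds(g, c("A", "C"))
  f <- tempfile(fileext = ".sif")
  write_sif(ps, f)
  expect_setequal(readLines(f), c("A pp B", "B pp C"))
})
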