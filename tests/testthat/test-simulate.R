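test_that("expression simulation is reproducible and role-annotated", {
  spec <- expression_sim_spec(n_informative = 4L, effect_size = 2,
                              n_redundant = 3L, n_noise = 13L,
                              n_per_class = 10L, seed = 7L)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth, b$truth)
  expect_equal(table(a$truth$role)[["informative"]], 4L)
  expect_equal(table(a$truth$role)[["redundant"]], 3L)
  expect_equal(table(a$truth$role)[["noise"]], 13L)
  # every redundant copy names an informative source
  red <- a$truth[a$truth$role == "redundant", ]
  src_roles <- a$truth$role[match(red$source_probe, a$truth$probe_id)]
  expect_true(all(src_roles == "informative"))
  expect_error(simulate_expression(expression_sim_spec(n_per_class = 1L)),
               "n_per_class")
})

test_that("null construction: zero effect size leaves no class signal", {
  pvals <- unlist(lapply(1:8, function(s) {
    sim <- simulate_expression(expression_sim_spec(
      n_informative = 25L, effect_size = 0, n_redundant = 0L, n_noise = 25L,
      n_per_class = 20L, seed = s))
    y <- sim$dataset$labels
    apply(sim$dataset$values, 1L, function(x)
      t.test(x[y == 1L], x[y == 0L])$p.value)
  }))
  # at alpha = 0.001 roughly 0.1% of probes reject; allow binomial slack
  expect_lt(mean(pvals < 0.001), 0.01)
})

test_that("strong informative probes dominate noise probes in t-statistics", {
  for (s in 1:20) {
    sim <- simulate_expression(expression_sim_spec(
      n_informative = 10L, effect_size = 3, n_redundant = 0L, n_noise = 50L,
      n_per_class = 45L, seed = s))
    y <- sim$dataset$labels
    tstat <- abs(apply(sim$dataset$values, 1L, function(x)
      t.test(x[y == 1L], x[y == 0L])$statistic))
    inf <- sim$truth$role == "informative"
    expect_gt(min(tstat[inf]), max(tstat[!inf]))
  }
})

test_that("redundant copies track their source tightly", {
  sim <- simulate_expression(expression_sim_spec(
    n_informative = 5L, effect_size = 1, n_redundant = 5L, n_noise = 5L,
    n_per_class = 30L, seed = 3L))
  red <- sim$truth[sim$truth$role == "redundant", ]
  for (i in seq_len(nrow(red))) {
    r <- cor(sim$dataset$values[red$probe_id[i], ],
             sim$dataset$values[red$source_probe[i], ])
    expect_gt(r, 0.97)
  }
})

test_that("network simulation plants detectable hubs reproducibly", {
  spec <- network_sim_spec(n_background = 200L, n_hubs = 1L, hub_degree = 30L,
                           seed = 5L)
  a <- simulate_network(spec)
  b <- simulate_network(spec)
  expect_identical(a$edges, b$edges)
  expect_identical(a$hubs, b$hubs)
  # planted hub sits in the top 1% of the degree distribution
  g <- igraph::graph_from_data_frame(a$edges, directed = FALSE)
  deg <- igraph::degree(g)
  expect_gte(deg[a$hubs], quantile(deg, 0.99))
  # spec guards
  expect_error(network_sim_spec(n_background = 3L, attachment = 3L),
               "attachment")
})

test_that("score range is honoured so a 0.8 filter can be a no-op", {
  net <- simulate_network(network_sim_spec(score_range = c(0.85, 1), seed = 9L))
  expect_true(all(net$edges$score > 0.8))
  expect_equal(nrow(net$edges[net$edges$score > 0.8, ]), nrow(net$edges))
})

test_that("write_simulation emits a complete, loadable study", {
  dir <- tempfile()
  paths <- write_simulation(
    expression_sim_spec(n_informative = 4L, n_redundant = 2L, n_noise = 14L,
                        n_per_class = 5L, seed = 2L),
    network_sim_spec(n_background = 50L, hub_degree = 10L, seed = 2L),
    dir)
  expect_true(all(file.exists(unlist(paths))))
  ds <- suppressMessages(read_expression_table(paths$expression, paths$labels))
  expect_equal(dim(ds$values), c(20L, 10L))
  el <- read_edge_list(paths$edges)
  expect_true(all(el$score >= 0 & el$score <= 1))
  m <- suppressMessages(read_gene_map(paths$gene_map))
  expect_equal(length(m), 4L)   # one entry per informative gene
  truth <- read.delim(paths$truth_probes)
  expect_setequal(truth$probe_id, ds$probe_ids)
})
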