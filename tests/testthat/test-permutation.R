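make_star_world <- function(seed = 1L) {
  net <- simulate_network(network_sim_spec(n_background = 200L, n_hubs = 1L,
                                           hub_degree = 30L,
                                           score_range = c(0.85, 1),
                                           seed = seed))
  g <- build_network(net$edges, 0.8)
  list(net = net, g = g)
}

test_that("a planted hub seeded by its neighbours is significant", {
  w <- make_star_world(seed = 17L)
  hub <- w$net$hubs
  nbrs <- igraph::V(w$g)$name[
    as.integer(igraph::neighbors(w$g, hub))]
  set.seed(17)
  seeds <- sort(sample(nbrs, 8L))
  ps <- shortest_paths_among_seeds(w$g, seeds)
  bt <- betweenness_counts(ps)
  expect_gt(bt$betweenness[bt$protein == hub], 0L)
  res <- permutation_test(w$g, bt, permutation_config(n_permutations = 1000L,
                                                      rng_seed = 17L))
  expect_lte(res$p_value[res$protein == hub], 0.05)
})

test_that("edge cases of the p-value formula behave as forced", {
  w <- make_star_world(seed = 3L)
  nodes <- igraph::V(w$g)$name
  # observed betweenness 0: every permutation ties or exceeds, p = 1
  obs0 <- data.frame(protein = nodes[1:3], betweenness = 0L)
  res0 <- permutation_test(w$g, obs0,
                           permutation_config(n_permutations = 50L, rng_seed = 1L))
  expect_true(all(res0$exceed_count == 50L))
  expect_true(all(res0$p_value == 1))
  # a single permutation can only give p = 0.5 or 1
  res1 <- permutation_test(w$g, data.frame(protein = nodes[1:5],
                                           betweenness = c(0L, 1L, 2L, 5L, 50L)),
                           permutation_config(n_permutations = 1L, rng_seed = 2L))
  expect_true(all(res1$p_value %in% c(0.5, 1)))
  expect_error(permutation_test(w$g, obs0,
                                permutation_config(seed_set_size = 10000L)),
               "seed_set_size")
})

test_that("identical config and inputs give identical exceedance counts", {
  w <- make_star_world(seed = 5L)
  nodes <- sort(igraph::V(w$g)$name)
  obs <- data.frame(protein = nodes[1:10], betweenness = c(3L, 1L, 0L, 2L, 4L,
                                                           0L, 1L, 2L, 0L, 6L))
  cfg <- permutation_config(n_permutations = 200L, rng_seed = 9L)
  a <- permutation_test(w$g, obs, cfg)
  b <- permutation_test(w$g, obs, cfg)
  expect_identical(a$exceed_count, b$exceed_count)
  expect_identical(a$p_value, b$p_value)
})

test_that("p-values are monotone non-increasing in observed betweenness", {
  w <- make_star_world(seed = 7L)
  node <- igraph::V(w$g)$name[5L]
  obs <- data.frame(protein = rep(node, 6L), betweenness = c(0L, 1L, 2L, 3L, 5L, 10L))
  res <- permutation_test(w$g, obs,
                          permutation_config(n_permutations = 300L, rng_seed = 4L))
  p_by_obs <- res$p_value[order(res$betweenness)]
  expect_true(all(diff(p_by_obs) <= 0))
})

test_that("random targets of a homogeneous graph are rarely significant", {
  # targets are random nodes, not nodes picked because they lay on the
  # observed paths: their observed betweenness under one random seed draw is
  # mostly zero, so the null should produce almost no significance
  frac_sig <- sapply(1:20, function(r) {
    set.seed(8000 + r)
    nodes <- sprintf("N%03d", 1:80)
    g0 <- igraph::sample_gnp(80, 0.08)
    igraph::V(g0)$name <- nodes
    comp <- igraph::components(g0)
    keep <- nodes[comp$membership == which.max(comp$csize)]
    g0 <- igraph::induced_subgraph(g0, keep)
    in_g <- igraph::V(g0)$name
    seeds <- sort(sample(in_g, 8L))
    ps <- shortest_paths_among_seeds(g0, seeds)
    bt <- betweenness_counts(ps)
    targets <- sample(in_g, 20L)
    obs <- data.frame(protein = targets,
                      betweenness = ifelse(targets %in% bt$protein,
                                           bt$betweenness[match(targets, bt$protein)],
                                           0L))
    res <- permutation_test(g0, obs,
                            permutation_config(n_permutations = 400L,
                                               rng_seed = 8000L + r))
    mean(res$p_value < 0.05)
  })
  expect_true(all(frac_sig >= 0 & frac_sig <= 0.12))
})
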