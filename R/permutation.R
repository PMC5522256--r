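#' Configuration for the hub permutation test
#'
#' Defaults follow the study: 1000 permutations of 8-protein random seed
#' sets, significance at p < 0.05.
#'
#' @param n_permutations Number of random seed-set draws.
#' @param seed_set_size Proteins per random seed set.
#' @param alpha Significance level.
#' @param rng_seed RNG seed; identical config and inputs give identical
#'   exceedance counts.
#' @return A list of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000L, seed_set_size = 8L,
                               alpha = 0.05, rng_seed = 1L) {
  stopifnot(n_permutations >= 1L, seed_set_size >= 2L, alpha > 0, alpha < 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed_set_size = as.integer(seed_set_size),
                 alpha = alpha,
                 rng_seed = as.integer(rng_seed)),
            class = "permutation_config")
}

#' Permutation test for path-occurrence betweenness
#'
#' Assesses whether the observed sub-network proteins are hubs of the
#' background network: each permutation draws `seed_set_size` nodes uniformly
#' without replacement from all network nodes, recomputes seed-pair shortest
#' paths under exactly the rules of [shortest_paths_among_seeds()], and
#' counts each target protein's betweenness. The per-protein p-value is
#' \eqn{(c + 1)/(n + 1)} where c is the number of permutations with permuted
#' betweenness at least the observed value; the uncorrected proportion
#' \eqn{c/n} is reported alongside. Unreachable pairs contribute no paths.
#'
#' @param network The background `igraph` graph (same graph the observed
#'   betweenness was computed on).
#' @param observed A `betweenness_record` data frame (columns `protein`,
#'   `betweenness`) for the target proteins.
#' @param config A [permutation_config()].
#' @return A data frame of class `permutation_result` with columns `protein`,
#'   `betweenness`, `exceed_count`, `p_value`, `p_plain`, `significant`.
#' @export
permutation_test <- function(network, observed, config = permutation_config()) {
  stopifnot(inherits(config, "permutation_config"),
            all(c("protein", "betweenness") %in% names(observed)))
  nodes <- igraph::V(network)$name
  if (config$seed_set_size > length(nodes))
    stop("seed_set_size exceeds network node count")
  targets <- observed$protein
  obs <- observed$betweenness
  adj <- adjacency_by_name(network)

  set.seed(config$rng_seed)
  exceed <- integer(length(targets))
  for (perm in seq_len(config$n_permutations)) {
    seeds <- sort(sample(nodes, config$seed_set_size))
    counts <- perm_betweenness(network, adj, seeds, targets)
    exceed <- exceed + as.integer(counts >= obs)
  }
  p <- (exceed + 1) / (config$n_permutations + 1)
  out <- data.frame(protein = targets,
                    betweenness = obs,
                    exceed_count = exceed,
                    p_value = p,
                    p_plain = exceed / config$n_permutations,
                    significant = p < config$alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$betweenness, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, config = config, class = c("permutation_result", "data.frame"))
}

# betweenness of `targets` under one random seed draw; same path rules as
# shortest_paths_among_seeds but without materializing the sub-network
perm_betweenness <- function(network, adj, seeds, targets) {
  dmat <- igraph::distances(network, v = seeds, weights = NA)
  colnames(dmat) <- igraph::V(network)$name
  counts <- stats::setNames(integer(length(targets)), targets)
  pairs <- utils::combn(seeds, 2L)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    p <- lex_shortest_path(adj, dmat[b, ], from = a, to = b)
    if (is.null(p) || length(p) < 3L) next
    internal <- p[-c(1L, length(p))]
    hit <- internal[internal %in% targets]
    if (length(hit) > 0L) counts[hit] <- counts[hit] + 1L
  }
  counts
}
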