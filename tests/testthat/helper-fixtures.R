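# shared fixture builders and independent oracles

# tiny expression dataset from an explicit matrix
make_dataset <- function(values, labels, probe_ids = NULL, symbols = NULL) {
  values <- as.matrix(values)
  if (is.null(probe_ids)) probe_ids <- paste0("pr", seq_len(nrow(values)))
  if (is.null(symbols)) symbols <- paste0("G", seq_len(nrow(values)))
  new_expression_dataset(probe_ids, symbols, values,
                         paste0("s", seq_len(ncol(values))), labels)
}

# random two-class dataset for property loops
random_dataset <- function(n_probes, n_samples, seed) {
  set.seed(seed)
  n1 <- max(1L, n_samples %/% 2L)
  labels <- rep(c(1L, 0L), times = c(n1, n_samples - n1))
  make_dataset(matrix(rnorm(n_probes * n_samples), nrow = n_probes), labels)
}

# independent brute-force greedy over a fully precomputed MI matrix:
# recomputes the mRMR score from scratch at every step with plain loops
oracle_mrmr <- function(dataset, N, estimator = "correlation") {
  vals <- dataset$values
  P <- nrow(vals)
  y <- as.numeric(dataset$labels)
  rel <- sapply(seq_len(P), function(i)
    suppressWarnings(estimate_mi(vals[i, ], y, estimator)))
  mimat <- matrix(0, P, P)
  for (i in seq_len(P)) for (j in seq_len(P)) {
    if (i != j) mimat[i, j] <- suppressWarnings(
      estimate_mi(vals[i, ], vals[j, ], estimator))
  }
  sel <- integer(0)
  for (step in seq_len(min(N, P))) {
    best <- NA_integer_; best_q <- -Inf
    for (j in seq_len(P)) {
      if (j %in% sel) next
      q <- if (length(sel) == 0L) rel[j]
           else rel[j] - mean(mimat[j, sel])
      if (q > best_q + 1e-9) { best_q <- q; best <- j }
    }
    sel <- c(sel, best)
  }
  dataset$probe_ids[sel]
}

# exhaustive breadth-first distances from one node, hand-rolled queue
oracle_bfs_dist <- function(edges_df, from, nodes) {
  adj <- split(c(edges_df$protein_b, edges_df$protein_a),
               c(edges_df$protein_a, edges_df$protein_b))
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  dist
}

# random simple graph as an edge_list with unit-interval scores
random_edge_list <- function(n_nodes, p_edge, seed, score = 0.9) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < p_edge
  el <- data.frame(protein_a = pairs[keep, 1L], protein_b = pairs[keep, 2L],
                   score = score, stringsAsFactors = FALSE)
  class(el) <- c("edge_list", "data.frame")
  el
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
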