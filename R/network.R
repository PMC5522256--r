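#' Build a confidence-filtered protein interaction network
#'
#' Keeps edges whose combined score is strictly greater than the threshold
#' (the study's "score greater than 0.8" filter; on the STRING 0-1000 integer
#' dialect this means > 800 before normalization) and drops nodes left
#' without edges. The result is a simple undirected `igraph` graph with a
#' `score` edge attribute.
#'
#' @param edges An `edge_list` (normalized, scores in [0, 1]).
#' @param threshold Confidence threshold; edges must exceed it strictly.
#' @return An `igraph` graph with graph attribute `threshold`.
#' @export
build_network <- function(edges, threshold = 0.8) {
  keep <- edges[edges$score > threshold, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no edges exceed confidence threshold ", threshold)
  g <- igraph::graph_from_data_frame(keep, directed = FALSE)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Map selected gene symbols to in-network seed proteins
#'
#' Applies the funnel the study reports (10 probes -> 9 genes -> 27 proteins
#' -> 8 in the high-confidence network): genes are expanded through the
#' gene-protein multimap and the union is intersected with the network's
#' node set. Counts at every stage are reported via `message()`.
#'
#' @param genes Character vector of gene symbols.
#' @param map A `gene_protein_map`.
#' @param network An `igraph` graph from [build_network()].
#' @return Sorted character vector of seed protein IDs (at least 2).
#' @export
map_seed_proteins <- function(genes, map, network) {
  if (length(genes) == 0L) stop("empty gene list")
  genes <- unique(genes[nzchar(genes)])
  hits <- lapply(genes, function(g) map_lookup(map, g))
  unmapped <- genes[lengths(hits) == 0L]
  proteins <- sort(unique(unlist(hits)))
  seeds <- sort(intersect(proteins, igraph::V(network)$name))
  message("map_seed_proteins: ", length(genes), " gene(s) -> ",
          length(proteins), " protein(s) -> ", length(seeds),
          " in network",
          if (length(unmapped) > 0L)
            paste0(" (unmapped: ", paste(unmapped, collapse = ", "), ")") else "")
  if (length(seeds) == 0L) stop("no mapped protein is present in the network")
  if (length(seeds) < 2L) stop("fewer than 2 seed proteins; no pairs to connect")
  seeds
}

# sorted adjacency list by node name; reused across many path queries
adjacency_by_name <- function(network) {
  nms <- igraph::V(network)$name
  adj <- igraph::as_adj_list(network, mode = "all")
  out <- lapply(adj, function(v) sort(nms[as.integer(v)]))
  names(out) <- nms
  out
}

# lexicographically smallest shortest path from `from` to `to`, walking the
# BFS distance gradient and taking the smallest-named admissible neighbour
lex_shortest_path <- function(adj, dist_to, from, to) {
  d <- dist_to[from]
  if (!is.finite(d)) return(NULL)
  path <- character(d + 1L)
  path[1L] <- from
  u <- from
  step <- 1L
  while (u != to) {
    nb <- adj[[u]]
    nxt <- nb[dist_to[nb] == dist_to[u] - 1L][1L]   # adj sorted => lexicographic
    step <- step + 1L
    path[step] <- nxt
    u <- nxt
  }
  path
}

#' All-pairs shortest paths among seed proteins
#'
#' For each unordered pair of seeds, one minimal-hop path on the filtered
#' graph is stored (unit edge weights, so Dijkstra reduces to breadth-first
#' search). Among co-minimal paths, the lexicographically smallest node
#' sequence is chosen, oriented from the lexicographically smaller seed, so
#' results are deterministic. Unreachable pairs are recorded as no-path and
#' skipped downstream. The sub-network is the union of all stored path nodes
#' and their consecutive edges.
#'
#' @param network An `igraph` graph from [build_network()].
#' @param seeds Character vector of at least 2 seed protein IDs.
#' @return A list of class `path_set`: `seeds`, `paths` (named list keyed
#'   `"a|b"`, each a node sequence or `NULL` for no-path), `nodes`
#'   (sub-network node set) and `edges` (data frame `from`, `to` of unique
#'   sub-network edges).
#' @export
shortest_paths_among_seeds <- function(network, seeds) {
  stopifnot(length(seeds) >= 2L)
  seeds <- sort(unique(seeds))
  missing <- setdiff(seeds, igraph::V(network)$name)
  if (length(missing) > 0L)
    stop("seed(s) absent from network: ", paste(missing, collapse = ", "))
  adj <- adjacency_by_name(network)
  dmat <- igraph::distances(network, v = seeds, weights = NA)
  colnames(dmat) <- igraph::V(network)$name

  pairs <- utils::combn(seeds, 2L)
  paths <- vector("list", ncol(pairs))
  names(paths) <- paste(pairs[1L, ], pairs[2L, ], sep = "|")
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    # single-bracket assignment keeps NULL (no-path) entries in place
    paths[j] <- list(lex_shortest_path(adj, dmat[b, ], from = a, to = b))
  }

  stored <- paths[!vapply(paths, is.null, logical(1))]
  nodes <- sort(unique(unlist(stored)))
  edges <- unique(do.call(rbind, lapply(stored, function(p) {
    if (length(p) < 2L) return(NULL)
    data.frame(from = pmin(utils::head(p, -1L), p[-1L]),
               to = pmax(utils::head(p, -1L), p[-1L]),
               stringsAsFactors = FALSE)
  })))
  if (is.null(edges)) edges <- data.frame(from = character(0), to = character(0))
  rownames(edges) <- NULL
  structure(list(seeds = seeds, paths = paths, nodes = nodes, edges = edges),
            class = "path_set")
}

#' Seed-pair path-occurrence betweenness
#'
#' For every node appearing in any stored path, counts the paths in which it
#' lies as a non-endpoint (internal) node. This is the study's betweenness:
#' occurrence on seed-pair shortest paths, not global betweenness centrality.
#' Seeds can accumulate counts through paths between other seed pairs.
#'
#' @param paths A `path_set`.
#' @return A data frame of class `betweenness_record` with columns `protein`
#'   and `betweenness`, sorted by descending count and then protein ID.
#' @export
betweenness_counts <- function(paths) {
  stopifnot(inherits(paths, "path_set"))
  stored <- paths$paths[!vapply(paths$paths, is.null, logical(1))]
  if (length(stored) == 0L) stop("no stored paths to count over")
  counts <- stats::setNames(integer(length(paths$nodes)), paths$nodes)
  for (p in stored) {
    internal <- p[-c(1L, length(p))]
    if (length(internal) > 0L)
      counts[internal] <- counts[internal] + 1L
  }
  out <- data.frame(protein = names(counts), betweenness = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$betweenness, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("betweenness_record", "data.frame")
  out
}

#' Write a sub-network in SIF format
#'
#' One line per edge: `node1 pp node2` ("pp" = protein-protein), consumable
#' by standard graph viewers.
#'
#' @param paths A `path_set`.
#' @param path Output file.
#' @param comment Optional `#` comment line written first.
#' @export
write_sif <- function(paths, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  if (nrow(paths$edges) > 0L)
    writeLines(paste(paths$edges$from, "pp", paths$edges$to), con)
  invisible(path)
}
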