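#' Specification for a simulated two-class expression matrix
#'
#' Defaults mirror the study design the pipeline targets: 45 tumour + 45
#' non-tumour samples, a small set of moderately class-separating probes
#' (one within-class standard deviation of mean shift), near-duplicate
#' redundant copies of those probes, and a large body of pure-noise probes.
#'
#' @param n_informative Planted class-separating probes.
#' @param effect_size Mean shift between classes, in units of the
#'   within-class standard deviation (which is 1).
#' @param n_redundant Near-duplicate copies of informative probes; each copy
#'   is its source probe plus Gaussian noise of sd 0.1 (correlation with the
#'   source about 0.995).
#' @param n_noise N(0, 1) probes carrying no class signal.
#' @param n_per_class Samples per class.
#' @param seed RNG seed; generation is reproducible given the seed.
#' @return A list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_informative = 10L, effect_size = 1,
                                n_redundant = 10L, n_noise = 480L,
                                n_per_class = 45L, seed = 1L) {
  stopifnot(n_informative >= 0, n_redundant >= 0, n_noise >= 0,
            effect_size >= 0, n_per_class >= 0)
  if (n_redundant > 0 && n_informative == 0)
    stop("redundant probes need at least one informative source probe")
  structure(list(n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Simulate a two-class expression dataset with known probe roles
#'
#' Informative probes are N(-effect_size/2, 1) in non-tumour and
#' N(+effect_size/2, 1) in tumour samples; redundant probes are a randomly
#' chosen informative probe plus N(0, 0.1) noise; noise probes are N(0, 1)
#' in both classes. Probe order is shuffled so position carries no signal.
#'
#' @param spec An [expression_sim_spec()].
#' @return A list with elements `dataset` (an `expression_dataset`) and
#'   `truth` (data frame `probe_id`, `role` in
#'   informative/redundant/noise, `source_probe` for redundant copies).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  if (spec$n_per_class < 2L) stop("n_per_class must be >= 2 (jackknife undefined otherwise)")
  set.seed(spec$seed)
  n_probes <- spec$n_informative + spec$n_redundant + spec$n_noise
  if (n_probes < 1L) stop("at least one probe required")
  m <- 2L * spec$n_per_class
  labels <- rep(c(1L, 0L), each = spec$n_per_class)
  shift <- ifelse(labels == 1L, spec$effect_size / 2, -spec$effect_size / 2)

  ids <- sprintf("p%05d", seq_len(n_probes))
  roles <- rep(c("informative", "redundant", "noise"),
               times = c(spec$n_informative, spec$n_redundant, spec$n_noise))

  vals <- matrix(0, nrow = n_probes, ncol = m)
  inf_idx <- which(roles == "informative")
  for (i in inf_idx) vals[i, ] <- stats::rnorm(m, mean = shift, sd = 1)
  source_probe <- rep(NA_character_, n_probes)
  red_idx <- which(roles == "redundant")
  if (length(red_idx) > 0L) {
    src <- sample(inf_idx, length(red_idx), replace = TRUE)
    for (j in seq_along(red_idx)) {
      vals[red_idx[j], ] <- vals[src[j], ] + stats::rnorm(m, sd = 0.1)
      source_probe[red_idx[j]] <- ids[src[j]]
    }
  }
  noi_idx <- which(roles == "noise")
  for (i in noi_idx) vals[i, ] <- stats::rnorm(m)

  perm <- sample.int(n_probes)
  vals <- vals[perm, , drop = FALSE]
  ids_p <- ids[perm]
  roles_p <- roles[perm]
  source_p <- source_probe[perm]

  sample_ids <- sprintf("s%03d", seq_len(m))
  symbols <- paste0("GENE", sub("^p", "", ids_p))
  ds <- new_expression_dataset(ids_p, symbols, vals, sample_ids, labels)
  truth <- data.frame(probe_id = ids_p, role = roles_p,
                      source_probe = source_p, stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth)
}

#' Specification for a simulated interaction network with planted hubs
#'
#' A scale-free background graph is grown by preferential attachment
#' (interaction networks are heavy-tailed), then `n_hubs` extra nodes are each
#' wired to `hub_degree` randomly chosen background nodes, creating
#' star-shaped hubs whose identities are recorded as ground truth. Edge
#' confidences are drawn uniformly from `score_range`; the default emulates a
#' high-confidence subgraph that survives a 0.8 filter intact.
#'
#' @param n_background Background node count.
#' @param attachment Edges per new node during preferential attachment.
#' @param n_hubs Planted star hubs.
#' @param hub_degree Neighbours per planted hub.
#' @param score_range Interval for sampled edge confidence scores.
#' @param seed RNG seed.
#' @return A list of class `network_sim_spec`.
#' @export
network_sim_spec <- function(n_background = 200L, attachment = 3L,
                             n_hubs = 1L, hub_degree = 30L,
                             score_range = c(0.85, 1), seed = 1L) {
  stopifnot(n_background >= 2, attachment >= 1, n_hubs >= 0, hub_degree >= 1,
            length(score_range) == 2L, score_range[1] <= score_range[2],
            score_range[1] >= 0, score_range[2] <= 1)
  if (n_background < attachment + 1L)
    stop("n_background must be at least attachment + 1")
  if (hub_degree > n_background)
    stop("hub_degree cannot exceed n_background")
  structure(list(n_background = as.integer(n_background),
                 attachment = as.integer(attachment),
                 n_hubs = as.integer(n_hubs),
                 hub_degree = as.integer(hub_degree),
                 score_range = as.numeric(score_range),
                 seed = as.integer(seed)),
            class = "network_sim_spec")
}

#' Simulate a weighted interaction network with planted hubs
#'
#' @param spec A [network_sim_spec()].
#' @return A list with elements `edges` (an `edge_list`), `hubs` (character
#'   vector of planted hub node IDs) and `nodes` (all node IDs).
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "network_sim_spec"))
  set.seed(spec$seed)
  g <- igraph::sample_pa(spec$n_background, m = spec$attachment,
                         directed = FALSE)
  bg_names <- sprintf("PRT%05d", seq_len(spec$n_background))
  ends <- igraph::as_edgelist(g, names = FALSE)
  a <- bg_names[ends[, 1L]]
  b <- bg_names[ends[, 2L]]
  hubs <- character(0)
  if (spec$n_hubs > 0L) {
    hubs <- sprintf("HUB%03d", seq_len(spec$n_hubs))
    for (h in hubs) {
      nb <- sample(bg_names, spec$hub_degree)
      a <- c(a, rep(h, spec$hub_degree))
      b <- c(b, nb)
    }
  }
  el <- data.frame(protein_a = a, protein_b = b,
                   score = stats::runif(length(a), spec$score_range[1],
                                        spec$score_range[2]),
                   stringsAsFactors = FALSE)
  el <- normalize_edge_list(el)
  list(edges = el, hubs = hubs, nodes = c(bg_names, hubs))
}

#' Write a complete simulated study to disk
#'
#' Produces the four pipeline input files plus ground-truth tables:
#' `expression.tsv`, `labels.tsv`, `ppi_edges.tsv` (STRING 0-1000 integer
#' dialect), `gene_map.tsv` mapping each informative probe's gene symbol to
#' one to three network proteins, `truth_probes.tsv` (probe roles) and
#' `truth_hubs.tsv` (planted hub IDs).
#'
#' @param expr_spec An [expression_sim_spec()].
#' @param net_spec A [network_sim_spec()].
#' @param dir Output directory, created if absent.
#' @param proteins_per_gene Range of network proteins mapped per informative
#'   gene (sampled uniformly).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_simulation <- function(expr_spec, net_spec, dir,
                             proteins_per_gene = c(1L, 3L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(expr_spec)
  net <- simulate_network(net_spec)

  paths <- list(expression = file.path(dir, "expression.tsv"),
                labels = file.path(dir, "labels.tsv"),
                edges = file.path(dir, "ppi_edges.tsv"),
                gene_map = file.path(dir, "gene_map.tsv"),
                truth_probes = file.path(dir, "truth_probes.tsv"),
                truth_hubs = file.path(dir, "truth_hubs.tsv"))

  write_expression_table(sim$dataset, paths$expression, paths$labels)
  write_edge_list(net$edges, paths$edges, dialect = "string")

  # map informative genes onto network proteins (seed set for path tracing);
  # derived from the two spec seeds so the full study is reproducible
  set.seed(expr_spec$seed + 1000L * net_spec$seed + 7L)
  inf <- sim$truth$probe_id[sim$truth$role == "informative"]
  symbols <- sim$dataset$gene_symbols[match(inf, sim$dataset$probe_ids)]
  map <- list()
  for (s in symbols) {
    k <- sample(seq(proteins_per_gene[1], proteins_per_gene[2]), 1L)
    map[[s]] <- sort(sample(net$nodes, k))
  }
  class(map) <- "gene_protein_map"
  write_gene_map(map, paths$gene_map)

  utils::write.table(sim$truth, paths$truth_probes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(hub_id = net$hubs), paths$truth_hubs,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
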