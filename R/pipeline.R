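#' Full pipeline configuration
#'
#' Collects input paths and stage parameters. Defaults reproduce the study's
#' settings: 500 ranked features, k = 1 nearest neighbour, IFS tolerance
#' 0.01, PPI confidence threshold 0.8, 1000 permutations of 8-protein seed
#' sets at alpha 0.05.
#'
#' @param expression,labels,edges,gene_map Paths to the four input files
#'   (the dialects of [read_expression_table()], [read_edge_list()] and
#'   [read_gene_map()]).
#' @param out_dir Output directory, created if absent.
#' @param N Features to rank.
#' @param k Neighbour count.
#' @param delta IFS accuracy tolerance.
#' @param threshold PPI confidence threshold (strict).
#' @param n_permutations,seed_set_size,alpha Permutation test settings.
#' @param estimator MI estimator.
#' @param standardize Per-feature z-scoring before distances.
#' @param seed Global RNG seed; per-stage seeds are derived by fixed offsets
#'   so stages rerun alone reproduce their outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, labels, edges, gene_map, out_dir,
                            N = 500L, k = 1L, delta = 0.01, threshold = 0.8,
                            n_permutations = 1000L, seed_set_size = 8L,
                            alpha = 0.05, estimator = "correlation",
                            standardize = FALSE, seed = 1L) {
  paths <- c(expression = expression, labels = labels, edges = edges,
             gene_map = gene_map)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(list(expression = expression, labels = labels, edges = edges,
                 gene_map = gene_map, out_dir = out_dir,
                 N = as.integer(N), k = as.integer(k), delta = delta,
                 threshold = threshold,
                 n_permutations = as.integer(n_permutations),
                 seed_set_size = as.integer(seed_set_size), alpha = alpha,
                 estimator = estimator, standardize = standardize,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full biomarker-discovery pipeline
#'
#' Stages run in the study's order: load inputs, mRMR ranking, IFS with
#' jackknife KNN, classification report at the selected size, network
#' construction and seed mapping, shortest-path sub-network and betweenness,
#' hub permutation test. Every stage communicates through files only; each
#' output carries the config hash, and rerunning with the same config and
#' seed reproduces all outputs bit-exactly. A stage failure writes a
#' `FAILED` marker naming the stage and re-raises the error; outputs of
#' completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the manifest contents.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  # hash the scientific parameters only, so reruns into a different output
  # directory are recognisably the same analysis
  params <- unclass(config)[setdiff(names(config), "out_dir")]
  tmp <- tempfile()
  yaml::write_yaml(params, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(config_hash = hash, stages = list())
  stage_file <- function(name) file.path(config$out_dir, name)

  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage: ", stage, "\nerror: ", conditionMessage(e)),
                 stage_file("FAILED"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  write_tsv <- function(df, name) {
    path <- stage_file(name)
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    close(con)
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    path
  }

  inputs <- run_stage("load_inputs", function() {
    list(dataset = read_expression_table(config$expression, config$labels),
         edges = read_edge_list(config$edges),
         map = read_gene_map(config$gene_map))
  })
  manifest$n_probes <- nrow(inputs$dataset$values)
  manifest$n_samples <- ncol(inputs$dataset$values)
  manifest$n_dropped_probes <- attr(inputs$dataset, "n_dropped")

  ranked <- run_stage("mrmr_rank", function() {
    mrmr_rank(inputs$dataset, N = config$N, estimator = config$estimator)
  })
  write_tsv(as.data.frame(ranked), "ranked_features.tsv")

  ifs <- run_stage("ifs", function() {
    ifs_curve(ranked, inputs$dataset, k = config$k, delta = config$delta,
              standardize = config$standardize)
  })
  curve <- ifs$accuracies
  curve$selected <- curve$size == ifs$selected_size
  write_tsv(curve, "ifs_curve.tsv")
  manifest$selected_size <- ifs$selected_size
  manifest$selected_accuracy <- ifs$selected_accuracy

  report <- run_stage("classify", function() {
    jackknife_accuracy(inputs$dataset,
                       ranked$probe_id[seq_len(ifs$selected_size)],
                       k = config$k, standardize = config$standardize)
  })
  write_tsv(data.frame(sample_id = inputs$dataset$sample_ids,
                       label = inputs$dataset$labels,
                       predicted = unname(report$predictions),
                       correct = inputs$dataset$labels == report$predictions),
            "classification.tsv")
  manifest$jackknife_accuracy <- report$accuracy
  manifest$confusion <- as.list(report$confusion)

  netres <- run_stage("network", function() {
    network <- build_network(inputs$edges, threshold = config$threshold)
    genes <- unique(ranked$gene_symbol[seq_len(ifs$selected_size)])
    seeds <- map_seed_proteins(genes, inputs$map, network)
    paths <- shortest_paths_among_seeds(network, seeds)
    list(network = network, seeds = seeds, paths = paths,
         betweenness = betweenness_counts(paths))
  })
  write_sif(netres$paths, stage_file("subnetwork.sif"),
            comment = paste("config_hash:", hash))
  bt <- netres$betweenness
  bt$is_seed <- bt$protein %in% netres$seeds
  write_tsv(bt, "betweenness.tsv")
  manifest$n_seed_proteins <- length(netres$seeds)
  manifest$subnetwork_nodes <- length(netres$paths$nodes)
  manifest$subnetwork_edges <- nrow(netres$paths$edges)

  permres <- run_stage("permutation", function() {
    permutation_test(netres$network, netres$betweenness,
                     permutation_config(n_permutations = config$n_permutations,
                                        seed_set_size = config$seed_set_size,
                                        alpha = config$alpha,
                                        rng_seed = config$seed + 400L))
  })
  write_tsv(as.data.frame(permres), "permutation.tsv")
  manifest$n_significant <- sum(permres$significant)

  jsonlite::write_json(manifest, stage_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
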