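#' Read a probes x samples expression table with phenotype labels
#'
#' Loads a tab-separated expression matrix (first column probe IDs, optional
#' second column gene symbols detected by header, remaining columns numeric
#' sample intensities) together with a two-column sample/label file, and
#' returns a validated `expression_dataset`.
#'
#' Rows containing any missing or non-numeric cell are dropped; the count of
#' dropped rows is reported via `message()` and stored in the `n_dropped`
#' attribute. Samples are restricted to the intersection of the matrix columns
#' and the label file, in label-file order.
#'
#' @param path Path to the tab-separated expression table. The header row
#'   holds sample IDs; a second column is treated as gene symbols when its
#'   header matches `symbol` or `gene` (case-insensitive).
#' @param labels_path Path to a two-column tab-separated file mapping
#'   sample ID to phenotype, given as `tumor`/`non-tumor` or `1`/`0`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `probe_ids`, `gene_symbols`, `values` (numeric matrix, probes x samples),
#'   `sample_ids` and `labels` (integer, 1 = tumour).
#' @export
read_expression_table <- function(path, labels_path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           colClasses = list(character = 1), showProgress = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs a probe column and at least one sample column")
  probe_ids <- as.character(tab[[1L]])
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup) > 0L) {
    stop("duplicate probe IDs in ", path, ": ", paste(utils::head(dup, 10L), collapse = ", "))
  }
  has_symbols <- ncol(tab) >= 3L &&
    grepl("symbol|^gene", tolower(names(tab)[2L]))
  gene_symbols <- if (has_symbols) as.character(tab[[2L]]) else rep("", length(probe_ids))
  gene_symbols[is.na(gene_symbols)] <- ""
  first_val <- if (has_symbols) 3L else 2L
  vals <- tab[, first_val:ncol(tab), drop = FALSE]
  vals <- as.matrix(as.data.frame(lapply(vals, function(col) suppressWarnings(as.numeric(col)))))
  colnames(vals) <- names(tab)[first_val:ncol(tab)]
  rownames(vals) <- probe_ids

  keep <- stats::complete.cases(vals)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("read_expression_table: dropped ", n_dropped,
            " probe row(s) with missing or non-numeric values")
    vals <- vals[keep, , drop = FALSE]
    probe_ids <- probe_ids[keep]
    gene_symbols <- gene_symbols[keep]
  }

  lab_tab <- data.table::fread(labels_path, sep = "\t", header = TRUE,
                               data.table = FALSE, colClasses = "character",
                               showProgress = FALSE)
  if (ncol(lab_tab) < 2L) stop("labels file needs two columns: sample_id, label")
  lab_samples <- as.character(lab_tab[[1L]])
  labels_raw <- tolower(trimws(as.character(lab_tab[[2L]])))
  labels_all <- ifelse(labels_raw %in% c("tumor", "tumour", "1"), 1L,
                ifelse(labels_raw %in% c("non-tumor", "non-tumour", "normal", "0"), 0L, NA_integer_))
  if (anyNA(labels_all)) {
    stop("unrecognized label value(s): ",
         paste(unique(labels_raw[is.na(labels_all)]), collapse = ", "))
  }
  common <- lab_samples[lab_samples %in% colnames(vals)]
  if (length(common) == 0L) stop("no sample IDs shared between expression table and labels file")
  vals <- vals[, common, drop = FALSE]
  labels <- labels_all[match(common, lab_samples)]

  new_expression_dataset(probe_ids, gene_symbols, vals, common, labels,
                         n_dropped = n_dropped)
}

#' Construct and validate an expression dataset
#'
#' Low-level constructor enforcing the container's invariants: matrix shape
#' matches the ID vectors, no missing values, unique probe and sample IDs.
#'
#' @param probe_ids Character vector of unique probe identifiers.
#' @param gene_symbols Character vector of per-probe symbols (may be `""`).
#' @param values Numeric matrix, probes x samples.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param labels Integer vector, one per sample, 1 = tumour, 0 = non-tumour.
#' @param n_dropped Count of probe rows dropped at load time.
#' @return An `expression_dataset` object.
#' @export
new_expression_dataset <- function(probe_ids, gene_symbols, values, sample_ids,
                                   labels, n_dropped = 0L) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values),
            nrow(values) == length(probe_ids),
            ncol(values) == length(sample_ids),
            length(labels) == length(sample_ids),
            length(gene_symbols) == length(probe_ids),
            !anyNA(values),
            !anyDuplicated(probe_ids),
            !anyDuplicated(sample_ids),
            all(labels %in% c(0L, 1L)))
  rownames(values) <- probe_ids
  colnames(values) <- sample_ids
  structure(list(probe_ids = as.character(probe_ids),
                 gene_symbols = as.character(gene_symbols),
                 values = values,
                 sample_ids = as.character(sample_ids),
                 labels = as.integer(labels)),
            n_dropped = as.integer(n_dropped),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$values), "probes x", ncol(x$values), "samples\n")
  cat("  tumour:", sum(x$labels == 1L), " non-tumour:", sum(x$labels == 0L), "\n")
  invisible(x)
}

#' Write an expression dataset back to the tab-separated dialect
#'
#' Emits the same layout `read_expression_table()` consumes, so a write/read
#' round trip reproduces the retained rows bit-exactly.
#'
#' @param dataset An `expression_dataset`.
#' @param path Output path for the expression table.
#' @param labels_path Output path for the two-column labels file.
#' @export
write_expression_table <- function(dataset, path, labels_path) {
  df <- data.frame(probe_id = dataset$probe_ids,
                   gene_symbol = dataset$gene_symbols,
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  lab <- data.frame(sample_id = dataset$sample_ids,
                    label = ifelse(dataset$labels == 1L, "tumor", "non-tumor"))
  data.table::fwrite(lab, labels_path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a STRING-style weighted protein interaction edge list
#'
#' Accepts whitespace- or tab-separated columns `protein_a`, `protein_b`,
#' `score`. The score dialect is auto-detected: any score above 1 means the
#' 0-1000 STRING integer scale, and all scores are divided by 1000. Self-loops
#' are removed and duplicate unordered pairs collapsed keeping the maximum
#' score, so normalization is idempotent.
#'
#' @param path Path to the edge-list file (header optional; a non-numeric
#'   third field on the first line is treated as a header).
#' @return A data frame of class `edge_list` with columns `protein_a`,
#'   `protein_b`, `score` (score in [0, 1]).
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[ \t]+")[[1]]
  if (length(fields) < 3L) stop("edge list needs at least 3 columns: protein_a, protein_b, score")
  has_header <- is.na(suppressWarnings(as.numeric(fields[3L])))
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("edge list needs at least 3 columns: protein_a, protein_b, score")
  el <- data.frame(protein_a = as.character(tab[[1L]]),
                   protein_b = as.character(tab[[2L]]),
                   score = as.numeric(tab[[3L]]),
                   stringsAsFactors = FALSE)
  if (anyNA(el$score)) stop("non-numeric interaction scores in ", path)
  if (any(el$score < 0) || any(el$score > 1000)) {
    stop("interaction scores must lie in [0, 1000]; found range [",
         min(el$score), ", ", max(el$score), "]")
  }
  if (any(el$score > 1)) el$score <- el$score / 1000
  normalize_edge_list(el)
}

normalize_edge_list <- function(el) {
  el <- el[el$protein_a != el$protein_b, , drop = FALSE]
  a <- pmin(el$protein_a, el$protein_b)
  b <- pmax(el$protein_a, el$protein_b)
  key <- paste(a, b, sep = "\r")
  score <- tapply(el$score, key, max)
  keys <- names(score)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(protein_a = vapply(parts, `[[`, "", 1L),
                    protein_b = vapply(parts, `[[`, "", 2L),
                    score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Write an edge list
#'
#' @param edges An `edge_list` data frame.
#' @param path Output path.
#' @param dialect `"unit"` writes scores in [0, 1] at full precision;
#'   `"string"` writes the 0-1000 integer STRING dialect.
#' @export
write_edge_list <- function(edges, path, dialect = c("unit", "string")) {
  dialect <- match.arg(dialect)
  out <- edges
  if (dialect == "string") {
    out$score <- as.integer(round(out$score * 1000))
  } else {
    out$score <- format(out$score, digits = 17, trim = TRUE, scientific = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene symbol to protein ID multimap
#'
#' Two-column table `gene_symbol`, `protein_id`; repeated gene rows
#' accumulate, so one gene may map to several proteins (the study's 10 probes
#' gave 9 symbols mapping to 27 STRING proteins). Lookups of absent genes via
#' [map_lookup()] return the empty set rather than failing.
#'
#' @param path Path to the mapping file (header optional).
#' @return A named list of class `gene_protein_map`; each element is the
#'   character set of protein IDs for one gene symbol.
#' @export
read_gene_map <- function(path) {
  if (file.size(path) == 0) stop("empty gene map file: ", path)
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  has_header <- length(first) >= 2L &&
    grepl("gene|symbol", tolower(first[1L]))
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) stop("empty gene map file: ", path)
  if (ncol(tab) < 2L) stop("gene map needs two columns: gene_symbol, protein_id")
  m <- lapply(split(tab[[2L]], tab[[1L]]), function(p) sort(unique(p)))
  message("read_gene_map: ", length(m), " gene(s) mapping to ",
          length(unique(unlist(m))), " distinct protein(s)")
  structure(m, class = "gene_protein_map")
}

#' Look up the protein set of a gene symbol
#'
#' @param map A `gene_protein_map`.
#' @param gene A single gene symbol.
#' @return Character vector of protein IDs; `character(0)` if unmapped.
#' @export
map_lookup <- function(map, gene) {
  hit <- map[[gene]]
  if (is.null(hit)) character(0) else hit
}

#' Write a gene map
#' @param map A `gene_protein_map`.
#' @param path Output path.
#' @export
write_gene_map <- function(map, path) {
  df <- data.frame(gene_symbol = rep(names(map), lengths(map)),
                   protein_id = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
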