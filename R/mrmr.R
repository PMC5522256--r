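#' Greedy minimum-redundancy-maximum-relevance probe ranking
#'
#' Ranks probes by the mRMR criterion: the first feature is the one with the
#' highest mutual information with the phenotype; each subsequent step adds
#' the remaining feature maximizing
#' \deqn{q = I(x_j, y) - \frac{1}{|S|} \sum_{x_k \in S} I(x_j, x_k)}
#' where \eqn{S} is the set already selected. The stored score for the first
#' feature is its relevance. Ties are broken by input probe order (scores
#' within 1e-9 of the step maximum count as tied, so mathematically equal
#' scores cannot be split by floating-point accumulation order) and the
#' ranking is deterministic.
#'
#' @param dataset An `expression_dataset` with both classes present.
#' @param N Number of features to rank (default 500, the study's choice);
#'   silently capped at the probe count with a warning.
#' @param estimator MI estimator passed to [estimate_mi()].
#' @param bins Bin count for the binned estimator.
#' @return A data frame of class `ranked_features` with columns `rank`,
#'   `probe_id`, `gene_symbol`, `q_score`, plus attributes `estimator_tag`
#'   and `relevance` (the full named relevance vector, for diagnostics).
#' @export
mrmr_rank <- function(dataset, N = 500L, estimator = c("correlation", "binned"),
                      bins = 3L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(unique(dataset$labels)) < 2L)
    stop("both phenotype classes must be present for ranking")
  if (N < 1L) stop("N must be >= 1")
  P <- nrow(dataset$values)
  if (N > P) {
    warning("N = ", N, " exceeds usable probe count ", P, "; capped")
    N <- P
  }
  vals <- dataset$values
  y <- as.numeric(dataset$labels)
  relevance <- mi_rows(vals, y, estimator, bins)
  names(relevance) <- dataset$probe_ids

  selected <- integer(N)
  q_scores <- numeric(N)
  remaining <- rep(TRUE, P)
  red_sum <- numeric(P)

  for (step in seq_len(N)) {
    q <- if (step == 1L) relevance else relevance - red_sum / (step - 1L)
    q[!remaining] <- -Inf
    # ties (within numerical noise) resolve to the lowest input index
    pick <- which(q >= max(q) - 1e-9)[1L]
    selected[step] <- pick
    q_scores[step] <- q[pick]
    remaining[pick] <- FALSE
    if (step < N && any(remaining)) {
      idx <- which(remaining)
      red_sum[idx] <- red_sum[idx] +
        mi_pair_rows(vals, pick, idx, estimator, bins)
    }
  }

  out <- data.frame(rank = seq_len(N),
                    probe_id = dataset$probe_ids[selected],
                    gene_symbol = dataset$gene_symbols[selected],
                    q_score = q_scores,
                    stringsAsFactors = FALSE)
  structure(out, estimator_tag = estimator, relevance = relevance,
            class = c("ranked_features", "data.frame"))
}

# MI of row `pick` against each row in `idx`
mi_pair_rows <- function(vals, pick, idx, estimator, bins) {
  x <- vals[pick, ]
  if (estimator == "correlation") {
    sds <- apply(vals[idx, , drop = FALSE], 1L, stats::sd)
    r <- rep(0, length(idx))
    ok <- sds > 0 & stats::sd(x) > 0
    if (any(ok)) {
      r[ok] <- suppressWarnings(
        as.numeric(stats::cor(t(vals[idx[ok], , drop = FALSE]), x)))
    }
    -0.5 * log(1 - pmin(r^2, 1 - 1e-12))
  } else {
    vapply(idx, function(i) {
      if (stats::sd(vals[i, ]) == 0 || stats::sd(x) == 0) 0
      else mi_binned(vals[i, ], x, bins)
    }, numeric(1))
  }
}

#' Rank probes by relevance only
#'
#' Plain maximum-relevance ordering (mutual information with the phenotype,
#' no redundancy penalty); the contrast with [mrmr_rank()] shows how mRMR
#' demotes near-duplicate probes.
#'
#' @inheritParams mrmr_rank
#' @return A `ranked_features` data frame; `q_score` holds the relevance.
#' @export
relevance_rank <- function(dataset, N = 500L,
                           estimator = c("correlation", "binned"), bins = 3L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(dataset, "expression_dataset"))
  P <- nrow(dataset$values)
  N <- min(N, P)
  relevance <- mi_rows(dataset$values, as.numeric(dataset$labels), estimator, bins)
  ord <- order(-relevance, seq_len(P))[seq_len(N)]
  structure(data.frame(rank = seq_len(N),
                       probe_id = dataset$probe_ids[ord],
                       gene_symbol = dataset$gene_symbols[ord],
                       q_score = relevance[ord],
                       stringsAsFactors = FALSE),
            estimator_tag = estimator,
            class = c("ranked_features", "data.frame"))
}
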