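#' Incremental feature selection curve
#'
#' Evaluates the nested prefixes \eqn{s_i = \{f_1, \ldots, f_i\}} of a ranked
#' feature list by jackknife k-nearest-neighbour accuracy and selects the
#' subset size. Following the study's parsimony argument (a 10-probe set at
#' accuracy 0.88 was preferred over an 80-probe set at 0.89), the selected
#' size is the smallest i whose accuracy is within `delta` of the maximum;
#' `delta = 0` reduces to the smallest argmax.
#'
#' @param ranked A `ranked_features` data frame from [mrmr_rank()].
#' @param dataset The `expression_dataset` the ranking came from.
#' @param k Neighbour count for the classifier.
#' @param N Largest subset size to evaluate (default: full ranking length).
#' @param delta Accuracy tolerance for the parsimonious choice (default 0.01).
#' @param standardize Passed to [jackknife_accuracy()].
#' @return A list of class `ifs_result`: `accuracies` (data frame `size`,
#'   `accuracy`), `selected_size`, `selected_accuracy`, `tolerance`, `k`.
#' @export
ifs_curve <- function(ranked, dataset, k = 1L, N = nrow(ranked), delta = 0.01,
                      standardize = FALSE) {
  stopifnot(inherits(ranked, "ranked_features"), nrow(ranked) >= 1L,
            delta >= 0)
  N <- min(N, nrow(ranked))
  acc <- numeric(N)
  for (i in seq_len(N)) {
    acc[i] <- jackknife_accuracy(dataset, ranked$probe_id[seq_len(i)], k = k,
                                 standardize = standardize)$accuracy
  }
  selected <- which(acc >= max(acc) - delta)[1L]
  structure(list(accuracies = data.frame(size = seq_len(N), accuracy = acc),
                 selected_size = selected,
                 selected_accuracy = acc[selected],
                 tolerance = delta,
                 k = k),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("IFS curve over", nrow(x$accuracies), "subset sizes\n")
  cat("  max accuracy:", sprintf("%.4f", max(x$accuracies$accuracy)),
      "at size", with(x$accuracies, size[which.max(accuracy)]), "\n")
  cat("  selected size:", x$selected_size,
      sprintf("(accuracy %.4f, tolerance %.3g)", x$selected_accuracy,
              x$tolerance), "\n")
  invisible(x)
}
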