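#' Estimate mutual information between two variables
#'
#' Two estimators are offered, both returning MI in nats:
#' \describe{
#'   \item{correlation}{The Gaussian/correlation estimator
#'     \eqn{-\tfrac12 \ln(1 - \rho^2)} with \eqn{\rho} the Pearson
#'     correlation (point-biserial when one variable is binary).
#'     \eqn{\rho^2} is clipped to at most \eqn{1 - 10^{-12}}, so identical
#'     vectors return the finite cap \eqn{\tfrac12 \ln 10^{12} \approx 13.8}.}
#'   \item{binned}{Each continuous variable is discretized into `bins`
#'     equal-frequency bins and the plug-in discrete MI is computed.
#'     Variables with no more distinct values than `bins` (e.g. a binary
#'     phenotype) are used as-is.}
#' }
#' Zero-variance input yields MI 0 with a warning. Both estimators are
#' symmetric in their arguments and non-negative.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param estimator `"correlation"` (default) or `"binned"`.
#' @param bins Equal-frequency bin count for the binned estimator.
#' @return Mutual information in nats (non-negative scalar).
#' @export
estimate_mi <- function(x, y, estimator = c("correlation", "binned"), bins = 3L) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; MI defined as 0")
    return(0)
  }
  if (estimator == "correlation") mi_correlation(x, y) else mi_binned(x, y, bins)
}

mi_correlation <- function(x, y) {
  r2 <- min(stats::cor(x, y)^2, 1 - 1e-12)
  -0.5 * log(1 - r2)
}

mi_binned <- function(x, y, bins = 3L) {
  xd <- discretize_ef(x, bins)
  yd <- discretize_ef(y, bins)
  tab <- table(xd, yd)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  pos <- p > 0
  mi <- sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
  max(mi, 0)
}

# equal-frequency discretization; values already coarser than the bin count
# (e.g. binary labels) pass through untouched
discretize_ef <- function(x, bins) {
  if (length(unique(x)) <= bins) return(factor(x))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 2L) return(factor(x))
  cut(x, breaks = br, include.lowest = TRUE)
}

# vectorized correlation MI of each matrix row against a target vector;
# zero-variance rows get 0 silently (they carry no information by definition)
mi_rows <- function(values, target, estimator = "correlation", bins = 3L) {
  if (estimator == "correlation") {
    sds <- apply(values, 1L, stats::sd)
    r <- rep(0, nrow(values))
    ok <- sds > 0 & stats::sd(target) > 0
    if (any(ok)) {
      r[ok] <- suppressWarnings(as.numeric(stats::cor(t(values[ok, , drop = FALSE]), target)))
    }
    r2 <- pmin(r^2, 1 - 1e-12)
    -0.5 * log(1 - r2)
  } else {
    apply(values, 1L, function(row) {
      if (stats::sd(row) == 0 || stats::sd(target) == 0) 0 else mi_binned(row, target, bins)
    })
  }
}
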