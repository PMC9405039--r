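#' Shannon entropy of a discrete variable, in bits
#'
#' \eqn{H(X) = -\sum_x P(x) \log_2 P(x)} over the observed values, with
#' \eqn{0 \log 0 = 0}.
#'
#' @param x Vector of discrete values (any atomic type).
#' @return Entropy in bits.
#' @export
entropy <- function(x) {
  if (length(x) == 0) stop("entropy of an empty vector is undefined")
  if (anyNA(x)) stop("entropy input must not contain missing values")
  p <- tabulate(factor(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional entropy of the labels given a discrete feature, in bits
#'
#' \eqn{H(Y \mid X) = \sum_x P(x) H(Y \mid X = x)}: the average label entropy
#' within each feature-value stratum, weighted by stratum probability.
#'
#' @param feature Vector of discrete feature values.
#' @param labels Vector of class labels, same length.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(feature, labels) {
  if (length(feature) != length(labels)) {
    stop("feature and labels must have equal length")
  }
  strata <- split(labels, factor(feature))
  w <- vapply(strata, length, numeric(1)) / length(labels)
  h <- vapply(strata, entropy, numeric(1))
  sum(w * h)
}

#' Discretizer specification for continuous features
#'
#' Entropy estimation needs discrete values; continuous features are binned
#' first. Equal-frequency binning (quantile cut points) is the default: it is
#' robust to the skewed ranges typical of clinical measurements. Equal-width
#' binning is available as an alternative.
#'
#' @param method `"frequency"` (equal-frequency, default) or `"width"`
#'   (equal-width).
#' @param bins Number of bins (default 10).
#' @return An object of class `discretizer`.
#' @export
discretizer <- function(method = c("frequency", "width"), bins = 10) {
  method <- match.arg(method)
  stopifnot(bins >= 2)
  structure(list(method = method, bins = bins), class = "discretizer")
}

#' Bin a numeric vector according to a discretizer
#'
#' A feature with at most `disc$bins` distinct values is already discrete and
#' is returned as-is (nominal codes are never re-binned).
#'
#' @param x Numeric vector.
#' @param disc A [discretizer()].
#' @return An integer/numeric vector of bin identifiers.
#' @export
discretize <- function(x, disc = discretizer()) {
  ux <- unique(x)
  if (length(ux) <= disc$bins) return(x)
  if (disc$method == "frequency") {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = disc$bins + 1),
                          names = FALSE, type = 7))
  } else {
    br <- seq(min(x), max(x), length.out = disc$bins + 1)
  }
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Information gain of a feature about the class labels
#'
#' \eqn{IG(Y; X) = H(Y) - H(Y \mid X)}: the reduction in class entropy from
#' conditioning on the (discretized) feature. Always in
#' \eqn{[0, H(Y)]} up to floating-point tolerance.
#'
#' @param feature Numeric or discrete feature vector.
#' @param labels Class labels, same length.
#' @param disc A [discretizer()] applied to continuous features.
#' @return Information gain in bits.
#' @export
information_gain <- function(feature, labels, disc = discretizer()) {
  f <- if (is.numeric(feature)) discretize(feature, disc) else feature
  entropy(labels) - conditional_entropy(f, labels)
}

#' Rank every feature of a design matrix by information gain
#'
#' Each feature is scored in isolation (univariate filter); the ranking is
#' sorted by decreasing IG with ties broken by original column order, so
#' duplicate columns rank adjacently and deterministically.
#'
#' @param dm A [design_matrix()].
#' @param disc A [discretizer()].
#' @return An object of class `feature_ranking`: a data frame with columns
#'   `rank`, `feature`, `ig` (bits), carrying the class entropy as attribute
#'   `"h_class"`.
#' @export
rank_features <- function(dm, disc = discretizer()) {
  ig <- vapply(seq_len(ncol(dm$X)),
               function(j) information_gain(dm$X[, j], dm$y, disc),
               numeric(1))
  feature_ranking(dm$feature_names, ig, h_class = entropy(dm$y))
}

#' Assemble a feature ranking from names and IG values
#'
#' Used both by [rank_features()] and to inject externally computed IG
#' values (e.g. a published ranking) into the selection machinery.
#'
#' @param features Character vector of feature names.
#' @param ig Numeric vector of IG values in bits.
#' @param h_class Optional class entropy (bits) for the bound check.
#' @return A `feature_ranking` data frame sorted by decreasing IG, ties in
#'   input order.
#' @export
feature_ranking <- function(features, ig, h_class = NULL) {
  stopifnot(length(features) == length(ig))
  ord <- order(-ig)  # stable: ties keep input order
  out <- data.frame(rank = seq_along(ig), feature = features[ord],
                    ig = ig[ord], stringsAsFactors = FALSE)
  attr(out, "h_class") <- h_class
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Standard-deviation threshold for feature selection
#'
#' The population standard deviation (divisor N) of all IG values in the
#' ranking, returned at full precision. Selection compares IG values against
#' it after rounding both to 3 decimals (see [select_features()]).
#'
#' @param ranking A `feature_ranking`.
#' @return The threshold in bits.
#' @export
std_threshold <- function(ranking) {
  ig <- ranking$ig
  if (length(ig) < 2) stop("threshold needs at least two ranked features")
  sqrt(mean((ig - mean(ig))^2))
}

#' Select the features whose IG clears a threshold
#'
#' A feature is kept when its IG is greater than or equal to the threshold.
#' By convention both sides are rounded to 3 decimals before comparison
#' (`digits = 3`); pass `digits = NULL` for full-precision comparison.
#'
#' @param ranking A `feature_ranking`.
#' @param threshold Threshold in bits; defaults to [std_threshold()] of the
#'   ranking.
#' @param digits Decimal places used for the comparison (default 3), or
#'   `NULL` for no rounding.
#' @return An object of class `selection_result`: list with `threshold`,
#'   `selected` and `discarded` feature-name vectors (in rank order).
#' @export
select_features <- function(ranking, threshold = std_threshold(ranking),
                            digits = 3) {
  stopifnot(is.finite(threshold), threshold >= 0)
  ig <- ranking$ig
  thr <- threshold
  if (!is.null(digits)) {
    ig <- round(ig, digits)
    thr <- round(threshold, digits)
  }
  keep <- ig >= thr
  if (!any(keep)) warning("threshold exceeds every IG value; empty selection")
  structure(list(threshold = threshold,
                 selected = ranking$feature[keep],
                 discarded = ranking$feature[!keep]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("feature selection: threshold", format(round(x$threshold, 4)),
      "bits;", length(x$selected), "selected,",
      length(x$discarded), "discarded\n")
  if (length(x$discarded)) {
    cat("  discarded:", paste(x$discarded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a feature ranking as TSV
#'
#' Columns rank, feature, IG — the conventional ranking-table layout.
#'
#' @param ranking A `feature_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
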