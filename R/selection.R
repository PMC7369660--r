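#' Standardize the feature columns of a labelled table
#'
#' Centers each feature column to mean 0 and scales to unit sample
#' standard deviation (denominator `n - 1`). Constant columns become all
#' zero and are reported in the `constant` attribute instead of producing
#' `NaN`. The `label` column, if present, is passed through untouched.
#'
#' @param table Data frame of numeric features, optionally with a `label`
#'   column.
#' @param center,scale Optional precomputed centering/scaling vectors (as
#'   returned in attributes), so a test fold can be standardized with the
#'   training fold's parameters.
#' @return The standardized table with attributes `center`, `scale`, and
#'   `constant` (logical per feature).
#' @export
normalize_features <- function(table, center = NULL, scale = NULL) {
  stopifnot(is.data.frame(table), nrow(table) >= 2)
  featcols <- setdiff(names(table), "label")
  X <- as.matrix(table[featcols])
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, stats::sd)
  const <- !is.finite(scale) | scale == 0
  scale_use <- ifelse(const, 1, scale)
  Z <- sweep(sweep(X, 2, center, "-"), 2, scale_use, "/")
  Z[, const] <- 0
  out <- as.data.frame(Z)
  if ("label" %in% names(table)) out$label <- table$label
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  attr(out, "constant") <- const
  out
}

#' One-way ANOVA F test for a single feature
#'
#' Classical one-way fixed-effects ANOVA of a numeric feature across
#' classes: `F = MS_between / MS_within` with `(k - 1, n - k)` degrees of
#' freedom and the p-value from the upper tail of the F distribution
#' (equal-variance `oneway.test`). The degenerate case of zero
#' within-class variance with unequal class means is reported as
#' `F = Inf`, `p = 0` with `degenerate = TRUE` rather than `NaN`.
#'
#' @param x Numeric vector.
#' @param g Class labels (coerced to factor); every class needs >= 2
#'   members.
#' @return List with `statistic` (F), `p.value`, `df` (length 2), and
#'   `degenerate`.
#' @examples
#' anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3)) # F = 13.5
#' @export
anova_oneway <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least two classes")
  n_k <- table(g)
  if (any(n_k < 2)) stop("degenerate group: every class needs >= 2 members")
  k <- nlevels(g); n <- length(x)
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  means <- tapply(x, g, mean)
  if (ssw == 0) {
    degen <- length(unique(means)) > 1
    return(list(statistic = if (degen) Inf else NaN,
                p.value = if (degen) 0 else NaN,
                df = c(k - 1, n - k), degenerate = TRUE))
  }
  ht <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       df = unname(c(ht$parameter[1], ht$parameter[2])), degenerate = FALSE)
}

#' Rank features by ANOVA and keep the most discriminative
#'
#' Computes the one-way F statistic of every feature column against the
#' class labels, ranks by ascending p-value (ties broken by original
#' column order), and keeps either the top `k` features or, in
#' significance mode, all features with `p < alpha`.
#'
#' @param table Data frame with feature columns and a `label` column.
#' @param k Number of features to keep (mutually exclusive with `alpha`).
#' @param alpha Significance level for threshold mode.
#' @return The reduced table (selected features + `label`), with an
#'   `anova` attribute: data frame of feature, F, p, rank, selected.
#' @export
select_features <- function(table, k = NULL, alpha = NULL) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  featcols <- setdiff(names(table), "label")
  if (is.null(k) == is.null(alpha))
    stop("give exactly one of `k` or `alpha`")
  if (!is.null(k) && (k < 1 || k > length(featcols)))
    stop("empty selection: `k` must be in 1..number of features")
  res <- lapply(featcols, function(f) anova_oneway(table[[f]], table$label))
  Fv <- vapply(res, `[[`, 0, "statistic")
  pv <- vapply(res, `[[`, 0, "p.value")
  ord <- order(pv, seq_along(pv))   # deterministic tie-break: column order
  rank <- match(seq_along(pv), ord)
  keep <- if (!is.null(k)) ord[seq_len(k)] else which(pv < alpha)
  keep <- sort(keep)                # preserve original column order
  if (!length(keep)) stop("empty selection: no feature passes alpha")
  out <- table[c(featcols[keep], "label")]
  attr(out, "anova") <- data.frame(
    feature = featcols, statistic = Fv, p.value = pv, rank = rank,
    selected = seq_along(featcols) %in% keep)
  out
}
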