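#' ARD relevance-increase feature pre-selection
#'
#' Implements the relevance thresholding used to prune GP-LVM latent
#' dimensions. Relevances (inverse squared ARD lengthscales) are sorted; the
#' per-feature relevance increase is the gap by which a feature exceeds the
#' next-smaller one; the threshold is the median of these increases. Walking
#' the features from most to least relevant — the most relevant feature
#' anchors the walk and is always kept — features are kept until the first
#' one whose increase falls strictly below the median; that feature and all
#' less relevant ones are dropped. With all increases equal (e.g., constant
#' relevances) nothing falls strictly below the median and every feature is
#' kept. The rule is scale-invariant.
#'
#' @param relevances nonnegative numeric vector, length >= 2.
#' @return object of class `selection_result` with fields `ordering` (feature
#'   indices by descending relevance), `increases` (aligned to `ordering`; the
#'   last, least relevant feature has increase `NA`), `threshold` (median
#'   increase), `relevance_kept` (indices surviving the rule) and `rule` (text
#'   record).
#' @export
relevance_threshold_select <- function(relevances) {
  if (length(relevances) < 2) {
    warning("fewer than 2 relevances; keeping all features")
    return(structure(list(ordering = order(relevances, decreasing = TRUE),
                          increases = NA_real_, threshold = NA_real_,
                          relevance_kept = seq_along(relevances),
                          rule = "fewer than 2 features: keep all"),
                     class = "selection_result"))
  }
  if (any(relevances < 0)) stop_param("relevances must be nonnegative")
  d <- length(relevances)
  ord_desc <- order(relevances, decreasing = TRUE)
  inc_asc <- diff(sort(relevances)) # inc_asc[i] reaches ascending position i+1
  threshold <- stats::median(inc_asc)
  # increase of the feature at descending rank j (j = 1..d-1) is inc_asc[d-j],
  # its relevance gap to the next-less-relevant feature; the least relevant
  # feature has no gap below it and is kept only if the walk reaches it. The
  # most relevant feature anchors the walk and is always informative: a small
  # gap between two top features signals two informative features, not a flat
  # tail.
  inc_desc <- c(inc_asc[(d - 1):1], NA_real_)
  informative <- c(TRUE, inc_desc[seq_len(d - 2) + 1] >= threshold, TRUE)[seq_len(d)]
  first_bad <- which(!informative)[1]
  kept_ranks <- if (is.na(first_bad)) seq_len(d) else seq_len(first_bad - 1)
  structure(list(ordering = ord_desc,
                 increases = inc_desc,
                 threshold = threshold,
                 relevance_kept = sort(ord_desc[kept_ranks]),
                 rule = paste("increases = successive diffs of sorted relevances;",
                              "threshold = median(increases); walk descending",
                              "from the most relevant feature (always kept) and",
                              "stop at the first feature whose gap to the next",
                              "lower relevance is < threshold")),
            class = "selection_result")
}

# all permutations of 1..n as an n! x n integer matrix (n <= 9)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- .permutations(n - 1)
  k <- nrow(p)
  out <- matrix(0L, n * k, n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * k + seq_len(k)
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[p], k)
  }
  out
}

#' Spearman rank-correlation test
#'
#' Computes Spearman's rho as the Pearson correlation of (average-tie) ranks
#' and a two-sided p-value: by exhaustive enumeration of all `n!` rank
#' permutations for `n <= exact_limit`, otherwise by the usual t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 4 (`y` may be binary).
#' @param exact_limit sample-size cutoff for exact enumeration (default 9).
#' @return list with `rho`, `p_value`, `method`.
#' @export
spearman_test <- function(x, y, exact_limit = 9) {
  n <- length(x)
  if (length(y) != n) stop_param("x and y must have equal length")
  if (n < 4) stop_param("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: rho undefined, p = 1")
    return(list(rho = NA_real_, p_value = 1, method = "degenerate"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    P <- .permutations(n)
    cx <- rx - mean(rx); cy <- ry - mean(ry)
    # correlation of cx with every permutation of cy, up to common scale
    scores <- abs(matrix(cy[P], nrow(P)) %*% cx)
    p <- mean(scores >= abs(sum(cx * cy)) - 1e-9)
    method <- "exact_permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p_value = min(p, 1), method = method)
}

#' Spearman feature selection against a binary label
#'
#' Tests each feature column for a monotone relation with the class label and
#' keeps the features whose two-sided p-value is at or below `alpha` (default
#' 0.1). No multiple-testing correction is applied by default; a
#' Benjamini-Hochberg option is available.
#'
#' @param features `N x k` numeric matrix (rows = samples).
#' @param labels binary vector with both classes present.
#' @param alpha significance level (default 0.1).
#' @param correction `"none"` (default) or `"BH"`.
#' @param relevance_result optional [relevance_threshold_select()] output; when
#'   supplied, only the surviving features are tested and `selected` is a
#'   subset of `relevance_kept` (GP-LVM path). Autoencoder codes carry no ARD
#'   relevance and go straight to the Spearman stage.
#' @return a `selection_result` with `rho`, `p_values` (NA for untested
#'   features), `alpha` and `selected` (final feature indices).
#' @export
spearman_select <- function(features, labels, alpha = 0.1,
                            correction = c("none", "BH"),
                            relevance_result = NULL) {
  correction <- match.arg(correction)
  features <- as.matrix(features)
  if (length(unique(labels)) < 2) stop_data("labels must contain both classes")
  if (nrow(features) != length(labels)) stop_param("features/labels misaligned")
  k <- ncol(features)
  candidates <- if (is.null(relevance_result)) seq_len(k) else
    intersect(relevance_result$relevance_kept, seq_len(k))
  rho <- rep(NA_real_, k); p <- rep(NA_real_, k)
  for (j in candidates) {
    res <- suppressWarnings(spearman_test(features[, j], labels))
    rho[j] <- res$rho
    p[j] <- res$p_value
  }
  p_eff <- p
  if (correction == "BH") p_eff[candidates] <- stats::p.adjust(p[candidates], "BH")
  selected <- candidates[!is.na(p_eff[candidates]) & p_eff[candidates] <= alpha]
  structure(list(ordering = relevance_result$ordering %||% order(abs(rho), decreasing = TRUE),
                 increases = relevance_result$increases %||% NULL,
                 threshold = relevance_result$threshold %||% NULL,
                 relevance_kept = candidates,
                 rho = rho, p_values = p, alpha = alpha,
                 correction = correction, selected = selected,
                 rule = paste0("Spearman two-sided p <= ", alpha,
                               if (correction == "BH") " (BH-adjusted)" else
                                 " (no multiplicity correction)")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", x$rule, "\n")
  if (!is.null(x$selected)) cat("selected features:",
                                paste(x$selected, collapse = ", "), "\n")
  else cat("relevance-kept features:",
           paste(x$relevance_kept, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection result as CSV
#' @param sel a `selection_result` from [spearman_select()].
#' @param path output path.
#' @export
write_selection_csv <- function(sel, path) {
  k <- length(sel$rho)
  utils::write.csv(data.frame(feature = seq_len(k),
                              rho = sel$rho, p_value = sel$p_values,
                              selected = seq_len(k) %in% sel$selected),
                   path, row.names = FALSE)
  invisible(path)
}
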