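## Correlation and one-way ANOVA from the direct formulas, plus the
## reporter-versus-clustering analysis.

#' Pearson or Spearman correlation with a t-approximation p-value
#'
#' Pearson uses the product-moment formula; Spearman applies it to ranks
#' with average ranks for ties. The p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom, or an
#' optional permutation test for small samples.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite).
#' @param method "pearson" or "spearman".
#' @param n_perm If > 0, a permutation p-value with this many draws is
#'   computed instead of the t approximation.
#' @return Object of class `correlation_result`: list with `method`,
#'   `coefficient`, `p_value`, `n`, and `undefined` (TRUE when a series
#'   has zero variance, in which case the coefficient is NA).
#' @export
correlation <- function(x, y, method = c("pearson", "spearman"),
                        n_perm = 0L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  n <- length(x)
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    return(structure(list(method = method, coefficient = NA_real_,
                          p_value = NA_real_, n = n, undefined = TRUE),
                     class = "correlation_result"))
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- min(max(r, -1), 1)
  if (n_perm > 0L) {
    r_perm <- vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      sum(dx * (yp - mean(yp))) / sqrt(sxx * sum((yp - mean(yp))^2))
    }, 0)
    p <- (1 + sum(abs(r_perm) >= abs(r) - 1e-12)) / (n_perm + 1)
  } else if (abs(r) == 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(method = method, coefficient = r, p_value = p, n = n,
                 undefined = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f, p = %.3g, n = %d\n",
              x$method, x$coefficient, x$p_value, x$n))
  invisible(x)
}

#' Ordinary one-way ANOVA
#'
#' Between/within mean-square ratio on (k - 1, N - k) degrees of freedom,
#' computed from the sums of squares.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return List with `F`, `p_value`, `df` (length-2), and the sums of
#'   squares `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 2L)) stop("each group needs at least 2 values")
  all_v <- unlist(groups)
  gm <- mean(all_v)
  means <- vapply(groups, mean, 0)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1L
  df2 <- length(all_v) - length(groups)
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else {
    f <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, p_value = p, df = c(df1, df2), ss_between = ssb,
       ss_within = ssw)
}

#' Correlate reporter signal with the clustering proxy
#'
#' Pearson correlation of the reporter-channel per-cell mean intensity
#' against the fluorophore per-cell SDI, quantified on the same frame —
#' the activity-versus-clustering analysis.
#'
#' @param cell_stats data.frame with per-cell columns `reporter_mi` and
#'   `sdi`.
#' @return List with `cor` (a [correlation()] result) and `scatter`
#'   (the analyzed table).
#' @export
reporter_vs_clustering <- function(cell_stats) {
  stopifnot(all(c("reporter_mi", "sdi") %in% names(cell_stats)))
  if (nrow(cell_stats) < 3L) stop("need at least 3 cells")
  res <- correlation(cell_stats$reporter_mi, cell_stats$sdi,
                     method = "pearson")
  list(cor = res, scatter = cell_stats[, c("reporter_mi", "sdi")])
}
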