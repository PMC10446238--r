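# Z-score matrices for heatmaps, deterministic cluster ordering, and
# the group-level fold-change statistics (classical one-way ANOVA,
# Spearman rank correlation).

#' Row-wise z-scores of a fold-change matrix
#'
#' Standardises each gene's fold-changes across the mutant contrasts to
#' standard deviations above or below the gene's own mean, the scale
#' used for the cohort heatmaps.  The sample (n-1) standard deviation
#' is the default; with only three contrasts the choice matters, so a
#' population mode is available.
#'
#' @param m Numeric matrix, genes in rows, contrasts in columns (>= 2
#'   columns).
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"` (n).
#' @return Matrix of the same shape; constant rows become all zeros
#'   with a warning.
#' @export
row_zscores <- function(m, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least two columns per row")
  n_finite <- rowSums(is.finite(m))
  if (any(n_finite < 2)) {
    stop("row with fewer than two finite values: ",
         paste(utils::head(which(n_finite < 2), 5), collapse = ", "))
  }
  mu <- rowMeans(m)
  dev <- m - mu
  denom <- if (sd_type == "sample") ncol(m) - 1 else ncol(m)
  s <- sqrt(rowSums(dev^2) / denom)
  constant <- s == 0
  if (any(constant)) {
    warning(sum(constant), " constant row(s) mapped to all-zero z-scores")
    s[constant] <- 1
  }
  z <- dev / s
  dimnames(z) <- dimnames(m)
  z
}

#' Deterministic heatmap row order from agglomerative clustering
#'
#' Average-linkage agglomerative clustering on Euclidean distances,
#' with the leaf order read off the dendrogram.  The procedure is fully
#' deterministic: equal-distance merges resolve by input order, so the
#' same matrix always yields the same permutation.
#'
#' @param m Numeric matrix with >= 2 rows (typically a z-score matrix).
#' @return Integer permutation of the row indices.
#' @export
cluster_order <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) return(seq_len(nrow(m)))
  hclust(dist(m, method = "euclidean"), method = "average")$order
}

#' Classical one-way ANOVA on groups of fold-changes
#'
#' F and p from the explicit sum-of-squares decomposition.  When every
#' observation is identical (both sums of squares zero) the groups are
#' indistinguishable and the result is F = 0, p = 1 rather than an
#' error, so degenerate synthetic inputs are handled gracefully.
#'
#' @param groups Named list of >= 2 numeric vectors, each of length
#'   >= 2.
#' @return List with `F`, `p`, `df` (numerator, denominator),
#'   `group_means` and `group_sds`.
#' @export
compare_group_fc <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("each group needs at least two values")
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) stop("missing values in groups")
  k <- length(groups)
  n <- length(values)
  grand <- mean(values)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  if (ss_between == 0 && ss_within == 0) {
    f <- 0; p <- 1
  } else if (ss_within == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, p = p, df = c(df1, df2),
       group_means = means,
       group_sds = vapply(groups, sd, numeric(1)))
}

#' Spearman rank correlation with two-tailed p
#'
#' Rho is the Pearson correlation of average-ranked data (ties get
#' average ranks).  The default p-value uses the t approximation with
#' n - 2 degrees of freedom, the common practice at these sample
#' sizes; an exact permutation mode (full enumeration) is available for
#' n <= 8.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param method `"t"` (default) or `"exact"`.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 8) stop("exact permutation mode supported for n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = p)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}
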