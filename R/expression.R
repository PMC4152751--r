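#' Reads-per-million normalization with the zero-count pseudocount
#'
#' `RPM = count / total_clean * 1e6`; entries with a zero count are set
#' to 0.01 so that downstream ratios are defined.
#'
#' @param counts non-negative count vector or matrix (columns =
#'   libraries).
#' @param total_clean clean-read totals: a scalar, or one value per
#'   column of `counts`.
#' @param floor value substituted for zero counts (default 0.01).
#' @return normalized values, same shape as `counts`.
#' @export
normalize_rpm <- function(counts, total_clean, floor = 0.01) {
  if (any(total_clean <= 0)) stop("total_clean must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.matrix(counts)) {
    if (length(total_clean) == 1L)
      total_clean <- rep(total_clean, ncol(counts))
    if (length(total_clean) != ncol(counts))
      stop("one total_clean value per column required")
    rpm <- sweep(counts, 2, total_clean, "/") * 1e6
  } else {
    rpm <- counts / total_clean * 1e6
  }
  rpm[counts == 0] <- floor
  rpm
}

#' Drop miRNAs with low normalized expression in both groups
#'
#' A row is removed iff its group-level normalized expression is strictly
#' below `threshold` in *every* group.  The group statistic is the mean
#' over the group's libraries (`how = "mean"`), or the rule can require
#' every library of every group to be below threshold (`how = "all"`).
#'
#' @param mat miRNA x library matrix of normalized expression.
#' @param groups named list of library-name vectors.
#' @param threshold expression threshold (default 1).
#' @param how group statistic, `"mean"` (default) or `"all"`.
#' @return the filtered matrix.
#' @export
filter_low_expression <- function(mat, groups, threshold = 1,
                                  how = c("mean", "all")) {
  how <- match.arg(how)
  mat <- as.matrix(mat)
  low <- vapply(groups, function(libs) {
    sub <- mat[, libs, drop = FALSE]
    if (how == "mean") rowMeans(sub) < threshold
    else apply(sub < threshold, 1, all)
  }, logical(nrow(mat)))
  if (nrow(mat) == 1L) low <- matrix(low, nrow = 1L)
  mat[!apply(low, 1, all), , drop = FALSE]
}

#' Group fold changes of normalized expression
#'
#' Ratio of group-mean normalized expression (numerator over denominator
#' group) with its log2; `down_2fold` flags ratios below 0.5.
#'
#' @param mat miRNA x library matrix of normalized expression (after the
#'   0.01 pseudocount, so ratios are always defined).
#' @param groups named list of library-name vectors.
#' @param numerator,denominator group names (defaults: first and second
#'   group).
#' @return a data.frame: `mirna`, group means, `ratio`, `log2fc`,
#'   `down_2fold`.
#' @export
fold_change <- function(mat, groups, numerator = names(groups)[1],
                        denominator = names(groups)[2]) {
  mat <- as.matrix(mat)
  mnum <- rowMeans(mat[, groups[[numerator]], drop = FALSE])
  mden <- rowMeans(mat[, groups[[denominator]], drop = FALSE])
  ratio <- mnum / mden
  out <- data.frame(mirna = rownames(mat), stringsAsFactors = FALSE)
  out[[paste0("mean_", numerator)]] <- mnum
  out[[paste0("mean_", denominator)]] <- mden
  out$ratio <- ratio
  out$log2fc <- log2(ratio)
  out$down_2fold <- ratio < 0.5
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test.  For combined sample sizes up to `exact_max`
#' the p-value is computed by exact enumeration of all group assignments
#' (correct under ties); otherwise by the normal approximation with tie
#' correction.  U is the number of (x, y) pairs with x > y, counting ties
#' as 1/2.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max maximum combined n for exact enumeration (default
#'   12).
#' @return a list with `statistic` (U), `p.value` and `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  ustat <- function(xv, yv) {
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  u <- ustat(x, y)
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    pool <- c(x, y)
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(s) ustat(pool[s], pool[-s]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    pool <- c(x, y)
    n <- n1 + n2
    ties <- table(pool)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = u, p.value = p, method = method)
}
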