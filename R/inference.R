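# Small-sample inference: exact Mann-Whitney rank-sum by full enumeration,
# plain Pearson chi-square, and confusion-matrix metrics.
#
# The exact route matters here: with four districts per arm, lookup tables
# and normal approximations (with or without continuity correction) do not
# give the permutation p-value, while full enumeration of the C(8,4) = 70
# group assignments does.

#' Exact two-sample Mann-Whitney U test
#'
#' Computes U with mid-ranks for ties and, for small samples
#' (`n1 + n2 <= max_exact_n`), the exact two-sided p-value by full
#' enumeration of all `choose(n1+n2, n1)` assignments of the observed
#' (mid-)ranks to the first group. The reported statistic is the smaller of
#' the two one-sided U values, and
#' `p = min(1, 2 * min(P(U_a <= u_obs), P(U_a >= u_obs)))`.
#' Above `max_exact_n` a normal approximation with tie correction (no
#' continuity correction) is used and flagged in `method`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param max_exact_n Largest combined sample size for which the exact
#'   enumeration is used (default 20).
#' @return A list: `u_statistic` (min of the two U's), `u_a`, `p_two_sided`,
#'   `n1`, `n2`, `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney_exact(c(2.82, 2.99, 4.85, 5.32), c(5.41, 6.72, 7.74, 12.24))
mann_whitney_exact <- function(group_a, group_b, max_exact_n = 20) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  r <- rank(c(group_a, group_b)) # mid-ranks for ties
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_b <- n1 * n2 - u_a
  u <- min(u_a, u_b)

  if (n1 + n2 <= max_exact_n) {
    # enumerate every assignment of the observed rank multiset to group a
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= u_a + eps)
    p_hi <- mean(u_all >= u_a - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (u_a - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(u_statistic = u, u_a = u_a, p_two_sided = p, n1 = n1, n2 = n2,
       method = method)
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic \eqn{\sum (O - E)^2 / E} on a contingency table
#' of non-negative integer counts, with expected counts from the product of
#' margins over the grand total and no continuity correction.
#'
#' @param table Matrix of non-negative counts, at least 2 x 2, with all row
#'   and column margins positive.
#' @return A list: `statistic`, `df`, `p_value`, `expected` (matrix).
#' @export
#' @examples
#' m <- rbind(Anopheles = c(3, 31), Aedes = c(6, 31), Culex = c(344, 367))
#' chi_square_test(m)$statistic # 33.63
chi_square_test <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  if (any(m < 0) || any(is.na(m))) {
    stop("table must contain non-negative counts", call. = FALSE)
  }
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(m)
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision and recall from the four cells of a binary confusion
#' matrix. Precision (recall) is `NA` when no positive calls (no actual
#' positives) exist, rather than an arbitrary 0 or 1.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts; not all zero.
#' @return A list: `accuracy`, `precision`, `recall`, plus the counts.
#' @export
#' @examples
#' confusion_metrics(7, 0, 1, 0) # recall 0.875
confusion_metrics <- function(tp, fp, fn, tn) {
  cells <- c(tp, fp, fn, tn)
  if (any(cells < 0) || any(is.na(cells))) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  total <- sum(cells)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  list(
    accuracy = (tp + tn) / total,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}
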