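# Method-ranking statistics. Activity classes act as judges and screening
# methods as the ranked objects: Kendall's coefficient of concordance W
# (with the standard mid-rank tie correction), its chi-square significance
# approximation, and the pairwise improvement percentage between mean recalls.

#' Rank scores within one judge
#'
#' Assigns rank n to the largest score and 1 to the smallest (so the best
#' method carries the highest rank), with mid-ranks for ties.
#'
#' @param scores numeric vector of finite scores.
#' @return numeric vector of ranks.
#' @export
rank_within_judge <- function(scores) {
  if (!length(scores)) stop("empty score row")
  if (any(!is.finite(scores))) stop("non-finite score")
  rank(scores, ties.method = "average")
}

#' Kendall's coefficient of concordance
#'
#' For an m-judges x n-objects score matrix, ranks each judge's row
#' ([rank_within_judge()]), forms the rank totals Ri, their mean m(n+1)/2 and
#' the squared-deviation sum, and computes
#' `W = 12 * delta / (m^2 (n^3 - n) - m * sum(T))` where `T = sum(t^3 - t)`
#' over each judge's tie groups -- the tie-corrected form, which reduces to
#' the classical `12 delta / m^2 (n^3 - n)` on tie-free matrices.
#' Significance uses the chi-square approximation `chi2 = m (n - 1) W` with
#' n - 1 degrees of freedom.
#'
#' @param M numeric matrix or data.frame, judges (rows) x objects (columns),
#'   m >= 2 and n >= 2.
#' @param tie_correction apply the tie-corrected denominator (default TRUE).
#' @return object of class `concordance_result`: `W`, `mean_ranks`,
#'   `total_ranks`, `chi_square`, `df`, `p_value`, and 0.05/0.01 significance
#'   flags.
#' @export
kendall_w <- function(M, tie_correction = TRUE) {
  M <- as.matrix(M)
  m <- nrow(M); n <- ncol(M)
  if (m < 2L || n < 2L) stop("need at least 2 judges and 2 objects")
  R <- t(apply(M, 1, rank_within_judge))
  Ri <- colSums(R)
  Rbar <- m * (n + 1) / 2
  delta <- sum((Ri - Rbar)^2)
  Tsum <- sum(apply(R, 1, function(r) { t <- table(r); sum(t^3 - t) }))
  den <- m^2 * (n^3 - n) - if (tie_correction) m * Tsum else 0
  W <- 12 * delta / den
  chi <- m * (n - 1) * W
  p <- stats::pchisq(chi, df = n - 1, lower.tail = FALSE)
  structure(list(W = W, mean_ranks = Ri / m, total_ranks = Ri,
                 chi_square = chi, df = n - 1L, p_value = p,
                 significant_05 = p < 0.05, significant_01 = p < 0.01,
                 m = m, n = n),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Kendall W = %.7f  (chi-square = %.3f, df = %d, p = %.3g)\n",
              x$W, x$chi_square, x$df, x$p_value))
  ord <- order(-x$mean_ranks)
  for (i in ord)
    cat(sprintf("  %-16s %6.2f\n", names(x$mean_ranks)[i], x$mean_ranks[i]))
  invisible(x)
}

#' Improvement percentage between two recall values
#'
#' `100 * (recall_1 - recall_2) / recall_1`: the relative gain of method 1
#' over method 2 expressed against method 1's recall.
#'
#' @param recall_1 recall of the (proposed) method; must be positive.
#' @param recall_2 recall of the comparison method.
#' @return improvement percentage.
#' @export
improvement_percentage <- function(recall_1, recall_2) {
  if (recall_1 <= 0) stop("recall_1 must be positive")
  100 * (recall_1 - recall_2) / recall_1
}

#' Ordered method ranking report
#'
#' Methods sorted by descending mean rank across judges; tied mean ranks keep
#' their input order.
#'
#' @param M judges x objects score matrix (recall table).
#' @param method_names optional method names (defaults to column names).
#' @return data.frame (`method`, `mean_rank`) in ranking order.
#' @export
rank_report <- function(M, method_names = colnames(M)) {
  M <- as.matrix(M)
  if (length(method_names) != ncol(M))
    stop("method_names length does not match the number of columns")
  res <- kendall_w(M)
  mr <- unname(res$mean_ranks)
  ord <- order(-mr)                       # stable: ties keep input order
  data.frame(method = method_names[ord], mean_rank = mr[ord],
             stringsAsFactors = FALSE)
}

#' Full concordance report for a recall table
#'
#' Mirrors the benchmark ranking-table layout: W, chi-square, p-value,
#' significance flags, and the methods ordered by mean rank.
#'
#' @param table recall table (classes x methods).
#' @param tie_correction see [kendall_w()].
#' @return list with `W`, `chi_square`, `p_value`, `significant_05`,
#'   `significant_01`, and `ranking` (data.frame).
#' @export
concordance_report <- function(table, tie_correction = TRUE) {
  if (ncol(as.matrix(table)) < 2L) stop("need >=2 methods")
  res <- kendall_w(table, tie_correction)
  list(W = res$W, chi_square = res$chi_square, p_value = res$p_value,
       significant_05 = res$significant_05, significant_01 = res$significant_01,
       ranking = rank_report(table))
}
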