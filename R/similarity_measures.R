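# The explicit similarity-measure layers of the enhanced Siamese architecture,
# plus the continuous-Tanimoto screening baseline. All are pure, symmetric
# functions of two equal-length vectors.

.check_lengths <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch: ", length(a), " vs ", length(b))
}

#' Absolute-difference measure
#'
#' Elementwise `|fA - fB|`: the vector-valued first similarity measure of the
#' Siamese head. Zero exactly when the two feature vectors coincide.
#'
#' @param fa,fb numeric vectors of equal length.
#' @return numeric vector, same length.
#' @export
abs_difference <- function(fa, fb) {
  .check_lengths(fa, fb)
  abs(fa - fb)
}

#' Exponential Manhattan similarity
#'
#' `exp(-sum(|fA - fB|))`: a scalar in (0, 1] that equals 1 iff the two
#' vectors are identical and decays with their Manhattan distance.
#'
#' @param fa,fb numeric vectors of equal length.
#' @return scalar in (0, 1].
#' @export
exp_manhattan <- function(fa, fb) {
  .check_lengths(fa, fb)
  exp(-sum(abs(fa - fb)))
}

#' Continuous Jaccard similarity
#'
#' `sum(fA*fB) / (sum(fA^2) + sum(fB^2) - sum(fA*fB))` on real vectors.
#' Equals 1 iff the vectors are identical and nonzero; 0 for disjoint
#' supports; lies in \[0, 1\] for nonnegative inputs. Undefined (error) when
#' both vectors are zero.
#'
#' @param fa,fb numeric vectors of equal length, not both zero.
#' @return scalar similarity.
#' @export
jaccard_continuous <- function(fa, fb) {
  .check_lengths(fa, fb)
  p <- sum(fa * fb)
  den <- sum(fa^2) + sum(fb^2) - p
  if (den == 0) stop("Jaccard undefined: both vectors are zero")
  p / den
}

#' Russel similarity
#'
#' `sum(fA*fB) / n` where `n` is the vector length: a binary-heritage
#' association coefficient applied here to real-valued features (the raw
#' product sum, no binarization).
#'
#' @param fa,fb numeric vectors of equal length n >= 1.
#' @return scalar similarity.
#' @export
russel <- function(fa, fb) {
  .check_lengths(fa, fb)
  n <- length(fa)
  if (n == 0L) stop("Russel undefined for empty vectors")
  sum(fa * fb) / n
}

#' Continuous Tanimoto score (TAN baseline)
#'
#' The continuous Tanimoto coefficient applied to raw count fingerprints:
#' identical formula to [jaccard_continuous()]. This is the conventional
#' ligand-based virtual-screening baseline scorer. Note that on count vectors
#' it is not scale-invariant: `tanimoto_score(x, 2*x) < 1`.
#'
#' @param a,b count fingerprints (numeric vectors) of equal length, not both
#'   zero.
#' @return scalar similarity.
#' @export
tanimoto_score <- function(a, b) jaccard_continuous(a, b)

# ---- batched (row-wise) versions used inside the network forward passes ----
# A, B are batch x F matrices; a small epsilon guards the all-zero ReLU-output
# edge case inside a model, where an error would abort training.

.batch_absdiff <- function(A, B) abs(A - B)

.batch_exp_manhattan <- function(D) exp(-rowSums(D))  # D = |A - B|

.batch_jaccard <- function(A, B, eps = 1e-12) {
  p <- rowSums(A * B)
  den <- rowSums(A^2) + rowSums(B^2) - p + eps
  list(s = p / den, p = p, den = den)
}

.batch_russel <- function(A, B) rowSums(A * B) / ncol(A)
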