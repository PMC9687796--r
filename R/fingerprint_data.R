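#' @keywords internal
"_PACKAGE"

# Reserved label for background (non-active) molecules.
#' Reserved class label for inactive molecules
#'
#' Inactive molecules participate in screening libraries as background but are
#' never used as queries and never count as sharing an activity class (two
#' inactives form a negative training pair).
#' @export
INACTIVE_LABEL <- "INACTIVE"

#' Construct a screening library
#'
#' A screening library couples a matrix of count fingerprints (one molecule per
#' row, one hashed substructure position per column) with per-molecule activity
#' class labels and a registry of activity classes. Count fingerprints are
#' ECFC-style: fixed-length vectors of nonnegative integers.
#'
#' @param fingerprints integer matrix, N molecules x L positions, with unique
#'   rownames giving molecule ids. All entries must be nonnegative and every
#'   row must contain at least one nonzero count.
#' @param labels character vector of length N; activity class per molecule.
#'   Inactives carry the reserved label [INACTIVE_LABEL].
#' @param classes optional data.frame with columns `label`, `n_active`,
#'   `mean_pairwise_similarity`; built from `labels` when omitted
#'   (similarities left `NA` until computed).
#' @return An object of class `screening_library` with elements
#'   `fingerprints`, `labels`, `classes`.
#' @export
screening_library <- function(fingerprints, labels, classes = NULL) {
  if (!is.matrix(fingerprints) || !is.numeric(fingerprints))
    stop("`fingerprints` must be a numeric matrix")
  if (nrow(fingerprints) == 0L) stop("no molecules: library must have N >= 1 rows")
  if (is.null(rownames(fingerprints)))
    stop("`fingerprints` must have rownames (molecule ids)")
  if (anyDuplicated(rownames(fingerprints)))
    stop("molecule ids must be unique")
  if (any(fingerprints < 0)) stop("negative count in fingerprint matrix")
  if (any(fingerprints != round(fingerprints)))
    stop("fingerprint counts must be integers")
  if (length(labels) != nrow(fingerprints))
    stop("`labels` length must equal number of molecules")
  zero_rows <- which(rowSums(fingerprints) == 0)
  if (length(zero_rows))
    stop("molecule(s) with all-zero fingerprint: ",
         paste(rownames(fingerprints)[utils::head(zero_rows, 3)], collapse = ", "))
  labels <- as.character(labels)
  if (is.null(classes)) {
    active <- labels[labels != INACTIVE_LABEL]
    tab <- table(active)
    classes <- data.frame(
      label = names(tab),
      n_active = as.integer(tab),
      mean_pairwise_similarity = NA_real_,
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(is.data.frame(classes),
              all(c("label", "n_active", "mean_pairwise_similarity") %in% names(classes)))
    present <- unique(labels[labels != INACTIVE_LABEL])
    missing <- setdiff(present, classes$label)
    if (length(missing))
      stop("label(s) not in class registry: ", paste(missing, collapse = ", "))
  }
  structure(
    list(fingerprints = fingerprints, labels = labels, classes = classes),
    class = "screening_library"
  )
}

#' @export
print.screening_library <- function(x, ...) {
  n_inact <- sum(x$labels == INACTIVE_LABEL)
  cat(sprintf("screening_library: %d molecules x %d positions, %d classes, %d inactives\n",
              nrow(x$fingerprints), ncol(x$fingerprints), nrow(x$classes), n_inact))
  invisible(x)
}

#' @export
dim.screening_library <- function(x) dim(x$fingerprints)

#' Read a screening library from delimited text
#'
#' Rows are `molecule_id, class_label, v1..vL` with a mandatory header; the
#' separator (comma or tab) is auto-detected from the header line.
#'
#' @param path file path.
#' @param length expected fingerprint length L; when given, a mismatch is an
#'   error.
#' @return A [screening_library()].
#' @export
read_library <- function(path, length = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("no molecules: file is empty")
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("no molecules: file contains a header only")
  if (ncol(df) < 3L) stop("malformed file: need id, class and >=1 count column")
  ids <- df[[1L]]
  labels <- df[[2L]]
  counts <- df[, -(1:2), drop = FALSE]
  L <- ncol(counts)
  if (!is.null(length) && L != length)
    stop(sprintf("fingerprint length %d does not match declared length %d", L, length))
  mat <- matrix(NA_real_, nrow(df), L)
  for (j in seq_len(L)) {
    v <- suppressWarnings(as.numeric(counts[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed row %d: non-numeric count in column %d", bad[1L], j + 2L))
    mat[, j] <- v
  }
  neg <- which(rowSums(mat < 0) > 0)
  if (length(neg)) stop(sprintf("malformed row %d: negative count", neg[1L]))
  rownames(mat) <- ids
  screening_library(mat, labels)
}

#' Write a screening library to delimited text
#'
#' The file round-trips through [read_library()] with bit-identical integer
#' values; the inactive label is preserved verbatim.
#'
#' @param lib a [screening_library()].
#' @param path output path.
#' @param sep field separator, tab (default) or comma.
#' @export
write_library <- function(lib, path, sep = "\t") {
  stopifnot(inherits(lib, "screening_library"))
  df <- data.frame(
    molecule_id = rownames(lib$fingerprints),
    class_label = lib$labels,
    lib$fingerprints,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(df) <- c("molecule_id", "class_label",
                    paste0("v", seq_len(ncol(lib$fingerprints))))
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write library: ", conditionMessage(e)))
  invisible(path)
}

#' Fold raw hashed feature counts to a fixed-length count fingerprint
#'
#' Emulates the folding step that turns an open-ended hashed feature->count map
#' (as produced by extended-connectivity fingerprinting) into a fixed-length
#' count vector: position `j` accumulates all hashes `h` with `h mod L == j`
#' (zero-based), so the total count is conserved.
#'
#' @param hashes integer vector of nonnegative feature hashes.
#' @param counts numeric vector of nonnegative counts, same length as `hashes`.
#' @param length fold length L (default 1024).
#' @return numeric vector of length L.
#' @export
fold_counts <- function(hashes, counts, length = 1024L) {
  if (length < 1L) stop("length must be >= 1")
  if (base::length(hashes) != base::length(counts))
    stop("`hashes` and `counts` must have equal length")
  if (any(counts < 0)) stop("negative count")
  out <- numeric(length)
  if (base::length(hashes)) {
    pos <- (as.numeric(hashes) %% length) + 1L
    for (i in seq_along(pos)) out[pos[i]] <- out[pos[i]] + counts[i]
  }
  out
}

# Pairwise continuous-Tanimoto matrix over the rows of F (internal; O(n^2 L)).
.pairwise_tanimoto <- function(F) {
  P <- tcrossprod(F)            # dot products
  q <- diag(P)                  # squared norms
  den <- outer(q, q, "+") - P
  S <- P / den
  S[den == 0] <- NA_real_       # both-zero rows never occur in a valid library
  S
}

#' Mean pairwise continuous-Tanimoto similarity of an activity class
#'
#' The mean, over all unordered pairs of class members, of the continuous
#' Tanimoto coefficient applied to the raw count fingerprints. This is the
#' statistic used to characterize the structural homogeneity of an activity
#' class (roughly 0.10-0.15 for heterogeneous classes, 0.23-0.39 for
#' homogeneous ones in the MDDR/MUV benchmarks).
#'
#' @param lib a [screening_library()].
#' @param class_label class to measure; must have at least two members.
#' @return scalar in \[0, 1\].
#' @export
class_mean_pairwise_similarity <- function(lib, class_label) {
  stopifnot(inherits(lib, "screening_library"))
  idx <- which(lib$labels == class_label)
  if (!length(idx)) stop("unknown class: ", class_label)
  if (length(idx) < 2L) stop("singleton class: ", class_label)
  S <- .pairwise_tanimoto(lib$fingerprints[idx, , drop = FALSE])
  mean(S[upper.tri(S)])
}
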