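# Virtual-screening protocol: rank a library against a query, measure
# recall within the top n% of the ranking, and evaluate scorers by
# stratified k-fold cross-validation with randomly drawn per-class reference
# queries, as in the standard MDDR/MUV benchmark design.

#' Rank a screening library against a query fingerprint
#'
#' Every non-query molecule is scored against the query and sorted by
#' descending score; ties are broken by ascending molecule id (stable,
#' documented). The query itself is excluded from its own ranking.
#'
#' @param scorer a scorer object ([tan_scorer()], Siamese or hybrid).
#' @param query a molecule id present in `lib`, or a raw fingerprint vector.
#' @param lib a [screening_library()].
#' @param query_class activity class of the query; inferred when `query` is an
#'   id.
#' @return data.frame (`id`, `score`) of class `ranked_list`, with attributes
#'   `query_id` and `query_class`.
#' @export
rank_database <- function(scorer, query, lib, query_class = NULL) {
  stopifnot(inherits(lib, "screening_library"))
  F <- lib$fingerprints
  if (nrow(F) == 0L) stop("empty library")
  query_id <- NA_character_
  if (is.character(query) && length(query) == 1L) {
    qi <- match(query, rownames(F))
    if (is.na(qi)) stop("query id not in library: ", query)
    query_id <- query
    if (is.null(query_class)) query_class <- lib$labels[qi]
    qv <- F[qi, ]
    keep <- setdiff(seq_len(nrow(F)), qi)
  } else {
    qv <- as.numeric(query)
    if (length(qv) != ncol(F)) stop("query length does not match library")
    keep <- seq_len(nrow(F))
  }
  if (!length(keep)) stop("empty library after excluding the query")
  Fk <- F[keep, , drop = FALSE]
  Q <- matrix(qv, nrow(Fk), length(qv), byrow = TRUE)
  sc <- score_batch(scorer, Q, Fk)
  ids <- rownames(Fk)
  ord <- order(-sc, ids)
  out <- data.frame(id = ids[ord], score = sc[ord], stringsAsFactors = FALSE)
  structure(out, class = c("ranked_list", "data.frame"),
            query_id = query_id, query_class = query_class)
}

#' Recall within the top n% of a ranking
#'
#' The percentage of the query class's active molecules (among those present
#' in the ranked set) retrieved within the top `ceiling(pct/100 * N)`
#' positions.
#'
#' @param ranked a `ranked_list` from [rank_database()].
#' @param lib the [screening_library()] that was ranked (for class lookup).
#' @param pct cutoff percentage in (0, 100\].
#' @return recall percentage in \[0, 100\].
#' @export
recall_at <- function(ranked, lib, pct) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (pct <= 0 || pct > 100) stop("pct must be in (0, 100]")
  qc <- attr(ranked, "query_class")
  if (is.null(qc)) stop("ranked list lacks a query class")
  lab <- lib$labels[match(ranked$id, rownames(lib$fingerprints))]
  is_active <- lab == qc & lab != INACTIVE_LABEL
  total <- sum(is_active)
  if (total == 0L) stop("no same-class active present in the ranked list")
  top_n <- ceiling(pct / 100 * nrow(ranked))
  100 * sum(is_active[seq_len(top_n)]) / total
}

#' Cross-validation protocol
#'
#' @param k_folds number of stratified folds (>= 2).
#' @param queries_per_class reference queries sampled per class per fold.
#' @param cutoffs recall cutoffs in percent.
#' @param seed integer seed for fold assignment and query sampling.
#' @return list of class `cv_protocol`.
#' @export
cv_protocol <- function(k_folds = 5L, queries_per_class = 10L,
                        cutoffs = c(1, 5), seed = 1L) {
  stopifnot(k_folds >= 2L, queries_per_class >= 1L, all(cutoffs > 0))
  structure(list(k_folds = as.integer(k_folds),
                 queries_per_class = as.integer(queries_per_class),
                 cutoffs = cutoffs, seed = as.integer(seed)),
            class = "cv_protocol")
}

# Stratified fold assignment: shuffle within each label group (inactives
# included) and deal round-robin.
.assign_folds <- function(labels, k, seed) {
  .with_seed(seed, {
    fold <- integer(length(labels))
    for (grp in split(seq_along(labels), labels)) {
      fold[sample(grp)] <- rep_len(seq_len(k), length(grp))
    }
    fold
  })
}

# Build/train one scorer by kind token on a training library.
.make_scorer <- function(kind, train_lib, spec, n_pairs, pos_fraction, seed) {
  L <- ncol(train_lib$fingerprints)
  needs_pairs <- kind != "tan"
  pairs <- if (needs_pairs)
    generate_pairs(train_lib, n_pairs, pos_fraction, seed = .sub_seed(seed, 11))
  sspec <- spec
  sspec$seed <- as.integer(.sub_seed(seed, 13))
  tr <- function(m) train_scorer(m, pairs, sspec)
  switch(kind,
    "tan" = tan_scorer(),
    "smlp2" = tr(build_siamese(smlp_config(L, 2L), seed = .sub_seed(seed, 21))),
    "smlp3" = tr(build_siamese(smlp_config(L, 3L), seed = .sub_seed(seed, 22))),
    "scnn1d2" = tr(build_siamese(scnn1d_config(L, 2L), seed = .sub_seed(seed, 23))),
    "scnn1d3" = tr(build_siamese(scnn1d_config(L, 3L), seed = .sub_seed(seed, 24))),
    "hybrid-d-max2" = decision_hybrid(
      tr(build_siamese(smlp_config(L, 2L), seed = .sub_seed(seed, 21))),
      tr(build_siamese(scnn1d_config(L, 2L), seed = .sub_seed(seed, 23)))),
    "hybrid-d-max3" = decision_hybrid(
      tr(build_siamese(smlp_config(L, 3L), seed = .sub_seed(seed, 22))),
      tr(build_siamese(scnn1d_config(L, 3L), seed = .sub_seed(seed, 24)))),
    "hybrid-f-sum" = tr(build_feature_hybrid(
      feature_hybrid_config(L, "sum"), seed = .sub_seed(seed, 25))),
    "hybrid-f-max" = tr(build_feature_hybrid(
      feature_hybrid_config(L, "max"), seed = .sub_seed(seed, 26))),
    stop("unknown model kind: ", kind)
  )
}

#' Model kinds understood by the evaluation pipeline
#' @export
MODEL_KINDS <- c("tan", "smlp2", "smlp3", "scnn1d2", "scnn1d3",
                 "hybrid-d-max2", "hybrid-d-max3", "hybrid-f-sum", "hybrid-f-max")

#' Cross-validated screening evaluation
#'
#' Splits the library into `k` stratified folds. Per fold and method: train
#' the scorer on pairs drawn from the k-1 training folds (the TAN baseline
#' needs no training), then for each activity class sample
#' `queries_per_class` reference actives from the test fold, rank each query
#' against the remaining test-fold molecules, and average the recall over the
#' queries. Cells are means over folds. Fully seeded and reproducible.
#'
#' @param lib a [screening_library()].
#' @param methods character vector of model kinds (see `MODEL_KINDS`).
#' @param protocol a [cv_protocol()].
#' @param spec a [train_spec()] used for all trainable methods.
#' @param n_pairs training pairs drawn per fold.
#' @param pos_fraction positive fraction of training pairs.
#' @return named list of recall tables (one per cutoff): data.frames with
#'   activity classes as rows and methods as columns, values in \[0, 100\].
#' @export
run_cv <- function(lib, methods = "tan", protocol = cv_protocol(),
                   spec = train_spec(), n_pairs = 2000L, pos_fraction = 0.5) {
  stopifnot(inherits(lib, "screening_library"), inherits(protocol, "cv_protocol"))
  methods <- match.arg(methods, MODEL_KINDS, several.ok = TRUE)
  k <- protocol$k_folds
  cls <- lib$classes$label
  small <- lib$classes$label[lib$classes$n_active < k]
  if (length(small))
    stop("class too small for ", k, "-fold stratification: ",
         paste(small, collapse = ", "))
  per_fold <- floor(min(lib$classes$n_active) / k)
  if (per_fold < 1L)
    stop("classes too small for the requested fold count")
  fold <- .assign_folds(lib$labels, k, .sub_seed(protocol$seed, 1))
  tables <- lapply(protocol$cutoffs, function(ct)
    matrix(0, length(cls), length(methods),
           dimnames = list(cls, methods)))
  names(tables) <- as.character(protocol$cutoffs)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    test_lib <- screening_library(lib$fingerprints[test_idx, , drop = FALSE],
                                  lib$labels[test_idx])
    train_lib <- screening_library(lib$fingerprints[train_idx, , drop = FALSE],
                                   lib$labels[train_idx])
    for (mi in seq_along(methods)) {
      scorer <- .make_scorer(methods[mi], train_lib, spec, n_pairs, pos_fraction,
                             seed = .sub_seed(protocol$seed, 100 * f + mi))
      for (ci in seq_along(cls)) {
        members <- rownames(test_lib$fingerprints)[test_lib$labels == cls[ci]]
        nq <- min(protocol$queries_per_class, length(members))
        if (nq < 1L)
          stop("class ", cls[ci], " has no members in test fold ", f)
        queries <- .with_seed(.sub_seed(protocol$seed, 10000 * f + ci), {
          sample(members, nq)
        })
        for (cti in seq_along(protocol$cutoffs)) {
          rec <- vapply(queries, function(q) {
            rk <- rank_database(scorer, q, test_lib)
            recall_at(rk, test_lib, protocol$cutoffs[cti])
          }, numeric(1))
          tables[[cti]][ci, mi] <- tables[[cti]][ci, mi] + mean(rec) / k
        }
      }
    }
  }
  lapply(tables, as.data.frame)
}

#' Summarize a recall table
#'
#' Computes the per-method mean recall over activity classes (the "Mean" row)
#' and the shaded-cell count: for each method, the number of classes where it
#' attains the row maximum (ties counted for every attaining method).
#'
#' @param table data.frame of recall percentages, classes x methods.
#' @return list with `mean` (named numeric) and `shaded` (named integer).
#' @export
recall_summary <- function(table) {
  M <- as.matrix(table)
  if (nrow(M) == 0L || ncol(M) == 0L) stop("empty recall table")
  rmax <- apply(M, 1, max)
  shaded <- colSums(M == matrix(rmax, nrow(M), ncol(M)))
  list(mean = colMeans(M), shaded = as.integer(shaded) |>
         stats::setNames(colnames(M)))
}

#' Read a recall table from delimited text
#'
#' First column holds activity-class labels; remaining columns are methods.
#' Round-trips bit-exactly through [write_recall_table()].
#'
#' @param path TSV/CSV file path.
#' @return data.frame with class labels as rownames.
#' @export
read_recall_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("malformed table: need a class column and >=1 method")
  out <- data.frame(row.names = df[[1L]])
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v))
      stop("malformed table: non-numeric cell in column ", colnames(df)[j],
           ", row ", which(is.na(v))[1L])
    out[[colnames(df)[j]]] <- v
  }
  out
}

#' Write a recall table to delimited text
#'
#' @param table data.frame with class labels as rownames.
#' @param path output path.
#' @export
write_recall_table <- function(table, path) {
  df <- data.frame(class = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged benchmark recall tables
#'
#' Returns one of the published MDDR/MUV benchmark recall tables shipped with
#' the package (per-class recall percentages of ten screening methods at the
#' top-1% and top-5% cutoffs), used to golden-test the summary and
#' concordance statistics.
#'
#' @param dataset one of `"ds1"`, `"ds2"`, `"ds3"`, `"muv"`.
#' @param cutoff 1 or 5.
#' @return data.frame, classes x methods.
#' @export
benchmark_recall_table <- function(dataset = c("ds1", "ds2", "ds3", "muv"),
                                   cutoff = 1) {
  dataset <- match.arg(dataset)
  stopifnot(cutoff %in% c(1, 5))
  path <- system.file("extdata",
                      sprintf("recall_%s_top%d.tsv", dataset, cutoff),
                      package = "siamscreen", mustWork = TRUE)
  read_recall_table(path)
}
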