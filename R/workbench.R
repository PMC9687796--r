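# End-to-end workbench: simulate a library, run the screening evaluation, and
# compute ranking statistics, each from a plain JSON config so experiments are
# reproducible from the shell (see inst/cli/vsworkbench.R for the thin CLI).

.config_hash <- function(path) unname(tools::md5sum(path))

#' Read an experiment configuration (JSON)
#'
#' @param path JSON file with fields `classes` (list of label/n_active/
#'   target_similarity), `n_inactive`, `length`, `count_scale`, `density`,
#'   `seed`, and optionally `methods`, `train`, `cv`.
#' @return named list with a parsed [generator_config()] under `$generator`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("classes", "n_inactive", "length", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("invalid config: missing field ", miss[1L])
  cl <- cfg$classes
  # accept either an array of objects (parsed as data.frame) or an object of
  # parallel arrays (parsed as a named list)
  if (!is.data.frame(cl)) cl <- as.data.frame(cl, stringsAsFactors = FALSE)
  if (!all(c("label", "n_active", "target_similarity") %in% names(cl)))
    stop("invalid config: missing field classes$label/n_active/target_similarity")
  specs <- lapply(seq_len(nrow(cl)), function(i)
    class_spec(cl$label[i], cl$n_active[i], cl$target_similarity[i]))
  gen <- generator_config(specs, n_inactive = cfg$n_inactive,
                          length = cfg$length,
                          count_scale = cfg$count_scale %||% 3,
                          density = cfg$density %||% 0.05,
                          seed = cfg$seed)
  cfg$generator <- gen
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a screening library from a config file
#'
#' Writes `library.tsv` plus a `manifest.json` recording the seed and the
#' md5 hash of the config; reruns with the same config are bit-identical.
#'
#' @param config_path JSON experiment config (see [read_experiment_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
vs_simulate <- function(config_path, out_dir) {
  cfg <- read_experiment_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- generate_library(cfg$generator)
  lib_path <- file.path(out_dir, "library.tsv")
  write_library(lib, lib_path)
  manifest <- list(seed = cfg$seed, config_hash = .config_hash(config_path),
                   n_molecules = nrow(lib$fingerprints),
                   length = ncol(lib$fingerprints),
                   classes = lib$classes)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(library = lib_path, manifest = man_path))
}

#' Run the screening evaluation pipeline
#'
#' Trains the requested scorers (where training applies), evaluates them by
#' cross-validation at the configured cutoffs, and writes one recall table
#' per cutoff plus a summary (mean row and shaded-cell counts). When two or
#' more methods are present a Kendall-W concordance report is written as
#' well.
#'
#' @param lib_path path to a library written by [write_library()].
#' @param out_dir output directory.
#' @param methods model kinds (see `MODEL_KINDS`).
#' @param protocol a [cv_protocol()].
#' @param spec a [train_spec()].
#' @param n_pairs training pairs per fold.
#' @return invisibly, the recall tables (list, one per cutoff).
#' @export
vs_run <- function(lib_path, out_dir, methods = "tan",
                   protocol = cv_protocol(), spec = train_spec(),
                   n_pairs = 2000L) {
  if (!file.exists(lib_path)) stop("missing library: ", lib_path)
  lib <- read_library(lib_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- run_cv(lib, methods, protocol, spec, n_pairs)
  for (ct in names(tables)) {
    tab <- tables[[ct]]
    write_recall_table(tab, file.path(out_dir, sprintf("recall_top%s.tsv", ct)))
    sm <- recall_summary(tab)
    summ <- data.frame(method = colnames(tab), mean = unname(sm$mean),
                       shaded = unname(sm$shaded))
    utils::write.table(summ, file.path(out_dir, sprintf("summary_top%s.tsv", ct)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (ncol(tab) >= 2L) {
      rep <- concordance_report(tab)
      jsonlite::write_json(
        list(W = rep$W, chi_square = rep$chi_square, p_value = rep$p_value,
             ranking = rep$ranking),
        file.path(out_dir, sprintf("concordance_top%s.json", ct)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  invisible(tables)
}

#' Concordance statistics for a recall table file
#'
#' @param table_path recall table written by [write_recall_table()] (or any
#'   delimited class x method table).
#' @return a [concordance_report()] list.
#' @export
vs_stats <- function(table_path) {
  tab <- read_recall_table(table_path)
  if (ncol(tab) < 2L) stop("need >=2 methods in the recall table")
  concordance_report(tab)
}
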