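# Synthetic screening-library generator. Real MDDR/MUV collections are
# license-restricted or external; their published statistical shape -- activity
# classes characterized by size and mean pairwise continuous-Tanimoto
# similarity (~0.10-0.39), over a large inactive background -- is emulated by a
# template-copy model whose copy fraction is calibrated against the measured
# similarity.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream index.
.sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

#' Specification of one synthetic activity class
#'
#' @param label class label (character).
#' @param n_active number of active molecules, >= 2.
#' @param target_similarity desired mean pairwise continuous-Tanimoto
#'   similarity within the class, in (0, 1\].
#' @return list of class `class_spec`.
#' @export
class_spec <- function(label, n_active, target_similarity) {
  stopifnot(n_active >= 2)
  if (target_similarity <= 0 || target_similarity > 1)
    stop("target_similarity must be in (0, 1]")
  structure(list(label = as.character(label), n_active = as.integer(n_active),
                 target_similarity = target_similarity),
            class = "class_spec")
}

#' Configuration for the synthetic library generator
#'
#' @param class_specs list of [class_spec()] objects.
#' @param n_inactive number of background molecules.
#' @param length fingerprint length L.
#' @param count_scale mean nonzero count (counts are 1 + Poisson(count_scale-1)).
#' @param density expected fraction of nonzero positions, in (0, 1).
#' @param seed integer seed controlling every random draw.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(class_specs, n_inactive = 100L, length = 1024L,
                             count_scale = 3, density = 0.05, seed = 1L) {
  if (inherits(class_specs, "class_spec")) class_specs <- list(class_specs)
  stopifnot(all(vapply(class_specs, inherits, logical(1), "class_spec")))
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (count_scale < 1) stop("count_scale must be >= 1")
  labels <- vapply(class_specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate class labels")
  structure(list(class_specs = class_specs, n_inactive = as.integer(n_inactive),
                 length = as.integer(length), count_scale = count_scale,
                 density = density, seed = as.integer(seed)),
            class = "generator_config")
}

# One background draw: Bernoulli(density) support, counts 1 + Poisson(scale-1).
.background_rows <- function(n, L, density, count_scale) {
  on <- matrix(stats::rbinom(n * L, 1L, density), n, L)
  cnt <- matrix(1 + stats::rpois(n * L, count_scale - 1), n, L)
  M <- on * cnt
  # a valid molecule needs >= 1 nonzero position; force one deterministically
  zero <- which(rowSums(M) == 0)
  for (i in zero) M[i, (i %% L) + 1L] <- 1
  M
}

# Members of one class at copy fraction rho: each position is copied from the
# class template with probability rho, otherwise redrawn from the background.
.class_members <- function(n, template, rho, L, density, count_scale) {
  keep <- matrix(stats::rbinom(n * L, 1L, rho), n, L)
  bg <- .background_rows(n, L, density, count_scale)
  M <- keep * matrix(template, n, L, byrow = TRUE) + (1 - keep) * bg
  zero <- which(rowSums(M) == 0)
  for (i in zero) M[i, (i %% L) + 1L] <- 1
  M
}

.mean_pairwise_tan <- function(M) {
  S <- .pairwise_tanimoto(M)
  mean(S[upper.tri(S)])
}

# Calibrate rho by bisection against the measured mean pairwise similarity of
# a pilot sample. Common random numbers (one fixed set of copy-mask uniforms
# and background draws reused across iterations) make the measurement a
# deterministic, monotone nondecreasing function of rho, so the bisection
# converges cleanly from the background level at rho = 0 to 1 at rho = 1.
.calibrate_rho <- function(target, template, L, density, count_scale,
                           seed, pilot_n = 24L, reps = 3L, tol = 0.03,
                           iters = 20L) {
  pilots <- lapply(seq_len(reps), function(r)
    .with_seed(.sub_seed(seed, r), {
      list(U = matrix(stats::runif(pilot_n * L), pilot_n, L),
           bg = .background_rows(pilot_n, L, density, count_scale))
    }))
  measure <- function(rho) {
    mean(vapply(pilots, function(pl) {
      keep <- pl$U < rho
      M <- keep * matrix(template, pilot_n, L, byrow = TRUE) + (!keep) * pl$bg
      zero <- which(rowSums(M) == 0)
      for (i in zero) M[i, (i %% L) + 1L] <- 1
      .mean_pairwise_tan(M)
    }, numeric(1)))
  }
  lo_sim <- measure(0)
  if (target < lo_sim - tol)
    stop(sprintf(paste0("calibration failure: target similarity %.3f is below the ",
                        "background level %.3f; raise target_similarity or lower density"),
                 target, lo_sim))
  lo <- 0; hi <- 1
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (measure(mid) < target) lo <- mid else hi <- mid
  }
  rho <- (lo + hi) / 2
  s <- measure(rho)
  if (abs(s - target) > tol)
    stop(sprintf("calibration failure: reached similarity %.3f for target %.3f", s, target))
  rho
}

#' Generate a synthetic screening library
#'
#' Each activity class is built around a random template fingerprint; members
#' copy a calibrated fraction of template positions and redraw the rest from
#' the background distribution, so the realized mean pairwise
#' continuous-Tanimoto similarity approaches the class's target. Inactives are
#' drawn wholly from the background. Fully deterministic under the config
#' seed.
#'
#' @param cfg a [generator_config()].
#' @return a [screening_library()] whose class registry records the realized
#'   mean pairwise similarity of every class.
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  L <- cfg$length
  blocks <- list(); labels <- character(0)
  reg <- data.frame(label = character(0), n_active = integer(0),
                    mean_pairwise_similarity = numeric(0), stringsAsFactors = FALSE)
  for (ci in seq_along(cfg$class_specs)) {
    sp <- cfg$class_specs[[ci]]
    template <- .with_seed(.sub_seed(cfg$seed, 1000 + ci), {
      t <- .background_rows(1L, L, cfg$density, cfg$count_scale)
      t[1, ]
    })
    rho <- .calibrate_rho(sp$target_similarity, template, L, cfg$density,
                          cfg$count_scale, .sub_seed(cfg$seed, 2000 + ci))
    M <- .with_seed(.sub_seed(cfg$seed, 3000 + ci), {
      .class_members(sp$n_active, template, rho, L, cfg$density, cfg$count_scale)
    })
    rownames(M) <- sprintf("%s_%04d", sp$label, seq_len(sp$n_active))
    blocks[[length(blocks) + 1L]] <- M
    labels <- c(labels, rep(sp$label, sp$n_active))
    reg <- rbind(reg, data.frame(label = sp$label, n_active = sp$n_active,
                                 mean_pairwise_similarity = .mean_pairwise_tan(M),
                                 stringsAsFactors = FALSE))
  }
  if (cfg$n_inactive > 0L) {
    Mi <- .with_seed(.sub_seed(cfg$seed, 9000), {
      .background_rows(cfg$n_inactive, L, cfg$density, cfg$count_scale)
    })
    rownames(Mi) <- sprintf("BG_%05d", seq_len(cfg$n_inactive))
    blocks[[length(blocks) + 1L]] <- Mi
    labels <- c(labels, rep(INACTIVE_LABEL, cfg$n_inactive))
  }
  F <- do.call(rbind, blocks)
  screening_library(F, labels, classes = reg)
}

#' Sample labelled training pairs from a screening library
#'
#' Pairs carry label 1 iff both molecules share an activity class (inactives
#' never match, including with each other), else 0 -- the standard same-class
#' supervision for Siamese similarity training. No self-pairs are emitted.
#'
#' @param lib a [screening_library()].
#' @param n_pairs number of pairs to draw.
#' @param pos_fraction fraction of positive (same-class) pairs, in (0, 1);
#'   the positive count is `round(n_pairs * pos_fraction)` exactly.
#' @param seed integer seed.
#' @return list of class `pair_batch` with elements `a`, `b` (matrices of
#'   fingerprints), `label` (0/1), `idx_a`, `idx_b` (row indices into `lib`).
#' @export
generate_pairs <- function(lib, n_pairs, pos_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(lib, "screening_library"))
  if (pos_fraction <= 0 || pos_fraction >= 1)
    stop("pos_fraction must be in (0, 1)")
  eligible <- lib$classes$label[lib$classes$n_active >= 2]
  if (length(eligible) < 2L)
    stop("need >= 2 activity classes with >= 2 members to sample pairs")
  n_pos <- round(n_pairs * pos_fraction)
  n_neg <- n_pairs - n_pos
  .with_seed(seed, {
    by_class <- split(seq_along(lib$labels), lib$labels)
    ia <- integer(n_pairs); ib <- integer(n_pairs); y <- integer(n_pairs)
    cls <- sample(eligible, n_pos, replace = TRUE)
    for (k in seq_len(n_pos)) {
      two <- sample(by_class[[cls[k]]], 2L)
      ia[k] <- two[1L]; ib[k] <- two[2L]; y[k] <- 1L
    }
    N <- length(lib$labels)
    for (k in seq_len(n_neg)) {
      repeat {
        i <- sample.int(N, 1L); j <- sample.int(N, 1L)
        same <- i == j ||
          (lib$labels[i] == lib$labels[j] && lib$labels[i] != INACTIVE_LABEL)
        if (!same && i != j) break
      }
      ia[n_pos + k] <- i; ib[n_pos + k] <- j; y[n_pos + k] <- 0L
    }
    structure(list(a = lib$fingerprints[ia, , drop = FALSE],
                   b = lib$fingerprints[ib, , drop = FALSE],
                   label = y, idx_a = ia, idx_b = ib),
              class = "pair_batch")
  })
}

#' @export
print.pair_batch <- function(x, ...) {
  cat(sprintf("pair_batch: %d pairs (%d positive), length %d\n",
              length(x$label), sum(x$label), ncol(x$a)))
  invisible(x)
}
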