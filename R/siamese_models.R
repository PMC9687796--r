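# The two enhanced Siamese similarity scorers. Each consists of a pair of
# weight-shared ("twin") branch networks mapping the two fingerprints to
# feature vectors fA, fB, an explicit similarity-measure block
# (absolute difference |fA-fB|, exponential Manhattan exp(-sum|fA-fB|), and
# optionally a third scalar measure: continuous Jaccard for the SMLP, Russel
# for the SCNN1D), a measure-fusion layer that broadcast-adds the scalar
# measures onto the absolute-difference vector, and a scoring head ending in
# a single sigmoid unit, so every score lies in [0, 1]. Weight sharing is
# structural: one parameter set serves both twins, so they can never diverge.

#' SMLP scorer configuration
#'
#' Twin branch: one dense layer of 1024 ReLU units (width fixed by the
#' architecture; it equals the measure-vector length). Post-fusion head:
#' dense ReLU layers of 1024, 512, 256, 128 and 64 units, then one sigmoid
#' output unit.
#'
#' @param input_length fingerprint length L (default 1024).
#' @param n_measures 2 (absolute difference + exponential Manhattan) or 3
#'   (adds the continuous Jaccard measure on the branch features).
#' @param branch_width branch feature width (1024).
#' @param head_widths widths of the post-fusion dense stack.
#' @return list of class `smlp_config`.
#' @export
smlp_config <- function(input_length = 1024L, n_measures = 2L,
                        branch_width = 1024L,
                        head_widths = c(1024L, 512L, 256L, 128L, 64L)) {
  stopifnot(n_measures %in% c(2L, 3L), input_length >= 1L)
  structure(list(input_length = as.integer(input_length),
                 n_measures = as.integer(n_measures),
                 branch_width = as.integer(branch_width),
                 head_widths = as.integer(head_widths)),
            class = "smlp_config")
}

#' SCNN1D scorer configuration
#'
#' Twin branch: two 1-D convolution layers (64 filters, kernel 3, ReLU), each
#' followed by max-pooling of size 2, then flatten and a dense sigmoid layer
#' producing a feature vector of width 512. The fused measure vector feeds the
#' single sigmoid output unit directly.
#'
#' @param input_length fingerprint length L; must be divisible by 4 (two
#'   pool-by-2 stages).
#' @param n_measures 2 or 3 (third measure: Russel on the branch features).
#' @param filters convolution filters per layer.
#' @param kernel kernel size.
#' @param feature_width branch output width (512).
#' @return list of class `scnn1d_config`.
#' @export
scnn1d_config <- function(input_length = 1024L, n_measures = 2L,
                          filters = 64L, kernel = 3L, feature_width = 512L) {
  stopifnot(n_measures %in% c(2L, 3L))
  if (input_length %% 4L != 0L)
    stop("input_length must be divisible by 4 (two pool-by-2 stages)")
  structure(list(input_length = as.integer(input_length),
                 n_measures = as.integer(n_measures),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 feature_width = as.integer(feature_width)),
            class = "scnn1d_config")
}

#' Training specification
#'
#' RMSprop with binary cross-entropy, the loss/optimizer pairing of the
#' architecture. Hyperparameters default to conventional values and are fully
#' configurable.
#'
#' @param learning_rate RMSprop learning rate.
#' @param epochs number of passes over the pair set.
#' @param batch_size mini-batch size.
#' @param seed integer seed controlling shuffling (and nothing else).
#' @param rho RMSprop decay.
#' @param epsilon RMSprop stabilizer.
#' @return list of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 1e-3, epochs = 20L, batch_size = 32L,
                       seed = 1L, rho = 0.9, epsilon = 1e-8) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 rho = rho, epsilon = epsilon),
            class = "train_spec")
}

#' Build an (untrained) enhanced Siamese scorer
#'
#' Both twins reference the single parameter set held in the scorer, so weight
#' sharing holds by construction throughout training.
#'
#' @param cfg an [smlp_config()] or [scnn1d_config()].
#' @param seed seed for the Glorot-uniform initialization.
#' @return an object of class `siamese_scorer` (and `smlp_scorer` or
#'   `scnn1d_scorer`).
#' @export
build_siamese <- function(cfg, seed = 1L) {
  UseMethod("build_siamese")
}

#' @export
build_siamese.smlp_config <- function(cfg, seed = 1L) {
  L <- cfg$input_length; Bw <- cfg$branch_width
  params <- .with_seed(seed, {
    p <- list(W1 = .glorot(L, Bw), b1 = numeric(Bw))
    prev <- Bw
    for (i in seq_along(cfg$head_widths)) {
      w <- cfg$head_widths[i]
      p[[paste0("Wh", i)]] <- .glorot(prev, w)
      p[[paste0("bh", i)]] <- numeric(w)
      prev <- w
    }
    p$Wo <- .glorot(prev, 1L); p$bo <- numeric(1L)
    p
  })
  structure(list(kind = "smlp", config = cfg, params = params,
                 trained = FALSE, loss_trace = numeric(0)),
            class = c("smlp_scorer", "siamese_scorer"))
}

#' @export
build_siamese.scnn1d_config <- function(cfg, seed = 1L) {
  L <- cfg$input_length; Fl <- cfg$filters
  flat <- (L %/% 4L) * Fl
  params <- .with_seed(seed, {
    list(Wc1 = .glorot(cfg$kernel * 1L, Fl), bc1 = numeric(Fl),
         Wc2 = .glorot(cfg$kernel * Fl, Fl), bc2 = numeric(Fl),
         Wd = .glorot(flat, cfg$feature_width), bd = numeric(cfg$feature_width),
         Wo = .glorot(cfg$feature_width, 1L), bo = numeric(1L))
  })
  structure(list(kind = "scnn1d", config = cfg, params = params,
                 trained = FALSE, loss_trace = numeric(0)),
            class = c("scnn1d_scorer", "siamese_scorer"))
}

#' Measure-fusion layer
#'
#' Broadcast-adds the scalar similarity measures onto the vector measure:
#' with scalars s2 (and s3 when present), `output_j = vector_j + s2 (+ s3)`.
#'
#' @param vector_measure numeric vector (absolute-difference measure).
#' @param scalar_measures numeric vector of 1 or 2 scalar measures.
#' @return fused numeric vector, same length as `vector_measure`.
#' @export
measure_fusion <- function(vector_measure, scalar_measures) {
  if (length(scalar_measures) < 1L) stop("need at least one scalar measure")
  vector_measure + sum(scalar_measures)
}

# ---- shared measure block (batched) ---------------------------------------
# fa, fb: (B, F). Returns fused matrix plus cache for backprop.
.measures_fwd <- function(fa, fb, n_measures, third = c("jaccard", "russel")) {
  third <- match.arg(third)
  D <- fa - fb
  sg <- sign(D)
  Dv <- abs(D)
  s2 <- exp(-rowSums(Dv))
  fused <- Dv + s2                       # vector recycles down rows: + s2 per row
  cache <- list(sg = sg, s2 = s2, third = NULL)
  if (n_measures == 3L) {
    if (third == "jaccard") {
      jc <- .batch_jaccard(fa, fb)
      fused <- fused + jc$s
      cache$third <- jc
    } else {
      s3 <- .batch_russel(fa, fb)
      fused <- fused + s3
      cache$third <- list(s = s3)
    }
    cache$third_kind <- third
  }
  cache$fused <- fused
  cache
}

# dfused: (B, F). Returns dfa, dfb.
.measures_bwd <- function(dfused, fa, fb, cache, n_measures) {
  sg <- cache$sg; s2 <- cache$s2
  rs <- rowSums(dfused)                  # gradient wrt each broadcast scalar
  dfa <- dfused * sg - (rs * s2) * sg    # |.| path + exp-Manhattan path
  dfb <- -dfused * sg + (rs * s2) * sg
  if (n_measures == 3L) {
    if (cache$third_kind == "jaccard") {
      p <- cache$third$p; den <- cache$third$den
      # d(p/den)/dfa_i = (fb_i*den - p*(2 fa_i - fb_i)) / den^2 (row vectors recycle)
      dfa <- dfa + rs * ((fb * den - p * (2 * fa - fb)) / den^2)
      dfb <- dfb + rs * ((fa * den - p * (2 * fb - fa)) / den^2)
    } else {
      n <- ncol(fa)
      dfa <- dfa + rs * fb / n
      dfb <- dfb + rs * fa / n
    }
  }
  list(dfa = dfa, dfb = dfb)
}

# ---- SMLP forward / backward ----------------------------------------------
.fwd_smlp <- function(model, A, B) {
  p <- model$params; cfg <- model$config
  Za <- .addb(A %*% p$W1, p$b1); fa <- .relu(Za)
  Zb <- .addb(B %*% p$W1, p$b1); fb <- .relu(Zb)
  mc <- .measures_fwd(fa, fb, cfg$n_measures, "jaccard")
  H <- mc$fused
  nh <- length(cfg$head_widths)
  Zs <- vector("list", nh); Hs <- vector("list", nh + 1L)
  Hs[[1L]] <- H
  for (i in seq_len(nh)) {
    Zs[[i]] <- .addb(Hs[[i]] %*% p[[paste0("Wh", i)]], p[[paste0("bh", i)]])
    Hs[[i + 1L]] <- .relu(Zs[[i]])
  }
  z <- .addb(Hs[[nh + 1L]] %*% p$Wo, p$bo)
  list(prob = .sigmoid(z),
       cache = list(A = A, B = B, Za = Za, Zb = Zb, fa = fa, fb = fb,
                    mc = mc, Zs = Zs, Hs = Hs))
}

.bwd_smlp <- function(model, cache, dz) {
  p <- model$params; cfg <- model$config
  nh <- length(cfg$head_widths)
  g <- list()
  Hlast <- cache$Hs[[nh + 1L]]
  g$Wo <- crossprod(Hlast, dz); g$bo <- colSums(dz)
  dH <- tcrossprod(dz, p$Wo)
  for (i in rev(seq_len(nh))) {
    dZ <- dH * (cache$Zs[[i]] > 0)
    g[[paste0("Wh", i)]] <- crossprod(cache$Hs[[i]], dZ)
    g[[paste0("bh", i)]] <- colSums(dZ)
    dH <- tcrossprod(dZ, p[[paste0("Wh", i)]])
  }
  mb <- .measures_bwd(dH, cache$fa, cache$fb, cache$mc, cfg$n_measures)
  dZa <- mb$dfa * (cache$Za > 0)
  dZb <- mb$dfb * (cache$Zb > 0)
  g$W1 <- crossprod(cache$A, dZa) + crossprod(cache$B, dZb)
  g$b1 <- colSums(dZa) + colSums(dZb)
  g
}

# ---- SCNN1D branch (shared with the feature hybrid) -----------------------
.scnn_branch_fwd <- function(X, p, cfg) {
  B <- nrow(X); L <- ncol(X)
  X3 <- array(X, c(B, L, 1L))
  c1 <- .conv1d_fwd(X3, p$Wc1, p$bc1); H1 <- .relu(c1$Y)
  p1 <- .pool2_fwd(H1)
  c2 <- .conv1d_fwd(p1$Y, p$Wc2, p$bc2); H2 <- .relu(c2$Y)
  p2 <- .pool2_fwd(H2)
  Flat <- p2$Y; dim(Flat) <- c(B, (L %/% 4L) * cfg$filters)
  Zd <- .addb(Flat %*% p$Wd, p$bd)
  f <- .sigmoid(Zd)
  list(f = f, c1 = c1, c2 = c2, p1 = p1, p2 = p2, Flat = Flat, Zd = Zd)
}

.scnn_branch_bwd <- function(df, br, p, cfg, B, L) {
  dZd <- df * br$f * (1 - br$f)
  g <- list(Wd = crossprod(br$Flat, dZd), bd = colSums(dZd))
  dFlat <- tcrossprod(dZd, p$Wd)
  dim(dFlat) <- c(B, L %/% 4L, cfg$filters)
  dH2 <- .pool2_bwd(dFlat, br$p2)
  dZ2 <- dH2 * (br$c2$Y > 0)
  cb2 <- .conv1d_bwd(dZ2, p$Wc2, br$c2$Xcol, br$c2$dims)
  g$Wc2 <- cb2$dW; g$bc2 <- cb2$db
  dH1 <- .pool2_bwd(cb2$dX, br$p1)
  dZ1 <- dH1 * (br$c1$Y > 0)
  cb1 <- .conv1d_bwd(dZ1, p$Wc1, br$c1$Xcol, br$c1$dims)
  g$Wc1 <- cb1$dW; g$bc1 <- cb1$db
  g
}

.fwd_scnn1d <- function(model, A, B) {
  p <- model$params; cfg <- model$config
  bra <- .scnn_branch_fwd(A, p, cfg)
  brb <- .scnn_branch_fwd(B, p, cfg)
  mc <- .measures_fwd(bra$f, brb$f, cfg$n_measures, "russel")
  z <- .addb(mc$fused %*% p$Wo, p$bo)
  list(prob = .sigmoid(z),
       cache = list(A = A, B = B, bra = bra, brb = brb, mc = mc))
}

.bwd_scnn1d <- function(model, cache, dz) {
  p <- model$params; cfg <- model$config
  g <- list(Wo = crossprod(cache$mc$fused, dz), bo = colSums(dz))
  dfused <- tcrossprod(dz, p$Wo)
  mb <- .measures_bwd(dfused, cache$bra$f, cache$brb$f, cache$mc, cfg$n_measures)
  Bn <- nrow(cache$A); L <- ncol(cache$A)
  ga <- .scnn_branch_bwd(mb$dfa, cache$bra, p, cfg, Bn, L)
  gb <- .scnn_branch_bwd(mb$dfb, cache$brb, p, cfg, Bn, L)
  for (nm in names(ga)) g[[nm]] <- ga[[nm]] + gb[[nm]]
  g
}

.forward_any <- function(model, A, B) {
  switch(model$kind,
         smlp = .fwd_smlp(model, A, B),
         scnn1d = .fwd_scnn1d(model, A, B),
         feature_hybrid = .fwd_fhybrid(model, A, B),
         stop("unknown model kind: ", model$kind))
}

.backward_any <- function(model, cache, dz) {
  switch(model$kind,
         smlp = .bwd_smlp(model, cache, dz),
         scnn1d = .bwd_scnn1d(model, cache, dz),
         feature_hybrid = .bwd_fhybrid(model, cache, dz),
         stop("unknown model kind: ", model$kind))
}

#' Train a Siamese (or feature-hybrid) scorer
#'
#' Mini-batch RMSprop on binary cross-entropy over labelled fingerprint pairs.
#' Deterministic given the training-spec seed. The per-epoch mean loss is
#' recorded in the returned scorer's `loss_trace`.
#'
#' @param scorer an untrained (or previously trained) scorer from
#'   [build_siamese()] or [build_feature_hybrid()].
#' @param pairs a `pair_batch` from [generate_pairs()].
#' @param spec a [train_spec()].
#' @return the trained scorer, with `trained = TRUE` and `loss_trace` filled.
#' @export
train_scorer <- function(scorer, pairs, spec = train_spec()) {
  stopifnot(inherits(pairs, "pair_batch"), inherits(spec, "train_spec"))
  if (is.null(scorer$params)) stop("scorer has no trainable parameters")
  y <- pairs$label
  if (length(y) == 0L) stop("empty pair batch")
  if (length(unique(y)) < 2L)
    stop("degenerate supervision: pair batch contains a single class label")
  n <- length(y)
  state <- .zero_like(scorer$params)
  losses <- numeric(spec$epochs)
  .with_seed(spec$seed, {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      bl <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
      eploss <- 0
      for (ix in bl) {
        A <- pairs$a[ix, , drop = FALSE]
        B <- pairs$b[ix, , drop = FALSE]
        yb <- y[ix]
        fw <- .forward_any(scorer, A, B)
        pr <- pmin(pmax(fw$prob, 1e-7), 1 - 1e-7)
        eploss <- eploss + sum(-(yb * log(pr) + (1 - yb) * log(1 - pr)))
        dz <- (fw$prob - yb) / length(ix)   # dL/dz through the sigmoid
        g <- .backward_any(scorer, fw$cache, dz)
        upd <- .rmsprop_step(scorer$params, g, state,
                             spec$learning_rate, spec$rho, spec$epsilon)
        scorer$params <- upd$params; state <- upd$state
      }
      losses[ep] <- eploss / n
    }
  })
  scorer$trained <- TRUE
  scorer$loss_trace <- losses
  scorer
}

#' Score a batch of fingerprint pairs
#'
#' Rows of `A` are scored against the corresponding rows of `B`. All scorers
#' return values in \[0, 1\] and are symmetric in their arguments.
#'
#' @param scorer a scorer object (TAN baseline, Siamese, or hybrid).
#' @param A,B numeric matrices with one fingerprint per row.
#' @return numeric vector of similarity scores.
#' @export
score_batch <- function(scorer, A, B) UseMethod("score_batch")

#' @export
score_batch.siamese_scorer <- function(scorer, A, B) {
  if (ncol(A) != scorer$config$input_length || ncol(B) != ncol(A))
    stop("length mismatch: fingerprints do not match model input length")
  as.numeric(.forward_any(scorer, A, B)$prob)
}

#' Score one fingerprint pair
#'
#' @param scorer a scorer object.
#' @param a,b numeric fingerprint vectors of equal length.
#' @return scalar score in \[0, 1\].
#' @export
score_pair <- function(scorer, a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  score_batch(scorer, matrix(a, 1L), matrix(b, 1L))
}

#' Continuous-Tanimoto baseline scorer
#'
#' A parameter-free scorer applying [tanimoto_score()] to the raw count
#' fingerprints; the conventional virtual-screening baseline (TAN).
#'
#' @return object of class `tan_scorer`.
#' @export
tan_scorer <- function() {
  structure(list(kind = "tan", trained = TRUE), class = "tan_scorer")
}

#' @export
score_batch.tan_scorer <- function(scorer, A, B) {
  if (ncol(A) != ncol(B)) stop("length mismatch")
  p <- rowSums(A * B)
  den <- rowSums(A^2) + rowSums(B^2) - p
  if (any(den == 0)) stop("Tanimoto undefined: both fingerprints zero")
  p / den
}

#' @export
print.siamese_scorer <- function(x, ...) {
  cat(sprintf("%s scorer (L=%d, %d measures, %s)\n", toupper(x$kind),
              x$config$input_length, x$config$n_measures,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}
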