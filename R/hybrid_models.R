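# Hybrid designs combining the SMLP and SCNN1D scorers.
#
# Decision fusion: the two complete scorers are trained independently and
# their final similarity scores are combined by elementwise maximum
# (Hybrid-D-Max2 with two measures per component, Hybrid-D-Max3 with three).
#
# Feature fusion: a single end-to-end model. The SMLP trunk (twin dense
# branch, three measures with continuous Jaccard, measure fusion, then dense
# ReLU layers of 1024 and 512 units) and the SCNN1D trunk (twin convolutional
# branch, three measures with Russel, measure fusion) each emit a 512-wide
# vector; the two vectors are combined elementwise by sum (Hybrid-F-Sum) or
# maximum (Hybrid-F-Max) and passed to a single sigmoid output unit. The whole
# model is one parameter set trained jointly with RMSprop on binary
# cross-entropy.

#' Decision-fusion hybrid of two trained scorers
#'
#' @param model_a,model_b trained scorers accepting the same fingerprint
#'   length (conventionally the SMLP and SCNN1D models).
#' @return object of class `decision_hybrid`.
#' @export
decision_hybrid <- function(model_a, model_b) {
  for (m in list(model_a, model_b))
    if (!isTRUE(m$trained)) stop("decision fusion requires trained components")
  La <- model_a$config$input_length; Lb <- model_b$config$input_length
  if (!is.null(La) && !is.null(Lb) && La != Lb)
    stop("components accept different fingerprint lengths")
  structure(list(kind = "decision_hybrid", model_a = model_a, model_b = model_b,
                 trained = TRUE),
            class = "decision_hybrid")
}

#' Decision fusion by maximum
#'
#' The hybrid score of a pair is the maximum of the two component scores, so
#' it always dominates both components.
#'
#' @param hybrid a [decision_hybrid()].
#' @param a,b fingerprint vectors.
#' @return scalar score in \[0, 1\].
#' @export
decision_fuse_max <- function(hybrid, a, b) {
  stopifnot(inherits(hybrid, "decision_hybrid"))
  score_pair(hybrid, a, b)
}

#' @export
score_batch.decision_hybrid <- function(scorer, A, B) {
  pmax(score_batch(scorer$model_a, A, B), score_batch(scorer$model_b, A, B))
}

#' Feature-fusion hybrid configuration
#'
#' @param input_length fingerprint length L, divisible by 4.
#' @param combine elementwise combination of the two 512-wide trunk vectors:
#'   `"sum"` or `"max"`.
#' @param filters,kernel SCNN1D trunk convolution shape.
#' @param trunk_width width of the combined feature space (512).
#' @return list of class `fhybrid_config`.
#' @export
feature_hybrid_config <- function(input_length = 1024L, combine = c("sum", "max"),
                                  filters = 64L, kernel = 3L, trunk_width = 512L) {
  combine <- match.arg(combine)
  if (input_length %% 4L != 0L)
    stop("input_length must be divisible by 4 (two pool-by-2 stages)")
  structure(list(input_length = as.integer(input_length), combine = combine,
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 trunk_width = as.integer(trunk_width), n_measures = 3L),
            class = "fhybrid_config")
}

#' Build an (untrained) feature-fusion hybrid scorer
#'
#' @param cfg a [feature_hybrid_config()], or a combine token (`"sum"`/`"max"`)
#'   for the default geometry.
#' @param seed initialization seed.
#' @param input_length fingerprint length, used when `cfg` is a token.
#' @return object of class `feature_hybrid`, trainable with [train_scorer()].
#' @export
build_feature_hybrid <- function(cfg = c("sum", "max"), seed = 1L,
                                 input_length = 1024L) {
  if (is.character(cfg)) {
    if (!cfg[1L] %in% c("sum", "max"))
      stop("invalid combine token: ", cfg[1L], " (must be \"sum\" or \"max\")")
    cfg <- feature_hybrid_config(input_length, cfg[1L])
  }
  stopifnot(inherits(cfg, "fhybrid_config"))
  L <- cfg$input_length; Fl <- cfg$filters; Tw <- cfg$trunk_width
  flat <- (L %/% 4L) * Fl
  params <- .with_seed(seed, {
    list(
      # SMLP trunk
      W1 = .glorot(L, 1024L), b1 = numeric(1024L),
      Wh1 = .glorot(1024L, 1024L), bh1 = numeric(1024L),
      Wh2 = .glorot(1024L, Tw), bh2 = numeric(Tw),
      # SCNN1D trunk
      Wc1 = .glorot(cfg$kernel * 1L, Fl), bc1 = numeric(Fl),
      Wc2 = .glorot(cfg$kernel * Fl, Fl), bc2 = numeric(Fl),
      Wd = .glorot(flat, Tw), bd = numeric(Tw),
      # output head
      Wo = .glorot(Tw, 1L), bo = numeric(1L)
    )
  })
  structure(list(kind = "feature_hybrid", config = cfg, params = params,
                 trained = FALSE, loss_trace = numeric(0)),
            class = c("feature_hybrid", "siamese_scorer"))
}

# SMLP trunk: dense branch -> 3 measures (Jaccard third) -> fusion ->
# dense 1024 -> dense 512, ReLU throughout.
.fhybrid_smlp_trunk_fwd <- function(A, B, p) {
  Za <- .addb(A %*% p$W1, p$b1); fa <- .relu(Za)
  Zb <- .addb(B %*% p$W1, p$b1); fb <- .relu(Zb)
  mc <- .measures_fwd(fa, fb, 3L, "jaccard")
  Z1 <- .addb(mc$fused %*% p$Wh1, p$bh1); H1 <- .relu(Z1)
  Z2 <- .addb(H1 %*% p$Wh2, p$bh2); H2 <- .relu(Z2)
  list(v = H2, Za = Za, Zb = Zb, fa = fa, fb = fb, mc = mc,
       Z1 = Z1, H1 = H1, Z2 = Z2)
}

.fhybrid_smlp_trunk_bwd <- function(dv, tr, A, B, p) {
  dZ2 <- dv * (tr$Z2 > 0)
  g <- list(Wh2 = crossprod(tr$H1, dZ2), bh2 = colSums(dZ2))
  dH1 <- tcrossprod(dZ2, p$Wh2)
  dZ1 <- dH1 * (tr$Z1 > 0)
  g$Wh1 <- crossprod(tr$mc$fused, dZ1); g$bh1 <- colSums(dZ1)
  dfused <- tcrossprod(dZ1, p$Wh1)
  mb <- .measures_bwd(dfused, tr$fa, tr$fb, tr$mc, 3L)
  dZa <- mb$dfa * (tr$Za > 0)
  dZb <- mb$dfb * (tr$Zb > 0)
  g$W1 <- crossprod(A, dZa) + crossprod(B, dZb)
  g$b1 <- colSums(dZa) + colSums(dZb)
  g
}

.fwd_fhybrid <- function(model, A, B) {
  p <- model$params; cfg <- model$config
  ts <- .fhybrid_smlp_trunk_fwd(A, B, p)
  bra <- .scnn_branch_fwd(A, p, cfg)
  brb <- .scnn_branch_fwd(B, p, cfg)
  mcc <- .measures_fwd(bra$f, brb$f, 3L, "russel")
  vs <- ts$v; vc <- mcc$fused
  if (cfg$combine == "sum") {
    z0 <- vs + vc; mask <- NULL
  } else {
    mask <- vs >= vc                     # ties routed to the SMLP trunk
    z0 <- pmax(vs, vc)
  }
  z <- .addb(z0 %*% p$Wo, p$bo)
  list(prob = .sigmoid(z),
       cache = list(A = A, B = B, ts = ts, bra = bra, brb = brb,
                    mcc = mcc, z0 = z0, mask = mask))
}

.bwd_fhybrid <- function(model, cache, dz) {
  p <- model$params; cfg <- model$config
  g <- list(Wo = crossprod(cache$z0, dz), bo = colSums(dz))
  dz0 <- tcrossprod(dz, p$Wo)
  if (cfg$combine == "sum") {
    dvs <- dz0; dvc <- dz0
  } else {
    dvs <- dz0 * cache$mask; dvc <- dz0 * (1 - cache$mask)
  }
  gs <- .fhybrid_smlp_trunk_bwd(dvs, cache$ts, cache$A, cache$B, p)
  mb <- .measures_bwd(dvc, cache$bra$f, cache$brb$f, cache$mcc, 3L)
  Bn <- nrow(cache$A); L <- ncol(cache$A)
  ga <- .scnn_branch_bwd(mb$dfa, cache$bra, p, cfg, Bn, L)
  gb <- .scnn_branch_bwd(mb$dfb, cache$brb, p, cfg, Bn, L)
  for (nm in names(gs)) g[[nm]] <- gs[[nm]]
  for (nm in names(ga)) g[[nm]] <- ga[[nm]] + gb[[nm]]
  g
}

#' Train a feature-fusion hybrid scorer
#'
#' End-to-end training of both trunks and the output head as one parameter
#' set; identical contract to [train_scorer()].
#'
#' @inheritParams train_scorer
#' @return the trained scorer with its per-epoch loss trace.
#' @export
train_feature_hybrid <- function(scorer, pairs, spec = train_spec()) {
  stopifnot(inherits(scorer, "feature_hybrid"))
  train_scorer(scorer, pairs, spec)
}

#' @export
print.decision_hybrid <- function(x, ...) {
  cat(sprintf("decision-fusion (max) hybrid of %s + %s\n",
              toupper(x$model_a$kind), toupper(x$model_b$kind)))
  invisible(x)
}
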