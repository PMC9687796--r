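# All model tests run at reduced fingerprint length; the architectures are
# size-generic and the default 1024 geometry is exercised in construction.

test_that("measure fusion broadcast-adds the scalar measures", {
  expect_equal(measure_fusion(c(0, 1, 2), 0.5), c(0.5, 1.5, 2.5))
  expect_equal(measure_fusion(c(3, 4), c(0, 0)), c(3, 4))
  expect_equal(measure_fusion(1, c(0.2, 0.3)), 1.5)
  expect_error(measure_fusion(c(1, 2), numeric(0)), "scalar measure")
})

test_that("default geometries build and invalid ones are rejected", {
  m <- build_siamese(smlp_config(), seed = 1)
  expect_equal(dim(m$params$W1), c(1024, 1024))
  expect_equal(dim(m$params$Wh1), c(1024, 1024))
  expect_equal(dim(m$params$Wo), c(64, 1))
  expect_error(scnn1d_config(input_length = 1026), "divisible by 4")
  expect_error(smlp_config(n_measures = 4))
})

test_that("scores are symmetric, in [0,1], and sigmoid(0)=0.5 with a zeroed output layer", {
  set.seed(501)
  L <- 32
  A <- matrix(abs(rnorm(20 * L)), 20, L)
  B <- matrix(abs(rnorm(20 * L)), 20, L)
  for (m in list(build_siamese(smlp_config(L, 2, branch_width = 64,
                                           head_widths = c(64, 32)), seed = 2),
                 build_siamese(smlp_config(L, 3, branch_width = 64,
                                           head_widths = c(64, 32)), seed = 2),
                 build_siamese(scnn1d_config(L, 2, filters = 8,
                                             feature_width = 24), seed = 2),
                 build_siamese(scnn1d_config(L, 3, filters = 8,
                                             feature_width = 24), seed = 2))) {
    s_ab <- score_batch(m, A, B)
    s_ba <- score_batch(m, B, A)
    expect_true(all(s_ab >= 0 & s_ab <= 1))
    expect_lt(max(abs(s_ab - s_ba)), 1e-6)

    mz <- m
    mz$params$Wo[] <- 0; mz$params$bo[] <- 0
    expect_equal(score_pair(mz, A[1, ], A[1, ]), 0.5)
  }
  expect_error(score_batch(build_siamese(smlp_config(L), seed = 1),
                           A[, 1:10], B[, 1:10]), "length mismatch")
})

test_that("weight sharing is structural: one parameter set drives both twins", {
  L <- 16
  m <- build_siamese(smlp_config(L, 2, branch_width = 24, head_widths = 8), seed = 3)
  x <- abs(rnorm(L))
  branch <- function(model, v)
    pmax(matrix(v, 1) %*% model$params$W1 + rep(model$params$b1, each = 1), 0)
  before_a <- branch(m, x)
  m$params$W1 <- m$params$W1 + 0.1
  after_a <- branch(m, x)
  # feeding the same input through "both" twins is literally the same map,
  # so a parameter perturbation shifts both branch outputs identically
  expect_false(isTRUE(all.equal(before_a, after_a)))
  expect_identical(branch(m, x), branch(m, x))
})

test_that("analytic gradients agree with finite differences for both architectures", {
  set.seed(502)
  ns <- asNamespace("siamscreen")
  L <- 16
  A <- matrix(abs(rnorm(3 * L)), 3, L)
  B <- matrix(abs(rnorm(3 * L)), 3, L)
  y <- c(1, 0, 1)
  relerr <- function(model, eps = 1e-5) {
    loss <- function(m) {
      p <- pmin(pmax(ns$.forward_any(m, A, B)$prob, 1e-7), 1 - 1e-7)
      sum(-(y * log(p) + (1 - y) * log(1 - p))) / 3
    }
    fw <- ns$.forward_any(model, A, B)
    g <- ns$.backward_any(model, fw$cache, (fw$prob - y) / 3)
    worst <- 0
    for (nm in names(g)) {
      P <- model$params[[nm]]
      for (ii in sample(length(P), min(4, length(P)))) {
        m2 <- model
        m2$params[[nm]][ii] <- P[ii] + eps; lp <- loss(m2)
        m2$params[[nm]][ii] <- P[ii] - eps; lm <- loss(m2)
        num <- (lp - lm) / (2 * eps)
        an <- g[[nm]][ii]
        worst <- max(worst, abs(num - an) / max(1e-8, abs(num) + abs(an)))
      }
    }
    worst
  }
  expect_lt(relerr(build_siamese(smlp_config(L, 3, branch_width = 32,
                                             head_widths = c(32, 16)), seed = 7)),
            1e-5)
  expect_lt(relerr(build_siamese(scnn1d_config(L, 3, filters = 8,
                                               feature_width = 24), seed = 7)),
            1e-5)
})

test_that("training records a loss trace, is seed-deterministic, and preserves symmetry", {
  lib <- easy_library(length = 64, seed = 31)
  pairs <- generate_pairs(lib, 60, 0.5, seed = 2)
  m0 <- build_siamese(smlp_config(64L, 2, branch_width = 64,
                                  head_widths = c(64, 32)), seed = 3)
  m1 <- train_scorer(m0, pairs, train_spec(epochs = 1, seed = 4))
  expect_length(m1$loss_trace, 1)
  expect_true(all(is.finite(m1$loss_trace)))
  expect_true(m1$trained)

  m2 <- train_scorer(m0, pairs, train_spec(epochs = 1, seed = 4))
  probe <- score_pair(m1, lib$fingerprints[1, ], lib$fingerprints[40, ])
  expect_identical(probe,
                   score_pair(m2, lib$fingerprints[1, ], lib$fingerprints[40, ]))
  # symmetry survives training
  expect_equal(probe,
               score_pair(m1, lib$fingerprints[40, ], lib$fingerprints[1, ]),
               tolerance = 1e-6)

  # degenerate single-class supervision is rejected
  bad <- pairs; bad$label <- rep(1L, length(bad$label))
  expect_error(train_scorer(m0, bad, train_spec(epochs = 1)),
               "degenerate supervision")
})

test_that("a trained SMLP separates held-out same-class from different-class pairs", {
  lib <- easy_library(length = 64, seed = 11)
  pairs <- generate_pairs(lib, 300, 0.5, seed = 2)
  m <- build_siamese(smlp_config(64L, 2, branch_width = 128,
                                 head_widths = c(128, 64)), seed = 3)
  m <- train_scorer(m, pairs, train_spec(epochs = 4, seed = 4))
  held <- generate_pairs(lib, 200, 0.5, seed = 99)
  sc <- score_batch(m, held$a, held$b)
  expect_gt(mean(sc[held$label == 1]) - mean(sc[held$label == 0]), 0)
})

test_that("batch scoring equals a loop of single-pair scores", {
  set.seed(503)
  L <- 32
  m <- build_siamese(scnn1d_config(L, 2, filters = 8, feature_width = 16), seed = 5)
  A <- matrix(abs(rnorm(6 * L)), 6, L)
  B <- matrix(abs(rnorm(6 * L)), 6, L)
  batch <- score_batch(m, A, B)
  loop <- vapply(1:6, function(i) score_pair(m, A[i, ], B[i, ]), numeric(1))
  expect_equal(batch, loop, tolerance = 1e-12)
})
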