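# Small in-code fixtures shared across the suite.

# A tiny deterministic library: two 3-member classes plus two inactives, L = 6.
tiny_library <- function() {
  F <- rbind(
    A1 = c(3, 1, 0, 0, 2, 0),
    A2 = c(2, 1, 0, 0, 2, 1),
    A3 = c(3, 0, 1, 0, 2, 0),
    B1 = c(0, 0, 4, 2, 0, 1),
    B2 = c(0, 1, 4, 2, 0, 0),
    B3 = c(0, 0, 3, 2, 1, 1),
    I1 = c(1, 0, 0, 1, 0, 0),
    I2 = c(0, 2, 0, 0, 0, 1)
  )
  screening_library(F, c("A", "A", "A", "B", "B", "B", "INACTIVE", "INACTIVE"))
}

# An easy, well-separated synthetic library for learnability checks.
easy_library <- function(length = 64L, n_per_class = 30L, n_inactive = 40L,
                         target = 0.6, seed = 11L) {
  cfg <- generator_config(
    list(class_spec("C1", n_per_class, target),
         class_spec("C2", n_per_class, target)),
    n_inactive = n_inactive, length = length, seed = seed)
  generate_library(cfg)
}

# Random nonnegative feature vectors for measure/property tests.
random_pair <- function(n, rng) {
  list(a = abs(stats::rnorm(n)), b = abs(stats::rnorm(n)))
}
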