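## Shared fixtures, all generated in code at test time.

## Small, well-separated nested concept space (12 items, dim 8).
small_space <- function(seed = 1L) {
  generate_hierarchy(2, 2, 3, 8, c(10, 2, 0.5), seed = seed)
}

## Deterministic annotator (near-argmax choices, no lapse, no RT noise).
det_annotator <- function() {
  annotator_model(temperature = 1e-3, lapse_rate = 0, rt_noise_sd = 0)
}

## Random normalized soft-target rows.
random_soft <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(stats::rexp(n * 3), n, 3)
    m / rowSums(m)
  })
}

## Brute-force dot product, elementwise sum of products.
dot_oracle <- function(a, b) {
  acc <- 0
  for (t in seq_along(a)) acc <- acc + a[t] * b[t]
  acc
}

## Direct evaluation of the three-way softmax choice rule (independent of
## choice_probabilities' max-subtraction path).
softmax_oracle <- function(s, tau = 1) {
  e <- exp(s / tau)
  e / sum(e)
}

## A well-conditioned random affine map (identity + perturbation).
random_affine <- function(p, seed = 1L, sd = 0.25) {
  withr::with_seed(seed, {
    affine_transform(diag(p) + matrix(stats::rnorm(p * p, sd = sd), p, p),
                     stats::rnorm(p, sd = 0.3))
  })
}
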