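#' Generate a nested (superordinate / basic / subordinate) concept space
#'
#' Draws superordinate centroids from an isotropic Gaussian, basic-level
#' centroids around their superordinate centroid, and item vectors around
#' their basic centroid, with the stated spread at each level.  Each item
#' therefore carries one nested label per level; the subordinate level is
#' identified with the basic-level cell's items split one leaf per basic
#' group of `n_items_per_basic` (every item in a basic cell shares one
#' subordinate label drawn per cell).
#'
#' @param n_super number of superordinate categories.
#' @param n_basic_per_super basic-level categories per superordinate.
#' @param n_items_per_basic items per basic category.
#' @param dim embedding dimensionality (>= 2).
#' @param level_spreads positive numeric of length 3: standard deviations
#'   for (superordinate centroids, basic centroids, items).
#' @param seed integer seed; output is deterministic given the seed.
#' @return object of class `hierarchy_space` with fields `embeddings`
#'   (items x dim), `labels` (data.frame: item, subordinate, basic,
#'   superordinate) and `params`.
#' @export
generate_hierarchy <- function(n_super, n_basic_per_super, n_items_per_basic,
                               dim, level_spreads, seed = 1L) {
  n_super <- check_count(n_super, "n_super")
  n_basic_per_super <- check_count(n_basic_per_super, "n_basic_per_super")
  n_items_per_basic <- check_count(n_items_per_basic, "n_items_per_basic")
  dim <- check_count(dim, "dim", min = 2L)
  if (length(level_spreads) != 3L || any(level_spreads <= 0))
    stopf("`level_spreads` must be three positive numbers")
  n_basic <- n_super * n_basic_per_super
  n_items <- n_basic * n_items_per_basic

  emb <- withr::with_seed(seed, {
    super_c <- matrix(stats::rnorm(n_super * dim, sd = level_spreads[1L]),
                      n_super, dim)
    basic_c <- super_c[rep(seq_len(n_super), each = n_basic_per_super), ,
                       drop = FALSE] +
      matrix(stats::rnorm(n_basic * dim, sd = level_spreads[2L]), n_basic, dim)
    basic_c[rep(seq_len(n_basic), each = n_items_per_basic), , drop = FALSE] +
      matrix(stats::rnorm(n_items * dim, sd = level_spreads[3L]),
             n_items, dim)
  })

  basic <- rep(seq_len(n_basic), each = n_items_per_basic)
  labels <- data.frame(
    item = seq_len(n_items),
    subordinate = basic,            # one subordinate leaf per basic cell
    basic = basic,
    superordinate = rep(seq_len(n_super),
                        each = n_basic_per_super * n_items_per_basic)
  )
  structure(
    list(embeddings = emb, labels = labels,
         params = list(n_super = n_super,
                       n_basic_per_super = n_basic_per_super,
                       n_items_per_basic = n_items_per_basic,
                       dim = dim, level_spreads = as.numeric(level_spreads),
                       seed = as.integer(seed))),
    class = "hierarchy_space"
  )
}

#' @export
print.hierarchy_space <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<hierarchy_space> %d items (%d super x %d basic x %d items), dim %d\n",
    nrow(x$embeddings), p$n_super, p$n_basic_per_super, p$n_items_per_basic,
    p$dim))
  invisible(x)
}

#' Simulated annotator model
#'
#' A stylized human rater: choices follow the softmax choice rule over
#' ground-truth dot-product similarities at `temperature`, except that
#' with probability `lapse_rate` the rater picks a pair uniformly at
#' random.  Response times are log-linear in the entropy of the rater's
#' choice distribution: `log(RT) = rt_intercept + rt_slope * H + noise`.
#'
#' @param temperature positive choice-softmax temperature.
#' @param lapse_rate probability in \[0,1\] of a uniform random response.
#' @param rt_intercept,rt_slope log-RT model coefficients.
#' @param rt_noise_sd non-negative log-RT noise standard deviation.
#' @return object of class `annotator_model`.
#' @export
annotator_model <- function(temperature = 1, lapse_rate = 0,
                            rt_intercept = 0.5, rt_slope = 1,
                            rt_noise_sd = 0.1) {
  check_scalar(temperature, "temperature", lower = 0, strict_lower = TRUE)
  check_scalar(lapse_rate, "lapse_rate", lower = 0, upper = 1)
  check_scalar(rt_noise_sd, "rt_noise_sd", lower = 0)
  structure(
    list(temperature = temperature, lapse_rate = lapse_rate,
         rt_intercept = rt_intercept, rt_slope = rt_slope,
         rt_noise_sd = rt_noise_sd),
    class = "annotator_model"
  )
}

#' Simulate annotator odd-one-out responses for a set of triplets
#'
#' For each triplet and each of `n_annotators_per_triplet` raters, draws a
#' pair choice from the lapse-mixed softmax choice distribution over the
#' ground-truth similarities, and a response time from the annotator's
#' log-linear RT model evaluated at the entropy of that (lapse-mixed)
#' choice distribution.  The base seed is split into one deterministic
#' substream per annotator, so runs are reproducible and annotators are
#' independent.
#'
#' @param space `hierarchy_space` (or any list with an `embeddings` matrix).
#' @param triplets n x 3 integer matrix of item indices.
#' @param annot `annotator_model`.
#' @param n_annotators_per_triplet raters per triplet (>= 1).
#' @param seed integer seed.
#' @return `triplet_responses` with hard choices, participant ids and RTs.
#' @export
simulate_responses <- function(space, triplets, annot,
                               n_annotators_per_triplet = 1L, seed = 1L) {
  stopifnot(inherits(annot, "annotator_model"))
  emb <- check_matrix(space$embeddings, "space$embeddings")
  triplets <- as_triplet_matrix(triplets)
  check_indices(triplets, nrow(emb))
  n_annot <- check_count(n_annotators_per_triplet, "n_annotators_per_triplet")
  n <- nrow(triplets)

  s <- pair_similarities(emb, triplets)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  p_soft <- softmax3(s, annot$temperature)
  ## lapse-mixed choice distribution actually generating the responses
  p_mix <- (1 - annot$lapse_rate) * p_soft + annot$lapse_rate / 3
  h <- entropy_nats(p_mix)

  choice <- integer(n * n_annot)
  rt <- numeric(n * n_annot)
  for (a in seq_len(n_annot)) {
    sub_seed <- derive_seed(seed, a)
    idx <- (a - 1L) * n + seq_len(n)
    choice[idx] <- withr::with_seed(sub_seed, {
      u <- stats::runif(n)
      cum1 <- p_mix[, 1L]
      cum2 <- p_mix[, 1L] + p_mix[, 2L]
      1L + (u > cum1) + (u > cum2)
    })
    rt[idx] <- simulate_response_time(h, annot, seed = derive_seed(sub_seed, 7L))
  }
  triplet_responses(
    triplets = triplets,
    choice = choice,
    triplet = rep(seq_len(n), times = n_annot),
    participant = rep(seq_len(n_annot), each = n),
    rt_seconds = rt
  )
}

#' Simulate response times from choice entropy
#'
#' `log(RT) = rt_intercept + rt_slope * entropy + Normal(0, rt_noise_sd)`;
#' the result is strictly positive by construction.
#'
#' @param choice_entropy non-negative entropy value(s), nats.
#' @param annot `annotator_model`.
#' @param seed integer seed.
#' @return response times in seconds, same length as `choice_entropy`.
#' @export
simulate_response_time <- function(choice_entropy, annot, seed = 1L) {
  stopifnot(inherits(annot, "annotator_model"))
  if (any(choice_entropy < 0)) stopf("`choice_entropy` must be non-negative")
  n <- length(choice_entropy)
  noise <- if (annot$rt_noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(n, sd = annot$rt_noise_sd))
  } else rep(0, n)
  exp(annot$rt_intercept + annot$rt_slope * choice_entropy + noise)
}
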