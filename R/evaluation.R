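#' Representational similarity matrix (RSM)
#'
#' Pairwise similarity of embedding rows under a cosine or Pearson
#' kernel.  The Pearson kernel is the cosine of row-centred vectors, so a
#' row that is constant (zero variance) is rejected by name.  Diagonal is
#' exactly 1 for both kernels.
#'
#' @param X items x p embedding matrix (>= 2 items).
#' @param kernel "pearson" (default) or "cosine".
#' @return object of class `rsm`: list with `matrix` and `kernel`.
#' @export
rsm <- function(X, kernel = c("pearson", "cosine")) {
  X <- check_matrix(X, "X")
  kernel <- match.arg(kernel)
  if (nrow(X) < 2L) stopf("need at least 2 items")
  if (kernel == "pearson") {
    sds <- apply(X, 1L, stats::sd)
    if (any(sds == 0))
      stopf("constant row(s) under the pearson kernel: %s",
            paste(which(sds == 0), collapse = ", "))
    X <- X - rowMeans(X)
  }
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stopf("zero-norm row(s): %s",
                           paste(which(nrm == 0), collapse = ", "))
  M <- (X / nrm) %*% t(X / nrm)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  structure(list(matrix = M, kernel = kernel), class = "rsm")
}

rsm_matrix <- function(x) {
  if (inherits(x, "rsm")) x$matrix else check_matrix(x, "rsm")
}

#' Spearman representational similarity analysis
#'
#' Spearman rank correlation (average-rank ties) of the strictly upper
#' triangles (diagonal excluded) of two RSMs of equal dimension.
#'
#' @param rsm_a,rsm_b `rsm` objects or plain square matrices.
#' @return correlation in \[-1, 1\].
#' @export
rsa_spearman <- function(rsm_a, rsm_b) {
  A <- rsm_matrix(rsm_a)
  B <- rsm_matrix(rsm_b)
  if (!all(dim(A) == dim(B))) stopf("RSM dimensions differ")
  if (nrow(A) < 3L) stopf("need at least 3 items")
  ut <- upper.tri(A)
  stats::cor(A[ut], B[ut], method = "spearman")
}

#' Majority pair response from counts
#'
#' Modal pair of the three response counts; exact ties are broken
#' uniformly at random from the seeded stream.
#'
#' @param counts three non-negative counts (pairs ij, ik, jk).
#' @param seed integer seed for tie-breaking.
#' @return pair code (1 = ij, 2 = ik, 3 = jk).
#' @export
majority_response <- function(counts, seed = 1L) {
  if (length(counts) != 3L || any(counts < 0))
    stopf("`counts` must be three non-negative integers")
  if (sum(counts) < 1) stopf("`counts` must sum to at least 1")
  top <- which(counts == max(counts))
  if (length(top) == 1L) return(top)
  withr::with_seed(seed, top[sample.int(length(top), 1L)])
}

#' Leave-one-out noise ceiling
#'
#' For each triplet with >= 2 responses, holds out each response in turn
#' and compares it with the majority of the remaining responses
#' (seeded uniform tie-break).  Returns the average match rate over all
#' held-out comparisons; triplets with a single response are excluded
#' with a warning.
#'
#' @param responses `triplet_responses` with hard choices.
#' @param seed integer seed (tie-breaking).
#' @return noise ceiling in \[0, 1\].
#' @export
noise_ceiling_loo <- function(responses, seed = 1L) {
  stopifnot(inherits(responses, "triplet_responses"))
  if (is.null(responses$choice)) stopf("`responses` carries no hard choices")
  by_trip <- split(responses$choice, responses$triplet)
  sizes <- vapply(by_trip, length, 1L)
  if (any(sizes < 2L)) {
    warning(sprintf("%d triplet(s) with a single response excluded",
                    sum(sizes < 2L)), call. = FALSE)
    by_trip <- by_trip[sizes >= 2L]
  }
  if (length(by_trip) == 0L) stopf("no triplet has >= 2 responses")
  k <- 0L
  matches <- numeric(0)
  for (ch in by_trip) {
    for (h in seq_along(ch)) {
      rest <- tabulate(ch[-h], nbins = 3L)
      k <- k + 1L
      maj <- majority_response(rest, seed = derive_seed(seed, k))
      matches <- c(matches, as.numeric(ch[h] == maj))
    }
  }
  mean(matches)
}

#' Preprocess response times
#'
#' Natural-log transform plus an exclusion mask for slow trials:
#' responses strictly longer than `max_rt` seconds (default 10) are
#' flagged for exclusion; there is no lower bound.
#'
#' @param rts positive response times in seconds.
#' @param max_rt exclusion threshold, strict inequality (default 10).
#' @return list with `log_rt` and logical `keep` mask.
#' @export
preprocess_rts <- function(rts, max_rt = 10) {
  if (any(rts <= 0) || any(!is.finite(rts)))
    stopf("response times must be positive and finite")
  list(log_rt = log(rts), keep = rts <= max_rt)
}

#' Participant exclusion filter
#'
#' Keeps participants with catch-trial accuracy of at least 90% and at
#' most 10 missing (timed-out) trials.
#'
#' @param per_participant data.frame with columns `participant`,
#'   `catch_accuracy` (in \[0,1\]) and `n_missing`.
#' @return the kept subset of `per_participant`.
#' @export
exclude_participants <- function(per_participant) {
  req <- c("participant", "catch_accuracy", "n_missing")
  if (!all(req %in% names(per_participant)))
    stopf("`per_participant` needs columns: %s", paste(req, collapse = ", "))
  acc <- per_participant$catch_accuracy
  if (any(acc < 0 | acc > 1)) stopf("catch_accuracy outside [0, 1]")
  keep <- acc >= 0.90 & per_participant$n_missing <= 10
  per_participant[keep, , drop = FALSE]
}

#' Spearman correlation between model entropies and response latencies
#'
#' @param model_entropies per-triplet model choice entropies.
#' @param mean_log_rts per-triplet mean log response times.
#' @return Spearman rank correlation.
#' @export
entropy_rt_correlation <- function(model_entropies, mean_log_rts) {
  if (length(model_entropies) != length(mean_log_rts))
    stopf("input lengths differ")
  if (length(model_entropies) < 3L) stopf("need at least 3 triplets")
  stats::cor(model_entropies, mean_log_rts, method = "spearman")
}

#' Hierarchical distance-change contrast between two checkpoints
#'
#' Computes all pairwise Euclidean distances before and after a training
#' intervention, z-scores each distance set against its own checkpoint's
#' distribution (so global rescaling cancels), and reports the mean
#' z-change (`z_after - z_before`) per hierarchical relation level:
#' same subordinate, same basic (different subordinate), same
#' superordinate (different basic), different superordinate.  Pairs are
#' first aggregated within their (sorted) basic-category pair so large
#' categories do not dominate the level mean.
#'
#' @param X_before,X_after items x p embedding matrices over the same
#'   item set.
#' @param labels data.frame with columns `subordinate`, `basic`,
#'   `superordinate` (as in a `hierarchy_space`).
#' @return data.frame with `relation_level`, `mean_z_change`, `n_pairs`.
#' @export
distance_change_by_level <- function(X_before, X_after, labels) {
  X_before <- check_matrix(X_before, "X_before")
  X_after <- check_matrix(X_after, "X_after")
  if (nrow(X_before) != nrow(X_after))
    stopf("checkpoints cover different item sets")
  if (nrow(X_before) != nrow(labels))
    stopf("labels do not cover the item set")
  db <- as.numeric(stats::dist(X_before))
  da <- as.numeric(stats::dist(X_after))
  zb <- as.numeric(scale(db))
  za <- as.numeric(scale(da))
  change <- za - zb

  ## stats::dist enumerates pairs as (1,2..n), (2,3..n), ...
  n <- nrow(X_before)
  pi <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pj <- unlist(lapply(seq_len(n - 1L), function(i) seq.int(i + 1L, n)),
               use.names = FALSE)

  sub <- labels$subordinate; bas <- labels$basic; sup <- labels$superordinate
  level <- ifelse(sub[pi] == sub[pj], "same_subordinate",
           ifelse(bas[pi] == bas[pj], "same_basic",
           ifelse(sup[pi] == sup[pj], "same_superordinate",
                  "different_superordinate")))
  ## cluster-aware aggregation: average within basic-category pair first
  key <- paste(pmin(bas[pi], bas[pj]), pmax(bas[pi], bas[pj]), sep = "|")
  agg <- stats::aggregate(change,
                          by = list(level = level, cluster = key), FUN = mean)
  out <- stats::aggregate(agg$x, by = list(relation_level = agg$level),
                          FUN = mean)
  names(out)[2L] <- "mean_z_change"
  counts <- table(level)
  out$n_pairs <- as.integer(counts[out$relation_level])
  lv <- c("same_subordinate", "same_basic", "same_superordinate",
          "different_superordinate")
  out[order(match(out$relation_level, lv)), , drop = FALSE]
}

#' Item-level bootstrap confidence interval for a mean score
#'
#' Percentile 95% CI of the mean over seeded with-replacement resamples
#' of `sample_size` items, `n_boot` repetitions.
#'
#' @param per_item_scores numeric scores, one per item.
#' @param n_boot bootstrap repetitions (default 100).
#' @param sample_size items per resample (default 1000).
#' @param seed integer seed.
#' @return list with `mean`, `lo95`, `hi95`.
#' @export
bootstrap_ci <- function(per_item_scores, n_boot = 100L, sample_size = 1000L,
                         seed = 1L) {
  if (length(per_item_scores) < 1L) stopf("`per_item_scores` is empty")
  n_boot <- check_count(n_boot, "n_boot", min = 2L)
  sample_size <- check_count(sample_size, "sample_size")
  means <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      mean(per_item_scores[sample.int(length(per_item_scores),
                                      sample_size, replace = TRUE)])
    }, numeric(1))
  })
  qs <- stats::quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean = mean(per_item_scores), lo95 = qs[1L], hi95 = qs[2L])
}

#' Relative improvement between two accuracies
#'
#' `100 * (after - before) / before`, the standard relative performance
#' increase in percent (e.g. an accuracy moving from 44.24% to 61.7% is a
#' 39.47% relative increase).
#'
#' @param before,after accuracies (any common scale, both > 0 for
#'   `before`).
#' @return relative improvement in percent.
#' @export
relative_improvement <- function(before, after) {
  check_scalar(before, "before", lower = 0, strict_lower = TRUE)
  check_scalar(after, "after")
  100 * (after - before) / before
}
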