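#' Pairwise dot-product similarities within a triplet
#'
#' For a triplet of items \eqn{(i, j, k)} drawn from an embedding matrix
#' \eqn{X}, computes the three raw dot products
#' \eqn{s_{ij} = x_i^\top x_j}, \eqn{s_{ik} = x_i^\top x_k},
#' \eqn{s_{jk} = x_j^\top x_k}.  Similarity is deliberately the
#' unnormalized dot product; cosine/Pearson kernels live in [rsm()].
#'
#' @param emb numeric matrix, items in rows.
#' @param triplet integer vector of length 3 (1-based row indices) or an
#'   n x 3 matrix of triplets.
#' @return For a single triplet, a named numeric vector
#'   `c(s_ij, s_ik, s_jk)`; for a triplet matrix, an n x 3 matrix with
#'   those columns.
#' @export
pair_similarities <- function(emb, triplet) {
  emb <- check_matrix(emb, "emb")
  single <- is.null(dim(triplet))
  t <- as_triplet_matrix(triplet)
  check_indices(t, nrow(emb))
  xi <- emb[t[, 1L], , drop = FALSE]
  xj <- emb[t[, 2L], , drop = FALSE]
  xk <- emb[t[, 3L], , drop = FALSE]
  s <- cbind(
    s_ij = rowSums(xi * xj),
    s_ik = rowSums(xi * xk),
    s_jk = rowSums(xj * xk)
  )
  if (single) s[1L, ] else s
}

#' Model odd-one-out choice from triplet similarities
#'
#' The closest pair is the argmax of the three pairwise similarities; the
#' remaining item is the odd one out.  Exact ties are broken in the fixed
#' pair order (i,j) < (i,k) < (j,k) so the rule is deterministic.
#'
#' @param s numeric vector `c(s_ij, s_ik, s_jk)` or an n x 3 matrix.
#' @return list with `pair` (integer code 1 = ij, 2 = ik, 3 = jk) and
#'   `odd` (position of the odd item within the triplet: 3, 2, 1).
#' @export
choose_odd_one_out <- function(s) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L, ncol = 3L)
  if (any(is.na(s)) || any(!is.finite(s)))
    stopf("similarities must be finite (no NaN/Inf)")
  pair <- argmax3(s)
  ## odd item is the one not in the closest pair: ij -> k, ik -> j, jk -> i
  odd <- c(3L, 2L, 1L)[pair]
  list(pair = pair, odd = odd)
}

#' Softmax choice probabilities over the three pairs of a triplet
#'
#' The probability that a pair \eqn{(a,b)} is judged most similar (the
#' remaining item being the odd one out) is modelled as the softmax of the
#' pairwise similarities at temperature \eqn{\tau}:
#' \deqn{p_{ab} = \exp(s_{ab}/\tau) / \sum_{(u,v)} \exp(s_{uv}/\tau).}
#' Computed with max-subtraction so large similarities cannot overflow.
#'
#' @param s numeric vector `c(s_ij, s_ik, s_jk)` or an n x 3 matrix.
#' @param temperature positive softmax temperature (default 1).
#' @return probability vector (or matrix) over the pairs (ij, ik, jk).
#' @export
choice_probabilities <- function(s, temperature = 1) {
  check_scalar(temperature, "temperature", lower = 0, strict_lower = TRUE)
  single <- is.null(dim(s))
  if (single) s <- matrix(s, nrow = 1L, ncol = 3L)
  if (any(!is.finite(s))) stopf("similarities must be finite")
  p <- softmax3(s, temperature)
  colnames(p) <- paste0("p_", PAIR_CODES)
  if (single) p[1L, ] else p
}

#' Odd-one-out accuracy
#'
#' Fraction of triplets on which the model's chosen pair equals the
#' reference (e.g. human) chosen pair.
#'
#' @param model_choices,reference_choices integer pair codes (1, 2, 3) or
#'   character codes ("ij", "ik", "jk"), equal lengths.
#' @return accuracy in \[0, 1\].
#' @export
odd_one_out_accuracy <- function(model_choices, reference_choices) {
  if (length(model_choices) != length(reference_choices) ||
      length(model_choices) < 1L)
    stopf("choice lists must have equal length >= 1")
  mean(pair_code(model_choices) == pair_code(reference_choices))
}

pair_code <- function(x) {
  if (is.character(x)) {
    code <- match(x, PAIR_CODES)
    if (any(is.na(code))) stopf("chosen_pair must be one of ij, ik, jk")
    code
  } else {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L) || any(x > 3L))
      stopf("pair codes must be integers in 1..3")
    x
  }
}

#' Shannon entropy of a triplet choice distribution (nats)
#'
#' \eqn{H(p) = -\sum_r p_r \log p_r} with \eqn{0 \log 0 := 0}, natural
#' logarithm.  Input must be normalized to 1 within `tol`.
#'
#' @param p probability vector of length 3 (or n x 3 matrix).
#' @param tol normalization tolerance (default 1e-6).
#' @return entropy in nats, in \[0, log 3\].
#' @export
triplet_entropy <- function(p, tol = 1e-6) {
  single <- is.null(dim(p))
  if (single) p <- matrix(p, nrow = 1L)
  if (any(p < -tol) || any(abs(rowSums(p) - 1) > tol))
    stopf("`p` must be a normalized probability distribution")
  h <- entropy_nats(pmax(p, 0))
  if (single) h[1L] else h
}

#' Entropy of an empirical response-count distribution
#'
#' Discrete Shannon entropy of the pair-choice frequencies across
#' participants for one triplet, from raw counts.
#'
#' @param counts three non-negative integers (counts for pairs ij, ik, jk).
#' @return entropy in nats.
#' @export
response_distribution_entropy <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stopf("`counts` must be three non-negative integers")
  tot <- sum(counts)
  if (tot < 1) stopf("`counts` must sum to at least 1")
  entropy_nats(matrix(counts / tot, nrow = 1L))[1L]
}

#' Construct a triplet response set
#'
#' Container for triplets plus per-response hard choices and optional
#' per-triplet soft targets.  Responses are in long format: `triplet`
#' maps each response to a row of `triplets`.
#'
#' @param triplets n x 3 integer matrix of item indices (1-based).
#' @param choice integer/character pair code per response.
#' @param triplet integer index into `triplets` per response (defaults to
#'   1:n when there is one response per triplet).
#' @param participant optional participant id per response.
#' @param rt_seconds optional response time per response.
#' @param soft optional n x 3 matrix of per-triplet soft pair
#'   distributions (rows sum to 1).
#' @return object of class `triplet_responses`.
#' @export
triplet_responses <- function(triplets, choice = NULL, triplet = NULL,
                              participant = NULL, rt_seconds = NULL,
                              soft = NULL) {
  triplets <- as_triplet_matrix(triplets)
  n <- nrow(triplets)
  if (!is.null(choice)) {
    choice <- pair_code(choice)
    if (is.null(triplet)) {
      if (length(choice) != n)
        stopf("`triplet` mapping required when responses != triplets")
      triplet <- seq_len(n)
    }
    if (length(triplet) != length(choice))
      stopf("`triplet` and `choice` lengths differ")
    check_indices(as.integer(triplet), n, "response triplet")
  }
  if (!is.null(soft)) {
    soft <- check_matrix(soft, "soft")
    if (nrow(soft) != n || ncol(soft) != 3L)
      stopf("`soft` must be an n x 3 matrix matching `triplets`")
    if (any(abs(rowSums(soft) - 1) > 1e-6) || any(soft < 0))
      stopf("soft targets must be normalized probability rows")
  }
  structure(
    list(triplets = triplets, choice = choice,
         triplet = if (is.null(choice)) NULL else as.integer(triplet),
         participant = participant, rt_seconds = rt_seconds, soft = soft),
    class = "triplet_responses"
  )
}

#' @export
print.triplet_responses <- function(x, ...) {
  cat(sprintf(
    "<triplet_responses> %d triplets, %d responses%s%s\n",
    nrow(x$triplets), length(x$choice),
    if (!is.null(x$soft)) ", soft targets" else "",
    if (!is.null(x$rt_seconds)) ", RTs" else ""
  ))
  invisible(x)
}
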