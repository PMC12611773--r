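#' Affine transform into the human-aligned similarity space
#'
#' @param W p x p weight matrix.
#' @param b length-p bias vector.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(W, b = rep(0, ncol(W))) {
  W <- check_matrix(W, "W")
  if (nrow(W) != ncol(W)) stopf("`W` must be square")
  if (length(b) != ncol(W)) stopf("`b` length must match W")
  if (any(!is.finite(b))) stopf("`b` must be finite")
  structure(list(W = W, b = as.numeric(b), p = ncol(W)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> p = %d, ||W - (trW/p) I||_F = %.4g\n",
              x$p, sqrt(identity_deviation_sq(x$W))))
  invisible(x)
}

#' Apply an affine transform row-wise to an embedding matrix
#'
#' Maps each row x to `W x + b`.
#'
#' @param transform `affine_transform`.
#' @param X items x p embedding matrix.
#' @return transformed items x p matrix.
#' @export
apply_transform <- function(transform, X) {
  stopifnot(inherits(transform, "affine_transform"))
  X <- check_matrix(X, "X")
  if (ncol(X) != transform$p)
    stopf("`X` has %d columns but transform expects %d", ncol(X), transform$p)
  sweep(X %*% t(transform$W), 2L, transform$b, `+`)
}

#' Hard-alignment loss (negative log-likelihood of discrete choices)
#'
#' \eqn{-(1/n) \sum_s \log q(\mathrm{chosen\ pair}_s)} with q the softmax
#' (temperature 1) of the triplet's transformed pairwise similarities.
#'
#' @param sims n x 3 matrix of per-triplet similarities (ij, ik, jk).
#' @param choices pair code per triplet (1/2/3 or "ij"/"ik"/"jk").
#' @return non-negative mean negative log-likelihood.
#' @export
hard_align_loss <- function(sims, choices) {
  if (is.null(dim(sims))) sims <- matrix(sims, nrow = 1L, ncol = 3L)
  if (any(!is.finite(sims))) stopf("similarities must be finite")
  ch <- pair_code(choices)
  if (length(ch) != nrow(sims)) stopf("choices and sims lengths differ")
  q <- softmax3(sims)
  -mean(log(q[cbind(seq_len(nrow(sims)), ch)]))
}

#' Soft-alignment loss (mean KL from soft targets to model softmax)
#'
#' \eqn{(1/n) \sum_s [\sum p^* \log p^* - p^* \log q_s]}, i.e. the mean
#' Kullback-Leibler divergence KL(p* || q) with q the softmax (temperature
#' `temperature`) of the triplet's similarities.  Zero target components
#' contribute 0 to the entropy term.  Reduces exactly to
#' [hard_align_loss()] when every target is one-hot.
#'
#' @param sims n x 3 similarity matrix.
#' @param soft_targets n x 3 matrix of normalized target distributions.
#' @param temperature softmax temperature for q (default 1).
#' @return non-negative mean KL divergence.
#' @export
soft_align_loss <- function(sims, soft_targets, temperature = 1) {
  if (is.null(dim(sims))) sims <- matrix(sims, nrow = 1L, ncol = 3L)
  if (is.null(dim(soft_targets)))
    soft_targets <- matrix(soft_targets, nrow = 1L, ncol = 3L)
  if (nrow(sims) != nrow(soft_targets)) stopf("row counts differ")
  if (any(abs(rowSums(soft_targets) - 1) > 1e-6) || any(soft_targets < 0))
    stopf("soft targets must be normalized probability rows")
  q <- softmax3(sims, temperature)
  neg_h <- rowSums(ifelse(soft_targets > 0,
                          soft_targets * log(soft_targets), 0))
  ce <- -rowSums(soft_targets * log(pmax(q, 1e-300)))
  mean(neg_h + ce)
}

identity_deviation_sq <- function(W) {
  mu <- mean(diag(W))
  D <- W - diag(mu, nrow(W))
  sum(D * D)
}

#' Scaled-identity regularizer for the alignment transform
#'
#' \eqn{\lambda \| W - (\mathrm{tr} W / p) I \|_F^2}: penalizes deviation
#' of W from the nearest scaled identity, preserving nearest-neighbour
#' structure of the pretrained space.  Its null space is exactly the
#' scaled identities, and it is invariant to adding `c I` to W.
#'
#' @param W square weight matrix.
#' @param lambda_reg non-negative regularization weight.
#' @return non-negative penalty value.
#' @export
transform_regularizer <- function(W, lambda_reg = 1) {
  W <- check_matrix(W, "W")
  if (nrow(W) != ncol(W)) stopf("`W` must be square")
  check_scalar(lambda_reg, "lambda_reg", lower = 0)
  lambda_reg * identity_deviation_sq(W)
}

#' Fit the human-aligned affine transform by uncertainty distillation
#'
#' Minimizes `soft_align_loss(transformed sims, soft targets) +
#' transform_regularizer(W, lambda)` over (W, b) with Adam on seeded
#' minibatches of triplets.  W starts at the identity and b at zero, so
#' the penalty is initially zero and the pretrained similarity structure
#' is the starting point.
#'
#' @param teacher_X items x p teacher embedding matrix.
#' @param responses `triplet_responses` carrying soft targets (from
#'   [mc_triplet_probabilities()] or [pseudolabel()]).
#' @param lambda_reg regularization weight (default 0.01).
#' @param learning_rate Adam step size (default 0.01).
#' @param epochs training epochs (default 80).
#' @param batch_size triplets per minibatch (default 256).
#' @param seed integer seed.
#' @return `affine_transform`; attribute `history` logs the per-epoch
#'   objective (never increasing beyond optimizer tolerance).
#' @export
fit_transform <- function(teacher_X, responses, lambda_reg = 0.01,
                          learning_rate = 0.01, epochs = 80L,
                          batch_size = 256L, seed = 1L) {
  X <- check_matrix(teacher_X, "teacher_X")
  stopifnot(inherits(responses, "triplet_responses"))
  if (is.null(responses$soft))
    stopf("`responses` must carry soft targets for uncertainty distillation")
  check_scalar(lambda_reg, "lambda_reg", lower = 0)
  epochs <- check_count(epochs, "epochs")
  p <- ncol(X)
  trip <- responses$triplets
  P <- responses$soft
  n <- nrow(trip)

  params <- list(W = diag(p), b = rep(0, p))
  state <- adam_init(params)

  objective <- function(params) {
    XT <- sweep(X %*% t(params$W), 2L, params$b, `+`)
    s <- pair_similarities(XT, trip)
    soft_align_loss(s, P) + lambda_reg * identity_deviation_sq(params$W)
  }

  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    batches <- batch_indices(n, batch_size, derive_seed(seed, ep))
    for (rows in batches) {
      B <- length(rows)
      XT <- sweep(X %*% t(params$W), 2L, params$b, `+`)
      ti <- trip[rows, 1L]; tj <- trip[rows, 2L]; tk <- trip[rows, 3L]
      Xi <- XT[ti, , drop = FALSE]
      Xj <- XT[tj, , drop = FALSE]
      Xk <- XT[tk, , drop = FALSE]
      s <- cbind(rowSums(Xi * Xj), rowSums(Xi * Xk), rowSums(Xj * Xk))
      g <- (softmax3(s) - P[rows, , drop = FALSE]) / B
      Gi <- g[, 1L] * Xj + g[, 2L] * Xk
      Gj <- g[, 1L] * Xi + g[, 3L] * Xk
      Gk <- g[, 2L] * Xi + g[, 3L] * Xj
      Gx <- rbind(Gi, Gj, Gk)
      Xraw <- X[c(ti, tj, tk), , drop = FALSE]
      mu <- mean(diag(params$W))
      gW <- t(Gx) %*% Xraw +
        2 * lambda_reg * (params$W - diag(mu, p))
      gb <- colSums(Gx)
      upd <- adam_step(params, list(W = gW, b = gb), state, lr = learning_rate)
      params <- upd$params
      state <- upd$state
    }
    history[ep] <- objective(params)
  }
  out <- affine_transform(params$W, params$b)
  attr(out, "history") <- history
  attr(out, "config") <- list(lambda_reg = lambda_reg, epochs = epochs,
                              learning_rate = learning_rate,
                              batch_size = batch_size,
                              seed = as.integer(seed),
                              final_loss = history[epochs])
  out
}
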