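#' Variational per-item concept embedding
#'
#' Mean-field Gaussian embedding: each item has a mean vector (row of
#' `mu`) and a strictly positive standard-deviation vector (row of
#' `sigma`).  Sampling uses the reparameterization trick
#' `Y = mu + sigma * eps` with standard-normal `eps`, so a fitted model
#' yields a posterior distribution over triplet choice probabilities that
#' captures rater disagreement, not just the modal choice.
#'
#' @param mu items x d mean matrix.
#' @param sigma items x d positive standard-deviation matrix.
#' @return object of class `variational_embedding`.
#' @export
variational_embedding <- function(mu, sigma) {
  mu <- check_matrix(mu, "mu")
  sigma <- check_matrix(sigma, "sigma")
  if (!all(dim(mu) == dim(sigma))) stopf("`mu` and `sigma` shapes differ")
  if (any(sigma <= 0)) stopf("`sigma` must be strictly positive")
  structure(list(mu = mu, sigma = sigma, d = ncol(mu)),
            class = "variational_embedding")
}

#' @export
print.variational_embedding <- function(x, ...) {
  cat(sprintf("<variational_embedding> %d items, d = %d, mean sigma %.3g\n",
              nrow(x$mu), x$d, mean(x$sigma)))
  invisible(x)
}

#' Draw one reparameterized embedding sample
#'
#' @param ve `variational_embedding`.
#' @param seed integer seed; deterministic given the seed.
#' @return items x d matrix `mu + sigma * eps`, `eps` elementwise N(0,1).
#' @export
sample_embedding <- function(ve, seed = 1L) {
  stopifnot(inherits(ve, "variational_embedding"))
  if (any(ve$sigma <= 0)) stopf("invalid state: non-positive sigma")
  eps <- withr::with_seed(seed, matrix(stats::rnorm(length(ve$mu)),
                                       nrow(ve$mu), ncol(ve$mu)))
  ve$mu + ve$sigma * eps
}

#' Monte-Carlo triplet choice probabilities under the variational posterior
#'
#' Averages the softmax (temperature 1) choice probabilities of the
#' triplet's pairwise dot products over `R` reparameterized embedding
#' samples: \deqn{\hat p = (1/R) \sum_r \sigma(S(Y^{(r)}), 1).}
#'
#' @param ve `variational_embedding`.
#' @param triplets single triplet (length-3 vector) or n x 3 matrix.
#' @param n_samples number of Monte-Carlo samples R (default 50).
#' @param seed integer seed.
#' @return choice probability vector (or n x 3 matrix) over pairs
#'   (ij, ik, jk); rows sum to 1.
#' @export
mc_triplet_probabilities <- function(ve, triplets, n_samples = 50L,
                                     seed = 1L) {
  stopifnot(inherits(ve, "variational_embedding"))
  R <- check_count(n_samples, "n_samples")
  single <- is.null(dim(triplets))
  t <- as_triplet_matrix(triplets)
  check_indices(t, nrow(ve$mu))
  acc <- matrix(0, nrow(t), 3L)
  for (r in seq_len(R)) {
    Y <- sample_embedding(ve, seed = derive_seed(seed, r))
    s <- pair_similarities(Y, t)
    if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
    acc <- acc + softmax3(s)
  }
  p <- acc / R
  colnames(p) <- paste0("p_", PAIR_CODES)
  if (single) p[1L, ] else p
}

#' Fit the variational uncertainty embedding to hard triplet choices
#'
#' Maximizes the expected log-likelihood of the observed pair choices
#' under reparameterized samples (one fresh sample per minibatch step),
#' with a standard-normal Kullback-Leibler regularizer on the mean-field
#' posterior.  Sigma is parameterized through a softplus link so the
#' optimization is unconstrained; optimization is Adam with seeded
#' minibatch shuffling and early stopping on held-out negative
#' log-likelihood (20% split).
#'
#' @param responses `triplet_responses` with hard choices.
#' @param d latent dimensionality (>= 1).
#' @param epochs maximum epochs (default 150).
#' @param learning_rate Adam step size (default 0.05).
#' @param batch_size minibatch size (default 128).
#' @param prior_weight weight of the KL(q || N(0,1)) regularizer, applied
#'   per response (default 1e-3).
#' @param holdout_frac held-out fraction for early stopping (default 0.2).
#' @param patience epochs without held-out improvement before stopping.
#' @param seed integer seed.
#' @return fitted `variational_embedding`; attribute `history` carries
#'   per-epoch training/held-out NLL.
#' @export
fit_uncertainty_model <- function(responses, d, epochs = 150L,
                                  learning_rate = 0.05, batch_size = 128L,
                                  prior_weight = 1e-3, holdout_frac = 0.2,
                                  patience = 20L, seed = 1L) {
  stopifnot(inherits(responses, "triplet_responses"))
  if (is.null(responses$choice) || length(responses$choice) == 0L)
    stopf("`responses` must contain at least one hard choice")
  d <- check_count(d, "d")
  epochs <- check_count(epochs, "epochs")
  m <- max(responses$triplets)
  n <- length(responses$choice)

  trip <- responses$triplets[responses$triplet, , drop = FALSE]
  ch <- responses$choice

  idx_all <- withr::with_seed(derive_seed(seed, 1L), sample.int(n))
  n_hold <- if (n >= 10L) floor(holdout_frac * n) else 0L
  hold <- idx_all[seq_len(n_hold)]
  train <- if (n_hold > 0L) idx_all[-seq_len(n_hold)] else idx_all

  params <- withr::with_seed(derive_seed(seed, 2L), list(
    mu = matrix(stats::rnorm(m * d, sd = 0.1), m, d),
    rho = matrix(-2, m, d)          # softplus(-2) ~ 0.127 initial sigma
  ))
  state <- adam_init(params)
  softplus <- function(x) log1p(exp(x))

  nll_of <- function(params, rows) {
    ve <- variational_embedding(params$mu, softplus(params$rho))
    p <- mc_triplet_probabilities(ve, trip[rows, , drop = FALSE],
                                  n_samples = 10L,
                                  seed = derive_seed(seed, 999L))
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    -mean(log(pmax(p[cbind(seq_along(rows), ch[rows])], 1e-12)))
  }

  history <- data.frame(epoch = integer(), train_nll = numeric(),
                        holdout_nll = numeric())
  best <- list(params = params, nll = Inf, epoch = 0L)
  for (ep in seq_len(epochs)) {
    batches <- batch_indices(length(train), batch_size,
                             derive_seed(seed, 100L + ep))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      rows <- train[batches[[bi]]]
      B <- length(rows)
      sigma <- softplus(params$rho)
      eps <- withr::with_seed(derive_seed(seed, 10000L + ep * 131L + bi),
                              matrix(stats::rnorm(m * d), m, d))
      Y <- params$mu + sigma * eps
      ti <- trip[rows, 1L]; tj <- trip[rows, 2L]; tk <- trip[rows, 3L]
      Yi <- Y[ti, , drop = FALSE]
      Yj <- Y[tj, , drop = FALSE]
      Yk <- Y[tk, , drop = FALSE]
      s <- cbind(rowSums(Yi * Yj), rowSums(Yi * Yk), rowSums(Yj * Yk))
      q <- softmax3(s)
      onehot <- matrix(0, B, 3L)
      onehot[cbind(seq_len(B), ch[rows])] <- 1
      g <- (q - onehot) / B                      # d(mean NLL)/d s
      GYi <- g[, 1L] * Yj + g[, 2L] * Yk
      GYj <- g[, 1L] * Yi + g[, 3L] * Yk
      GYk <- g[, 2L] * Yi + g[, 3L] * Yj
      GY <- matrix(0, m, d)
      for (col in seq_len(d)) {
        GY[, col] <- GY[, col] +
          unname(tapply(c(GYi[, col], GYj[, col], GYk[, col]),
                        factor(c(ti, tj, tk), levels = seq_len(m)),
                        sum, default = 0))
      }
      GY[is.na(GY)] <- 0
      ## KL(N(mu, sigma^2) || N(0, 1)) gradient, weighted per response
      w <- prior_weight / n
      gmu <- GY + w * params$mu
      dsig <- GY * eps + w * (sigma - 1 / sigma)
      grho <- dsig * stats::plogis(params$rho)   # softplus'(rho)
      upd <- adam_step(params, list(mu = gmu, rho = grho), state,
                       lr = learning_rate)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + (-mean(log(pmax(rowSums(q * onehot), 1e-12))))
    }
    ep_loss <- ep_loss / length(batches)
    hn <- if (n_hold > 0L) nll_of(params, hold) else ep_loss
    history <- rbind(history, data.frame(epoch = ep, train_nll = ep_loss,
                                         holdout_nll = hn))
    if (hn < best$nll - 1e-6) best <- list(params = params, nll = hn, epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  ve <- variational_embedding(best$params$mu, softplus(best$params$rho))
  attr(ve, "history") <- history
  attr(ve, "config") <- list(d = d, epochs = epochs, seed = as.integer(seed),
                             learning_rate = learning_rate,
                             prior_weight = prior_weight,
                             best_epoch = best$epoch)
  ve
}
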