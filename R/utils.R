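#' @keywords internal
"_PACKAGE"

## Pair order convention used everywhere: 1 = (i,j), 2 = (i,k), 3 = (j,k).
## Ties in argmax are broken in this fixed order.
PAIR_CODES <- c("ij", "ik", "jk")

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower) {
    if (x <= lower) stopf("`%s` must be > %g", name, lower)
  } else if (x < lower) stopf("`%s` must be >= %g", name, lower)
  if (x > upper) stopf("`%s` must be <= %g", name, upper)
  as.numeric(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix", name)
  if (!all(is.finite(x)))
    stopf("`%s` contains non-finite entries", name)
  x
}

check_indices <- function(idx, n_items, name = "triplet") {
  if (any(idx < 1L) || any(idx > n_items))
    stopf("%s index out of range [1, %d]", name, n_items)
  invisible(idx)
}

## Triplet lists are stored as n x 3 integer matrices (1-based item rows).
as_triplet_matrix <- function(t) {
  if (is.null(dim(t))) t <- matrix(as.integer(t), nrow = 1L)
  if (ncol(t) != 3L) stopf("triplets must have three columns (i, j, k)")
  storage.mode(t) <- "integer"
  if (any(t[, 1L] == t[, 2L] | t[, 1L] == t[, 3L] | t[, 2L] == t[, 3L]))
    stopf("triplet items must be pairwise distinct")
  colnames(t) <- c("i", "j", "k")
  t
}

## Numerically safe softmax over the rows of a 3-column score matrix.
softmax3 <- function(s, temperature = 1) {
  s <- s / temperature
  m <- do.call(pmax, as.data.frame(s))
  e <- exp(s - m)
  e / rowSums(e)
}

## Row-wise argmax over 3 columns with fixed-order tie-break ij < ik < jk.
argmax3 <- function(s) {
  max.col(s, ties.method = "first")
}

## Deterministic derived seed for substream `k` of a base seed; stays < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1299721 * as.double(k)) %% 2147483629)
}

## Shannon entropy (nats) of rows of a probability matrix; 0 log 0 := 0.
entropy_nats <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  lp <- ifelse(p > 0, log(p), 0)
  -rowSums(p * lp)
}

## ---- Adam: a small first-order optimizer over named lists of arrays ----

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Minibatch index generator: seeded shuffle, then contiguous batches.
batch_indices <- function(n, batch_size, seed) {
  ord <- withr::with_seed(seed, sample.int(n))
  split(ord, ceiling(seq_along(ord) / batch_size))
}
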