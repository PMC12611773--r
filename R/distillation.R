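#' Student encoder (desk-scale differentiable maps)
#'
#' Two built-in encoder families over item feature vectors:
#' \describe{
#'   \item{linear}{`z = A f + c`;}
#'   \item{mlp}{one hidden tanh layer, `z = W2 tanh(W1 f + b1) + b2`.}
#' }
#' The constructor snapshots the initial parameters, which the
#' weight-decay-to-initialization penalty and post-hoc audits refer to.
#'
#' @param type "linear" or "mlp".
#' @param in_dim feature dimensionality.
#' @param out_dim representation dimensionality.
#' @param hidden hidden width for "mlp" (default 32).
#' @param init_scale standard deviation of the random initialization.
#' @param seed integer seed.
#' @return object of class `student_encoder` with `params` and
#'   `init_params`.
#' @export
student_encoder <- function(type = c("linear", "mlp"), in_dim, out_dim,
                            hidden = 32L, init_scale = 0.1, seed = 1L) {
  type <- match.arg(type)
  in_dim <- check_count(in_dim, "in_dim")
  out_dim <- check_count(out_dim, "out_dim")
  params <- withr::with_seed(seed, {
    if (type == "linear") {
      list(A = matrix(stats::rnorm(out_dim * in_dim, sd = init_scale),
                      out_dim, in_dim),
           c = rep(0, out_dim))
    } else {
      hidden <- check_count(hidden, "hidden")
      list(W1 = matrix(stats::rnorm(hidden * in_dim, sd = init_scale),
                       hidden, in_dim),
           b1 = rep(0, hidden),
           W2 = matrix(stats::rnorm(out_dim * hidden, sd = init_scale),
                       out_dim, hidden),
           b2 = rep(0, out_dim))
    }
  })
  structure(list(type = type, params = params, init_params = params),
            class = "student_encoder")
}

#' @export
print.student_encoder <- function(x, ...) {
  cat(sprintf("<student_encoder> type = %s, %d parameters\n", x$type,
              sum(vapply(x$params, length, 1L))))
  invisible(x)
}

#' Encode item features with a student encoder
#'
#' @param student `student_encoder`.
#' @param features items x in_dim feature matrix.
#' @return items x out_dim representation matrix.
#' @export
encode <- function(student, features) {
  stopifnot(inherits(student, "student_encoder"))
  F <- check_matrix(features, "features")
  p <- student$params
  if (student$type == "linear") {
    sweep(F %*% t(p$A), 2L, p$c, `+`)
  } else {
    H <- tanh(sweep(F %*% t(p$W1), 2L, p$b1, `+`))
    sweep(H %*% t(p$W2), 2L, p$b2, `+`)
  }
}

#' Dual-temperature distillation loss over triplet choice distributions
#'
#' Batch mean of KL( softmax(S_teacher, tau_teacher) ||
#' softmax(S_student, tau_student) ) over the three pairs of each
#' triplet.  Non-negative; zero iff the two distributions coincide on
#' every triplet.
#'
#' @param teacher_soft n x 3 matrix of teacher pair distributions
#'   (already at the teacher temperature).
#' @param student_sims n x 3 matrix of student pairwise similarities.
#' @param tau_student student softmax temperature (> 0).  Default 100,
#'   the full-scale grid-searched value; desk-scale similarity magnitudes usually call for 1.
#' @return non-negative mean KL divergence.
#' @export
distill_kl_loss <- function(teacher_soft, student_sims, tau_student = 100) {
  soft_align_loss(student_sims, teacher_soft, temperature = tau_student)
}

#' Weight decay to initialization
#'
#' \eqn{\lambda \|\theta_0 - \theta\|_2^2} summed over all parameter
#' arrays: penalizes drift of the fine-tuned parameters from their
#' pre-fine-tuning snapshot.
#'
#' @param params,init_params named lists of numeric arrays with matching
#'   shapes.
#' @param lambda_wd non-negative weight.
#' @return penalty value.
#' @export
weight_decay_to_init <- function(params, init_params, lambda_wd = 1) {
  check_scalar(lambda_wd, "lambda_wd", lower = 0)
  if (!identical(lapply(params, dim), lapply(init_params, dim)) ||
      !identical(lapply(params, length), lapply(init_params, length)))
    stopf("parameter shapes do not match the initialization snapshot")
  lambda_wd * sum(vapply(names(params), function(nm) {
    sum((params[[nm]] - init_params[[nm]])^2)
  }, numeric(1)))
}

#' Distil teacher triplet similarity structure into a student encoder
#'
#' Minimizes `distill_kl_loss + weight_decay_to_init` over the student
#' parameters with Adam on seeded minibatches of triplets.  Teacher soft
#' labels are precomputed and frozen (rows of `data$soft`); the student
#' side re-encodes the triplet items each step so gradients flow through
#' the encoder.
#'
#' @param student `student_encoder` (its `init_params` anchor the decay).
#' @param data `triplet_responses` with soft targets ([pseudolabel()]).
#' @param features items x in_dim feature matrix covering every item
#'   referenced by `data$triplets`.
#' @param tau_student student temperature (default 100, the full-scale value; desk-scale runs typically use 1).
#' @param lambda_wd weight-decay-to-initialization weight (default 0).
#' @param learning_rate Adam step size (default 0.01).
#' @param epochs training epochs (default 50).
#' @param batch_size triplets per minibatch (default 256).
#' @param seed integer seed.
#' @return fine-tuned `student_encoder`; attribute `history` logs the
#'   per-epoch training objective.
#' @export
distill <- function(student, data, features, tau_student = 100,
                    lambda_wd = 0, learning_rate = 0.01, epochs = 50L,
                    batch_size = 256L, seed = 1L) {
  stopifnot(inherits(student, "student_encoder"),
            inherits(data, "triplet_responses"))
  if (is.null(data$soft)) stopf("`data` must carry teacher soft labels")
  F <- check_matrix(features, "features")
  if (max(data$triplets) > nrow(F))
    stopf("items in `data` missing from `features`")
  check_scalar(lambda_wd, "lambda_wd", lower = 0)
  epochs <- check_count(epochs, "epochs")
  trip <- data$triplets
  P <- data$soft
  n <- nrow(trip)
  params <- student$params
  init <- student$init_params
  state <- adam_init(params)

  forward <- function(params) {
    if (student$type == "linear") {
      list(Z = sweep(F %*% t(params$A), 2L, params$c, `+`))
    } else {
      H <- tanh(sweep(F %*% t(params$W1), 2L, params$b1, `+`))
      list(Z = sweep(H %*% t(params$W2), 2L, params$b2, `+`), H = H)
    }
  }

  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    batches <- batch_indices(n, batch_size, derive_seed(seed, ep))
    for (rows in batches) {
      B <- length(rows)
      fw <- forward(params)
      Z <- fw$Z
      ti <- trip[rows, 1L]; tj <- trip[rows, 2L]; tk <- trip[rows, 3L]
      Zi <- Z[ti, , drop = FALSE]
      Zj <- Z[tj, , drop = FALSE]
      Zk <- Z[tk, , drop = FALSE]
      s <- cbind(rowSums(Zi * Zj), rowSums(Zi * Zk), rowSums(Zj * Zk))
      ## d(mean KL)/d s: (q - p)/(B * tau)
      g <- (softmax3(s, tau_student) - P[rows, , drop = FALSE]) /
        (B * tau_student)
      Gi <- g[, 1L] * Zj + g[, 2L] * Zk
      Gj <- g[, 1L] * Zi + g[, 3L] * Zk
      Gk <- g[, 2L] * Zi + g[, 3L] * Zj
      GZ <- matrix(0, nrow(F), ncol(Z))
      items <- c(ti, tj, tk)
      Gall <- rbind(Gi, Gj, Gk)
      for (col in seq_len(ncol(Z))) {
        add <- tapply(Gall[, col], factor(items, levels = seq_len(nrow(F))),
                      sum, default = 0)
        add[is.na(add)] <- 0
        GZ[, col] <- GZ[, col] + unname(add)
      }
      grads <- if (student$type == "linear") {
        list(A = t(GZ) %*% F + 2 * lambda_wd * (params$A - init$A),
             c = colSums(GZ) + 2 * lambda_wd * (params$c - init$c))
      } else {
        GH <- (GZ %*% params$W2) * (1 - fw$H^2)
        list(W1 = t(GH) %*% F + 2 * lambda_wd * (params$W1 - init$W1),
             b1 = colSums(GH) + 2 * lambda_wd * (params$b1 - init$b1),
             W2 = t(GZ) %*% fw$H + 2 * lambda_wd * (params$W2 - init$W2),
             b2 = colSums(GZ) + 2 * lambda_wd * (params$b2 - init$b2))
      }
      upd <- adam_step(params, grads, state, lr = learning_rate)
      params <- upd$params
      state <- upd$state
    }
    Zfull <- forward(params)$Z
    history[ep] <- distill_kl_loss(P, pair_similarities(Zfull, trip),
                                   tau_student) +
      weight_decay_to_init(params, init, lambda_wd)
  }
  out <- student
  out$params <- params
  attr(out, "history") <- history
  attr(out, "config") <- list(tau_student = tau_student,
                              lambda_wd = lambda_wd, epochs = epochs,
                              learning_rate = learning_rate,
                              batch_size = batch_size,
                              seed = as.integer(seed),
                              final_loss = history[epochs])
  out
}
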