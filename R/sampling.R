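#' Sample triplets uniformly at random
#'
#' Each triplet is three distinct items drawn uniformly without
#' replacement; triplets are i.i.d. (duplicates across triplets allowed).
#'
#' @param n_items number of items (>= 3).
#' @param n number of triplets.
#' @param seed integer seed.
#' @return n x 3 integer matrix of 1-based item indices.
#' @export
sample_random_triplets <- function(n_items, n, seed = 1L) {
  n_items <- check_count(n_items, "n_items", min = 3L)
  n <- check_count(n, "n")
  withr::with_seed(seed, {
    out <- matrix(0L, n, 3L)
    for (s in seq_len(n)) out[s, ] <- sample.int(n_items, 3L)
    as_triplet_matrix(out)
  })
}

#' Sample class-boundary triplets (two same-class, one different)
#'
#' Picks a class with at least two members uniformly at random, draws two
#' of its items without replacement, then one item from a different
#' class uniformly.  The same-class pair is stored as (i, j) with the
#' odd item in position k.
#'
#' @param labels class label per item (any atomic vector).
#' @param n number of triplets.
#' @param seed integer seed.
#' @return n x 3 integer matrix; columns i, j share a label, k differs.
#' @export
sample_class_boundary_triplets <- function(labels, n, seed = 1L) {
  n <- check_count(n, "n")
  labels <- as.vector(labels)
  by_class <- split(seq_along(labels), labels)
  big <- by_class[vapply(by_class, length, 1L) >= 2L]
  if (length(big) < 1L || length(by_class) < 2L)
    stopf("need >= 2 classes with at least one class of >= 2 items")
  withr::with_seed(seed, {
    out <- matrix(0L, n, 3L)
    for (s in seq_len(n)) {
      cls <- big[[sample.int(length(big), 1L)]]
      pair <- cls[sample.int(length(cls), 2L)]
      other <- seq_along(labels)[labels != labels[pair[1L]]]
      out[s, ] <- c(pair, other[sample.int(length(other), 1L)])
    }
    as_triplet_matrix(out)
  })
}

#' k-means clustering of encoded representations
#'
#' Runs `stats::kmeans` with `n_restarts` seeded restarts and keeps the
#' best (lowest inertia) solution.
#'
#' @param Z items x p representation matrix.
#' @param c number of clusters (2 <= c <= items).
#' @param seed integer seed.
#' @param n_restarts seeded restarts (default 5).
#' @return list with `labels` (cluster id per item, dense in 1..c),
#'   `n_clusters` and `inertia` (total within-cluster sum of squares).
#' @export
cluster_representations <- function(Z, c, seed = 1L, n_restarts = 5L) {
  Z <- check_matrix(Z, "Z")
  c <- check_count(c, "c", min = 1L)
  if (c > nrow(Z)) stopf("`c` (%d) exceeds the number of items (%d)", c, nrow(Z))
  if (c == nrow(Z))   # singleton clusters; base kmeans rejects this edge case
    return(list(labels = seq_len(nrow(Z)), n_clusters = c, inertia = 0))
  km <- withr::with_seed(seed, {
    stats::kmeans(Z, centers = c, nstart = n_restarts, iter.max = 50L)
  })
  list(labels = as.integer(km$cluster), n_clusters = c,
       inertia = km$tot.withinss)
}

#' Select the number of clusters by the elbow (knee) criterion
#'
#' Computes k-means inertia for each candidate cluster count and returns
#' the interior candidate maximizing the discrete second difference of
#' the inertia curve (the knee).  If the maximal curvature is small
#' relative to the total inertia drop (`< curvature_tol`), the curve has
#' no usable knee; the smallest candidate is returned with attribute
#' `low_curvature = TRUE`.
#'
#' @param Z items x p representation matrix.
#' @param candidate_cs ascending integer vector of >= 3 candidates.
#' @param seed integer seed.
#' @param curvature_tol relative-curvature threshold (default 0.2).
#' @return selected cluster count; attributes `inertia` and
#'   `low_curvature`.
#' @export
select_k_elbow <- function(Z, candidate_cs, seed = 1L, curvature_tol = 0.2) {
  Z <- check_matrix(Z, "Z")
  if (length(candidate_cs) < 3L) stopf("need at least 3 candidate counts")
  if (is.unsorted(candidate_cs, strictly = TRUE))
    stopf("`candidate_cs` must be strictly ascending")
  inertia <- vapply(seq_along(candidate_cs), function(t) {
    cluster_representations(Z, candidate_cs[t], seed = derive_seed(seed, t))$inertia
  }, numeric(1))
  d2 <- inertia[-c(length(inertia) - 1L, length(inertia))] -
    2 * inertia[-c(1L, length(inertia))] +
    inertia[-c(1L, 2L)]
  drop_total <- max(inertia[1L] - inertia[length(inertia)],
                    .Machine$double.eps)
  low <- max(d2) / drop_total < curvature_tol
  k <- if (low) candidate_cs[1L] else candidate_cs[which.max(d2) + 1L]
  structure(k, inertia = stats::setNames(inertia, candidate_cs),
            low_curvature = low)
}

#' Sample cluster-boundary triplets
#'
#' Identical contract to [sample_class_boundary_triplets()] with k-means
#' cluster ids playing the role of class labels: two items from one
#' cluster, one from a different cluster.
#'
#' @param assign result of [cluster_representations()].
#' @param n number of triplets.
#' @param seed integer seed.
#' @return n x 3 integer matrix.
#' @export
sample_cluster_boundary_triplets <- function(assign, n, seed = 1L) {
  sample_class_boundary_triplets(assign$labels, n, seed = seed)
}

#' Sample abstraction-stratified triplets
#'
#' Stratified sampling over a two-level class map emulating a balanced
#' multi-level judgement design.  Superclasses are drawn uniformly (not
#' item-proportionally, so over-represented fine classes are not
#' over-sampled), then one subclass within each drawn superclass, then
#' items without replacement from that subclass:
#' \describe{
#'   \item{coarse}{three items from three distinct superclasses;}
#'   \item{fine}{three items from a single subclass;}
#'   \item{boundary}{two items from one subclass and one item from a
#'     subclass of a different superclass.}
#' }
#' Superclass draws are restricted to superclasses that can supply the
#' requested pattern.
#'
#' @param superclass_map superclass label per item.
#' @param subclass_map subclass label per item (nested in superclass).
#' @param level one of "coarse", "fine", "boundary".
#' @param n number of triplets.
#' @param seed integer seed.
#' @return n x 3 integer matrix.
#' @export
sample_levels_triplets <- function(superclass_map, subclass_map, level,
                                   n, seed = 1L) {
  n <- check_count(n, "n")
  level <- match.arg(level, c("coarse", "fine", "boundary"))
  if (length(superclass_map) != length(subclass_map))
    stopf("superclass and subclass maps must cover the same items")
  sub2super <- tapply(superclass_map, subclass_map,
                      function(s) length(unique(s)))
  if (any(sub2super > 1L))
    stopf("subclasses must nest within superclasses")

  by_sub <- split(seq_along(subclass_map), subclass_map)
  sub_super <- vapply(by_sub, function(ix) as.character(superclass_map[ix[1L]]),
                      character(1))
  supers <- unique(as.character(superclass_map))
  ## subclasses of each superclass with at least `need` items
  feasible_subs <- function(need) {
    ok <- vapply(by_sub, length, 1L) >= need
    split(names(by_sub)[ok], sub_super[ok])
  }
  draw_from_sub <- function(sub_name, need) {
    ix <- by_sub[[sub_name]]
    ix[sample.int(length(ix), need)]
  }

  withr::with_seed(seed, {
    out <- matrix(0L, n, 3L)
    if (level == "coarse") {
      fs <- feasible_subs(1L)
      if (length(fs) < 3L)
        stopf("coarse triplets need >= 3 superclasses with items")
      for (s in seq_len(n)) {
        sup <- sample(names(fs), 3L)
        out[s, ] <- vapply(sup, function(sp) {
          subs <- fs[[sp]]
          draw_from_sub(subs[sample.int(length(subs), 1L)], 1L)
        }, integer(1))
      }
    } else if (level == "fine") {
      fs <- feasible_subs(3L)
      if (length(fs) < 1L)
        stopf("fine triplets need a subclass with >= 3 items")
      for (s in seq_len(n)) {
        subs <- fs[[sample(names(fs), 1L)]]
        out[s, ] <- draw_from_sub(subs[sample.int(length(subs), 1L)], 3L)
      }
    } else {
      fs_pair <- feasible_subs(2L)
      fs_one <- feasible_subs(1L)
      if (length(fs_pair) < 1L || length(fs_one) < 2L)
        stopf("boundary triplets need a 2-item subclass and a second superclass")
      for (s in seq_len(n)) {
        sp_pair <- sample(names(fs_pair), 1L)
        other <- setdiff(names(fs_one), sp_pair)
        if (length(other) < 1L)
          stopf("boundary triplets need a second superclass with items")
        sp_odd <- other[sample.int(length(other), 1L)]
        subs_p <- fs_pair[[sp_pair]]
        subs_o <- fs_one[[sp_odd]]
        out[s, 1:2] <- draw_from_sub(subs_p[sample.int(length(subs_p), 1L)], 2L)
        out[s, 3L] <- draw_from_sub(subs_o[sample.int(length(subs_o), 1L)], 1L)
      }
    }
    as_triplet_matrix(out)
  })
}

#' Pseudo-label triplets with a transformed teacher space
#'
#' For each triplet, stores the softmax (at `temperature`) of the
#' transformed teacher dot-product similarities as the soft label and its
#' argmax pair (fixed-order tie-break) as the hard label.  Deterministic
#' in (teacher space, triplets, temperature).
#'
#' @param teacher_space items x p matrix of *already transformed* teacher
#'   embeddings (see [apply_transform()]).
#' @param triplets n x 3 integer matrix.
#' @param temperature softmax temperature (default 1, the teacher side of
#'   the distillation objective).
#' @return `triplet_responses` with hard choices and soft targets.
#' @export
pseudolabel <- function(teacher_space, triplets, temperature = 1) {
  teacher_space <- check_matrix(teacher_space, "teacher_space")
  triplets <- as_triplet_matrix(triplets)
  check_indices(triplets, nrow(teacher_space))
  s <- pair_similarities(teacher_space, triplets)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
  soft <- choice_probabilities(s, temperature)
  if (is.null(dim(soft))) soft <- matrix(soft, nrow = 1L)
  hard <- argmax3(soft)
  triplet_responses(triplets, choice = hard, soft = soft)
}
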