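## Tabular dialects: TSV with header rows, 0-based item indices on disk,
## 1-based inside R.  Matrices are headerless TSV at full precision.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a numeric matrix as headerless TSV
#'
#' Full-precision (17 significant digits) so a round trip reproduces the
#' values to better than 1e-12.  Both LF and CRLF line endings are
#' accepted on read.
#'
#' @param X numeric matrix.
#' @param path file path.
#' @return `read_matrix` returns a numeric matrix; `write_matrix` its
#'   path, invisibly.
#' @export
write_matrix <- function(X, path) {
  X <- check_matrix(X, "X")
  lines <- apply(X, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "numeric")
  m <- as.matrix(df)
  dimnames(m) <- NULL
  m
}

#' Write / read triplet tables
#'
#' Dialect: TSV with header `i  j  k  [chosen_pair]  [p_ij p_ik p_jk]`,
#' 0-based item indices, `chosen_pair` in {ij, ik, jk}.
#'
#' @param triplets n x 3 integer matrix (1-based in R).
#' @param path file path.
#' @param choice optional pair codes per triplet.
#' @param soft optional n x 3 soft-label matrix.
#' @return `read_triplets` returns a list with `triplets` and, when
#'   present, `choice` and `soft`.
#' @export
write_triplets <- function(triplets, path, choice = NULL, soft = NULL) {
  triplets <- as_triplet_matrix(triplets)
  df <- data.frame(i = triplets[, 1L] - 1L, j = triplets[, 2L] - 1L,
                   k = triplets[, 3L] - 1L)
  if (!is.null(choice)) df$chosen_pair <- PAIR_CODES[pair_code(choice)]
  if (!is.null(soft)) {
    df$p_ij <- fmt_num(soft[, 1L])
    df$p_ik <- fmt_num(soft[, 2L])
    df$p_jk <- fmt_num(soft[, 3L])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplets
#' @export
read_triplets <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("i", "j", "k")
  if (!all(need %in% names(df))) stopf("missing columns i, j, k in %s", path)
  t <- as.matrix(df[, need]) + 1L
  bad <- which(t[, 1L] == t[, 2L] | t[, 1L] == t[, 3L] | t[, 2L] == t[, 3L])
  if (length(bad) > 0L)
    stopf("duplicate item index within a triplet at line %d of %s",
          bad[1L] + 1L, path)
  out <- list(triplets = as_triplet_matrix(t))
  if ("chosen_pair" %in% names(df)) out$choice <- pair_code(df$chosen_pair)
  if (all(c("p_ij", "p_ik", "p_jk") %in% names(df)))
    out$soft <- as.matrix(df[, c("p_ij", "p_ik", "p_jk")])
  out
}

#' Write / read long-format response tables
#'
#' Dialect: TSV with header `participant_id  i  j  k  chosen_pair
#' rt_seconds`, 0-based indices.
#'
#' @param responses `triplet_responses` with hard choices.
#' @param path file path.
#' @return `read_responses` returns a `triplet_responses`.
#' @export
write_responses <- function(responses, path) {
  stopifnot(inherits(responses, "triplet_responses"))
  if (is.null(responses$choice)) stopf("no hard choices to write")
  t <- responses$triplets[responses$triplet, , drop = FALSE]
  df <- data.frame(
    participant_id = responses$participant %||% rep(1L, length(responses$choice)),
    i = t[, 1L] - 1L, j = t[, 2L] - 1L, k = t[, 3L] - 1L,
    chosen_pair = PAIR_CODES[responses$choice],
    rt_seconds = fmt_num(responses$rt_seconds %||%
                           rep(NA_real_, length(responses$choice)))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("participant_id", "i", "j", "k", "chosen_pair")
  if (!all(need %in% names(df)))
    stopf("missing columns in %s: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  tr <- as.matrix(df[, c("i", "j", "k")]) + 1L
  key <- paste(tr[, 1L], tr[, 2L], tr[, 3L])
  uniq <- !duplicated(key)
  trip_idx <- match(key, key[uniq])
  triplet_responses(
    triplets = tr[uniq, , drop = FALSE],
    choice = pair_code(df$chosen_pair),
    triplet = trip_idx,
    participant = df$participant_id,
    rt_seconds = if ("rt_seconds" %in% names(df))
      suppressWarnings(as.numeric(df$rt_seconds)) else NULL
  )
}

#' Write / read a hierarchy label table
#'
#' Dialect: TSV with header `item_id  subordinate  basic  superordinate`,
#' 0-based item ids.
#'
#' @param labels data.frame as in a `hierarchy_space`.
#' @param path file path.
#' @return `read_labels` returns the data.frame (1-based `item`).
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(item_id = labels$item - 1L,
                   subordinate = labels$subordinate,
                   basic = labels$basic,
                   superordinate = labels$superordinate)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  data.frame(item = df$item_id + 1L, subordinate = df$subordinate,
             basic = df$basic, superordinate = df$superordinate)
}

#' Write / read an affine transform (W + b + JSON sidecar)
#'
#' @param transform `affine_transform`.
#' @param prefix path prefix; writes `<prefix>_W.tsv`, `<prefix>_b.tsv`
#'   and `<prefix>.json`.
#' @return `read_transform` returns an `affine_transform`.
#' @export
write_transform <- function(transform, prefix) {
  stopifnot(inherits(transform, "affine_transform"))
  write_matrix(transform$W, paste0(prefix, "_W.tsv"))
  write_matrix(matrix(transform$b, nrow = 1L), paste0(prefix, "_b.tsv"))
  meta <- c(list(p = transform$p), attr(transform, "config"))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_transform
#' @export
read_transform <- function(prefix) {
  W <- read_matrix(paste0(prefix, "_W.tsv"))
  b <- as.numeric(read_matrix(paste0(prefix, "_b.tsv")))
  affine_transform(W, b)
}

#' Write / read a variational embedding (mu + sigma + JSON sidecar)
#'
#' @param ve `variational_embedding`.
#' @param prefix path prefix; writes `<prefix>_mu.tsv`,
#'   `<prefix>_sigma.tsv` and `<prefix>.json`.
#' @return `read_variational_embedding` returns a
#'   `variational_embedding`.
#' @export
write_variational_embedding <- function(ve, prefix) {
  stopifnot(inherits(ve, "variational_embedding"))
  write_matrix(ve$mu, paste0(prefix, "_mu.tsv"))
  write_matrix(ve$sigma, paste0(prefix, "_sigma.tsv"))
  meta <- c(list(d = ve$d), attr(ve, "config"))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_variational_embedding
#' @export
read_variational_embedding <- function(prefix) {
  variational_embedding(read_matrix(paste0(prefix, "_mu.tsv")),
                        read_matrix(paste0(prefix, "_sigma.tsv")))
}
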