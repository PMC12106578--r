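#' Common-neighbour structural scores
#'
#' The node feature behind CE-GCN is a single integer per node and age: the
#' row sum of the squared adjacency matrix, f_t(i) = (A_t^2 1)_i. Because
#' (A^2)_ii is the degree of node i and (A^2)_ij (i != j) counts the common
#' neighbours of i and j, the score combines a node's degree with the total
#' number of common neighbours it shares with every other node — a global
#' plus local summary of its structural position.
#'
#' `squared_adjacency()` returns the exact integer matrix product A %*% A and
#' validates its input contract (binary, symmetric, zero diagonal);
#' `structural_score()` reduces it to the per-node score vector.
#'
#' @param snapshot A single snapshot: a list with an `adjacency` element, or
#'   a binary symmetric matrix itself.
#' @return `squared_adjacency()`: an n x n integer matrix.
#'   `structural_score()`: an integer vector of length n.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
#' structural_score(squared_adjacency(a)) # path graph: c(2, 3, 2) minus ...
#' @export
squared_adjacency <- function(snapshot) {
  a <- if (is.list(snapshot)) snapshot$adjacency else snapshot
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (!all(a %in% c(0, 1))) {
    stop("adjacency must be binary", call. = FALSE)
  }
  if (!isTRUE(all.equal(a, t(a), check.attributes = FALSE))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(diag(a) != 0)) {
    stop("adjacency must have a zero diagonal", call. = FALSE)
  }
  storage.mode(a) <- "integer"
  a %*% a
}

#' @rdname squared_adjacency
#' @param squared An n x n matrix, typically from `squared_adjacency()`.
#' @export
structural_score <- function(squared) {
  stopifnot(is.matrix(squared), nrow(squared) == ncol(squared))
  as.integer(rowSums(squared))
}

#' Feature vocabulary for one-hot encoding of structural scores
#'
#' Each distinct score value observed across the training snapshots gets its
#' own feature dimension, plus one reserved out-of-vocabulary (OOV) slot for
#' values first seen at later ages. The vocabulary is built from training
#' ages only, so no information about future (validation/test) network
#' structure leaks into the feature space, and the feature dimension d stays
#' fixed across the whole sequence — required because the evolving GCN weight
#' shapes are shared through time.
#'
#' @param score_list A list of integer score vectors, one per training
#'   snapshot (see [structural_score()]).
#' @return An object of class `feature_vocabulary`: list with `values`
#'   (sorted distinct scores), `slot` (named integer map value -> dimension),
#'   `oov_slot`, and `d` (total dimension, `length(values) + 1`).
#' @export
build_vocabulary <- function(score_list) {
  stopifnot(length(score_list) >= 1)
  values <- sort(unique(as.integer(unlist(score_list))))
  d <- length(values) + 1L
  slot <- stats::setNames(seq_along(values), values)
  structure(list(values = values, slot = slot, oov_slot = d, d = d),
            class = "feature_vocabulary")
}

#' @export
print.feature_vocabulary <- function(x, ...) {
  cat("<feature_vocabulary> d =", x$d, "(", length(x$values),
      "observed score values + 1 OOV slot )\n")
  invisible(x)
}

#' One-hot encode structural scores
#'
#' Maps each node's score to a binary indicator row: a single 1 in the
#' vocabulary slot of the score, or in the OOV slot when the value was never
#' observed in training. Every row sums to exactly 1.
#'
#' @param scores Integer score vector (one per node).
#' @param vocab A [build_vocabulary()] result.
#' @return An n x d binary matrix F_t, the initial GCN embedding H_t(0).
#' @export
one_hot_encode <- function(scores, vocab) {
  n <- length(scores)
  slots <- vocab$slot[as.character(scores)]
  slots[is.na(slots)] <- vocab$oov_slot
  f <- matrix(0, n, vocab$d)
  f[cbind(seq_len(n), slots)] <- 1
  f
}

# inverse for in-vocabulary rows (used in tests and feature export)
decode_one_hot <- function(row, vocab) {
  slot <- which(row == 1)
  if (slot == vocab$oov_slot) return(NA_integer_)
  vocab$values[slot]
}

#' Compute one-hot feature matrices for a snapshot sequence
#'
#' Convenience wrapper: structural scores for every age, a vocabulary built
#' from the requested training ages only, and the per-age one-hot matrices.
#'
#' @param sequence A `snapshot_sequence`.
#' @param train_ages Ages whose score values define the vocabulary; defaults
#'   to all ages (use the training block of a [temporal_split()] to avoid
#'   temporal leakage when fitting models).
#' @return A list with `features` (list of n x d matrices, named by age),
#'   `scores` (list of integer vectors) and `vocab`.
#' @export
compute_features <- function(sequence, train_ages = sequence$ages) {
  scores <- lapply(sequence$adjacency,
                   function(a) structural_score(squared_adjacency(a)))
  vocab <- build_vocabulary(scores[as.character(train_ages)])
  features <- lapply(scores, one_hot_encode, vocab = vocab)
  list(features = features, scores = scores, vocab = vocab)
}

#' Export features or vocabulary to plain text
#'
#' `export_features()` writes one TSV per age with columns `node_id`,
#' `score`, `slot`; `write_vocabulary()`/`read_vocabulary()` round-trip the
#' vocabulary through JSON.
#'
#' @param feats A [compute_features()] result.
#' @param dir,path Output locations.
#' @export
export_features <- function(feats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (age_chr in names(feats$scores)) {
    sc <- feats$scores[[age_chr]]
    slots <- feats$vocab$slot[as.character(sc)]
    slots[is.na(slots)] <- feats$vocab$oov_slot
    readr::write_tsv(
      tibble::tibble(node_id = seq_along(sc), score = sc,
                     slot = unname(slots)),
      file.path(dir, paste0("features_age_", age_chr, ".tsv")),
      progress = FALSE
    )
  }
  invisible(dir)
}

#' @rdname export_features
#' @param vocab A `feature_vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(values = vocab$values, oov_slot = vocab$oov_slot, d = vocab$d),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname export_features
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_vocabulary(list(as.integer(x$values)))
}
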