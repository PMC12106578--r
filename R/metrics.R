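#' Ranking metrics: average precision and reciprocal rank
#'
#' `average_precision()` is the discrete area under the precision-recall
#' curve: for a ranked candidate list, AP = (1/R) * sum over the ranks r that
#' hold a relevant item of precision@r, with R the number of relevant items.
#' `reciprocal_rank()` is 1 / (rank of the first relevant item), and 0 when
#' no relevant item is retrieved. Both lie in [0, 1].
#'
#' @param ranked_relevance Logical (or 0/1) vector: relevance of the ranked
#'   candidates, best-scored first.
#' @return A scalar in [0, 1].
#' @examples
#' average_precision(c(1, 0, 1)) # (1/1 + 2/3) / 2
#' reciprocal_rank(c(0, 1, 0)) # 1/2
#' @export
average_precision <- function(ranked_relevance) {
  rel <- as.numeric(ranked_relevance)
  n_rel <- sum(rel)
  if (n_rel == 0) {
    stop("average_precision: relevant set is empty; exclude this query",
         call. = FALSE)
  }
  r <- seq_along(rel)
  sum((cumsum(rel) / r) * rel) / n_rel
}

#' @rdname average_precision
#' @export
reciprocal_rank <- function(ranked_relevance) {
  pos <- which(as.numeric(ranked_relevance) == 1)
  if (length(pos) == 0) return(0)
  1 / pos[1]
}

#' Aggregate ranking metrics over queries
#'
#' MAP is the arithmetic mean of per-query AP values; MRR the mean of
#' per-query reciprocal ranks (queries whose relevant set is never retrieved
#' contribute 0 to MRR).
#'
#' @param values Numeric vector of per-query AP (for MAP) or reciprocal
#'   ranks (for MRR).
#' @return A scalar in [0, 1].
#' @export
mean_average_precision <- function(values) {
  if (length(values) == 0) {
    stop("mean_average_precision: no valid queries", call. = FALSE)
  }
  mean(values)
}

#' @rdname mean_average_precision
#' @export
mean_reciprocal_rank <- function(values) {
  if (length(values) == 0) {
    stop("mean_reciprocal_rank: no queries", call. = FALSE)
  }
  mean(values)
}

all_node_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])
}

edge_pairs <- function(adjacency) {
  idx <- which(upper.tri(adjacency) & adjacency == 1, arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])
}

pair_key <- function(pairs, n) (pairs[, 1] - 1) * n + pairs[, 2]

#' Prediction targets for one age transition
#'
#' Splits all unordered non-self node pairs into positives and negatives for
#' predicting the graph at `age + 1` from history up to `age`. In
#' `"all_edges"` mode the positives are every edge of G_(age+1); in
#' `"new_edges"` mode only the edges of G_(age+1) absent from G_(age) (the
#' hidden relationships the model is meant to surface). Positives and
#' negatives partition the full pair set; the pairs already linked at `age`
#' are returned separately so new-edge training and evaluation can exclude
#' them from the candidate pool.
#'
#' @param sequence A `snapshot_sequence`.
#' @param age Age t; `age + 1` must also be in the sequence.
#' @param mode `"new_edges"` (default) or `"all_edges"`.
#' @return List with integer pair matrices `positives`, `negatives`,
#'   `existing` (edges at `age`), and `mode`.
#' @export
make_targets <- function(sequence, age, mode = c("new_edges", "all_edges")) {
  mode <- match.arg(mode)
  stopifnot((age + 1) %in% sequence$ages)
  n <- n_diseases(sequence$catalog)
  a_now <- sequence$adjacency[[as.character(age)]]
  a_next <- sequence$adjacency[[as.character(age + 1)]]
  pos_adj <- if (mode == "all_edges") a_next else (a_next == 1 & a_now == 0) + 0L
  positives <- edge_pairs(pos_adj)
  pairs <- all_node_pairs(n)
  is_pos <- pair_key(pairs, n) %in% pair_key(positives, n)
  list(positives = positives, negatives = pairs[!is_pos, , drop = FALSE],
       existing = edge_pairs(a_now), mode = mode)
}

# Symmetric logit matrix for all pairs at one age.
score_matrix <- function(embeddings, params, n) {
  pairs <- all_node_pairs(n)
  logits <- as.vector(ag_value(score_pairs(embeddings, pairs, params)))
  s <- matrix(NA_real_, n, n)
  s[pairs] <- logits
  s[pairs[, c(2, 1)]] <- logits
  s
}

# One ranking query per (transition, node with >= 1 relevant partner).
# Candidates: all partners != node, minus already-linked partners in
# new_edges mode. Ranking: descending score, ties by ascending partner id.
ranking_queries <- function(sequence, embeddings, t_values, mode, params) {
  out <- lapply(t_values, function(t) {
    s <- score_matrix(embeddings[[as.character(t)]], params,
                      n_diseases(sequence$catalog))
    queries_from_scores(sequence, t, mode, s)
  })
  dplyr::bind_rows(c(list(empty_queries()), out))
}

empty_queries <- function() {
  tibble::tibble(age = integer(), query_node = integer(),
                 n_candidates = integer(), n_relevant = integer(),
                 ap = numeric(), rr = numeric())
}

# Queries for a single transition given a full symmetric score matrix.
queries_from_scores <- function(sequence, t, mode, s) {
  n <- n_diseases(sequence$catalog)
  out <- list()
  {
    tg <- make_targets(sequence, t, mode)
    if (nrow(tg$positives) == 0) return(empty_queries())
    rel_sets <- lapply(seq_len(n), function(i) integer(0))
    for (r in seq_len(nrow(tg$positives))) {
      i <- tg$positives[r, 1]; j <- tg$positives[r, 2]
      rel_sets[[i]] <- c(rel_sets[[i]], j)
      rel_sets[[j]] <- c(rel_sets[[j]], i)
    }
    linked <- sequence$adjacency[[as.character(t)]]
    for (q in seq_len(n)) {
      relevant <- rel_sets[[q]]
      if (length(relevant) == 0) next
      candidates <- setdiff(seq_len(n), q)
      if (mode == "new_edges") {
        candidates <- candidates[linked[q, candidates] == 0]
      }
      ord <- candidates[order(-s[q, candidates], candidates)]
      rel_ranked <- ord %in% relevant
      out[[length(out) + 1]] <- tibble::tibble(
        age = t, query_node = q, n_candidates = length(candidates),
        n_relevant = length(relevant),
        ap = average_precision(rel_ranked),
        rr = reciprocal_rank(rel_ranked)
      )
    }
  }
  if (length(out) == 0) return(empty_queries())
  dplyr::bind_rows(out)
}

#' Evaluate a fitted model by exhaustive ranking
#'
#' For every transition whose target age falls in the requested split block,
#' and every query node with at least one relevant partner, all eligible
#' partner nodes are scored and ranked exhaustively (no candidate sampling:
#' at 14 nodes there are at most 13 partners per query). Per-query AP and
#' reciprocal rank are aggregated into MAP and MRR.
#'
#' @param fit A `cegcn_fit` from [fit_cegcn()] or [fit_static_gcn()].
#' @param sequence The `snapshot_sequence` to evaluate on (typically the one
#'   the model was fitted to).
#' @param block `"test"`, `"val"` or `"train"`: which split block's target
#'   ages to evaluate.
#' @param mode Target mode; defaults to the mode the model was fitted with.
#' @return An object of class `cegcn_metrics`: list with `queries` (tibble of
#'   per-query results), `map`, `mrr`, `mode`, `block`, `ages`.
#' @export
evaluate_model <- function(fit, sequence, block = c("test", "val", "train"),
                           mode = fit$mode) {
  block <- match.arg(block)
  block_ages <- switch(block, test = fit$split$test_ages,
                       val = fit$split$val_ages, train = fit$split$train_ages)
  t_values <- intersect(block_ages - 1, sequence$ages)
  t_values <- t_values[(t_values + 1) %in% block_ages]
  features <- features_with_vocab(sequence, fit$vocab)
  ages_fwd <- sequence$ages[sequence$ages <= max(t_values)]
  emb <- forward_sequence(sequence, features, fit$params, fit$config,
                          ages = ages_fwd)
  queries <- ranking_queries(sequence, emb, t_values, mode, fit$params)
  if (nrow(queries) == 0) {
    stop("evaluate_model: no query has a non-empty relevant set in the ",
         block, " block; the metric is undefined", call. = FALSE)
  }
  structure(
    list(queries = queries, map = mean_average_precision(queries$ap),
         mrr = mean_reciprocal_rank(queries$rr), mode = mode, block = block,
         ages = sort(unique(queries$age + 1))),
    class = "cegcn_metrics"
  )
}

#' @export
print.cegcn_metrics <- function(x, ...) {
  cat("<cegcn_metrics> ", x$block, " block, mode = ", x$mode, "\n", sep = "")
  cat(sprintf("  MAP = %.4f  MRR = %.4f  (%d queries over %d target ages)\n",
              x$map, x$mrr, nrow(x$queries), length(x$ages)))
  invisible(x)
}

#' Monte-Carlo MRR of a random ranking
#'
#' Reference distribution for null-calibration checks: for each query the
#' relevant items are placed uniformly at random among the candidates, and
#' the resulting MRR is recorded; repeated `n_draws` times.
#'
#' @param queries A tibble with columns `n_candidates` and `n_relevant`
#'   (e.g. the `queries` element of a [evaluate_model()] result).
#' @param n_draws Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return Numeric vector of `n_draws` MRR values.
#' @export
random_ranking_mrr <- function(queries, n_draws = 200, seed = 1) {
  withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      rr <- mapply(function(nc, nr) 1 / min(sample.int(nc, nr)),
                   queries$n_candidates, queries$n_relevant)
      mean(rr)
    }, numeric(1))
  })
}

#' Ranked future-comorbidity report
#'
#' Scores every unordered disease pair at the requested age with the fitted
#' model and returns the `k` highest-scoring pairs, flagged by whether the
#' pair is already an edge at that age. High-scoring unlinked pairs are the
#' model's predicted future comorbidities.
#'
#' @param fit A `cegcn_fit`.
#' @param sequence The `snapshot_sequence` to report on.
#' @param age Age at which to score.
#' @param k Number of pairs to return (truncated with a warning when larger
#'   than the number of pairs).
#' @return A tibble with columns `disease_i`, `disease_j`, `score`,
#'   `already_linked`, sorted by score descending (ties by node ids).
#' @export
top_pairs_report <- function(fit, sequence, age, k = 10) {
  stopifnot(age %in% sequence$ages)
  n <- n_diseases(sequence$catalog)
  pairs <- all_node_pairs(n)
  if (k > nrow(pairs)) {
    warning("k exceeds the number of pairs; truncated to ", nrow(pairs),
            call. = FALSE)
    k <- nrow(pairs)
  }
  features <- features_with_vocab(sequence, fit$vocab)
  ages_fwd <- sequence$ages[sequence$ages <= age]
  emb <- forward_sequence(sequence, features, fit$params, fit$config,
                          ages = ages_fwd)
  logits <- as.vector(ag_value(
    score_pairs(emb[[as.character(age)]], pairs, fit$params)))
  linked <- sequence$adjacency[[as.character(age)]][pairs] == 1
  tibble::tibble(
    disease_i = sequence$catalog$name[pairs[, 1]],
    disease_j = sequence$catalog$name[pairs[, 2]],
    node_i = pairs[, 1], node_j = pairs[, 2],
    score = logits, already_linked = linked
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$node_i, .data$node_j) |>
    dplyr::slice_head(n = k)
}

# features for an arbitrary sequence under a fixed (training) vocabulary
features_with_vocab <- function(sequence, vocab) {
  lapply(sequence$adjacency, function(a) {
    one_hot_encode(structural_score(squared_adjacency(a)), vocab)
  })
}
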