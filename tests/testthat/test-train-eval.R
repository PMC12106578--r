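# --- temporal split -------------------------------------------------------

test_that("temporal splits round to non-empty contiguous ordered blocks", {
  s46 <- temporal_split(45:90)
  expect_equal(lengths(s46[1:3]), c(train_ages = 32, val_ages = 7,
                                    test_ages = 7))
  expect_equal(s46$train_ages, 45:76)
  expect_lt(max(s46$train_ages), min(s46$val_ages))
  expect_lt(max(s46$val_ages), min(s46$test_ages))

  s3 <- temporal_split(1:3)
  expect_equal(lengths(s3[1:3]), c(train_ages = 1, val_ages = 1,
                                   test_ages = 1))
  s10 <- temporal_split(1:10, c(0.8, 0.1, 0.1))
  expect_equal(lengths(s10[1:3]), c(train_ages = 8, val_ages = 1,
                                    test_ages = 1))
  expect_error(temporal_split(1:2), "too short")
})

# --- targets --------------------------------------------------------------

test_that("new-edge targets are the set difference of consecutive edge sets", {
  cat3 <- tiny_catalog(3)
  mk <- function(a_now, a_next) {
    structure(list(ages = c(50L, 51L), mode = "cumulative",
                   adjacency = list("50" = a_now, "51" = a_next),
                   weights = list("50" = a_now, "51" = a_next),
                   catalog = cat3),
              class = "snapshot_sequence")
  }
  a_now <- adj_from_edges(3, c(1, 2))
  a_next <- adj_from_edges(3, c(1, 2, 1, 3))
  tg <- make_targets(mk(a_now, a_next), 50, "new_edges")
  expect_equal(unname(tg$positives), matrix(c(1L, 3L), 1, 2))
  tg_same <- make_targets(mk(a_now, a_now), 50, "new_edges")
  expect_equal(nrow(tg_same$positives), 0)
  tg_all <- make_targets(mk(a_now, a_next), 50, "all_edges")
  expect_equal(nrow(tg_all$positives), 2)
})

test_that("positives and negatives partition all unordered non-self pairs", {
  ps <- planted_sequence(seed = 13, n_patients = 120)
  n <- 14
  for (t in c(50, 65, 80)) {
    for (mode in c("new_edges", "all_edges")) {
      tg <- make_targets(ps$sequence, t, mode)
      keys <- c(cegcn:::pair_key(tg$positives, n),
                cegcn:::pair_key(tg$negatives, n))
      all_keys <- cegcn:::pair_key(cegcn:::all_node_pairs(n), n)
      expect_setequal(keys, all_keys)
      expect_equal(length(keys), choose(n, 2)) # disjoint
    }
  }
})

# --- AP / MRR -------------------------------------------------------------

test_that("average precision and reciprocal rank match hand-computed values", {
  expect_equal(average_precision(c(1, 0, 1)), (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(1, 1, 1, 0)), 1)
  expect_equal(average_precision(c(0, 0, 0, 1, rep(0, 6))), 0.25)
  expect_error(average_precision(c(0, 0)), "empty")
  expect_equal(reciprocal_rank(c(0, 1, 0)), 0.5)
  expect_equal(reciprocal_rank(rep(0, 4)), 0)
  expect_equal(mean_reciprocal_rank(c(1 / 2, 1 / 4)), 0.375)
  expect_equal(mean_average_precision(c(1, 0.5)), 0.75)
  expect_error(mean_average_precision(numeric(0)), "queries")
})

test_that("AP and RR agree with exhaustive enumeration for all rankings of length <= 6", {
  # independent oracle: walk the ranked list accumulating precision/recall
  ap_oracle <- function(rel) {
    n_rel <- sum(rel); hits <- 0; total <- 0
    for (r in seq_along(rel)) {
      if (rel[r] == 1) { hits <- hits + 1; total <- total + hits / r }
    }
    total / n_rel
  }
  rr_oracle <- function(rel) {
    for (r in seq_along(rel)) if (rel[r] == 1) return(1 / r)
    0
  }
  for (len in 1:6) {
    grid <- as.matrix(expand.grid(rep(list(0:1), len)))
    for (row in seq_len(nrow(grid))) {
      rel <- grid[row, ]
      expect_equal(reciprocal_rank(rel), rr_oracle(rel))
      if (sum(rel) > 0) expect_equal(average_precision(rel), ap_oracle(rel))
    }
  }
})

test_that("improving the rank of a relevant item never decreases AP", {
  withr::local_seed(21)
  for (trial in 1:50) {
    len <- sample(3:10, 1)
    rel <- rbinom(len, 1, 0.4)
    if (sum(rel) == 0 || all(rel == 1)) next
    ap0 <- average_precision(rel)
    cands <- which(rel == 1 & seq_len(len) > 1)
    if (length(cands) == 0) next
    pos <- cands[sample.int(length(cands), 1)]
    if (rel[pos - 1] == 1) next
    rel2 <- rel; rel2[pos] <- 0; rel2[pos - 1] <- 1 # move one relevant item up
    expect_gte(average_precision(rel2), ap0)
  }
})

test_that("a random scorer attains the closed-form expected MRR", {
  # 5 candidates, 1 relevant: E[MRR] = mean(1/1..5) = 0.45666...
  withr::local_seed(31)
  rrs <- vapply(1:1000, function(s) {
    scores <- runif(5)
    ranked <- order(-scores)
    reciprocal_rank(ranked == 3) # the relevant item is candidate 3
  }, numeric(1))
  expected <- mean(1 / (1:5))
  se <- sd(rrs) / sqrt(length(rrs))
  expect_lt(abs(mean(rrs) - expected), 3 * se)
})

# --- training -------------------------------------------------------------

test_that("one epoch on a toy sequence changes parameters and is seed-reproducible", {
  ps <- planted_sequence(seed = 17, n_patients = 150)
  cf <- fast_config(epochs = 1, seed = 4)
  fit1 <- fit_cegcn(ps$sequence, config = cf)
  expect_true(all(is.finite(fit1$loss_curve$loss)))
  init <- init_cegcn_params(fit1$vocab$d, cf)
  expect_false(isTRUE(all.equal(fit1$params[["mlp.W1"]], init[["mlp.W1"]])))

  cf2 <- fast_config(epochs = 3, seed = 4)
  fitA <- fit_cegcn(ps$sequence, config = cf2)
  fitB <- fit_cegcn(ps$sequence, config = cf2)
  expect_identical(fitA$loss_curve$loss, fitB$loss_curve$loss)
  expect_identical(fitA$params, fitB$params)
})

test_that("training loss decreases on a learnable planted pattern", {
  ps <- planted_sequence(seed = 23, n_patients = 250, rule_strength = 1)
  cf <- fast_config(epochs = 40, patience = 40, seed = 6)
  fit <- fit_cegcn(ps$sequence, config = cf)
  curve <- fit$loss_curve$loss
  first5 <- mean(head(curve, 5))
  last5 <- mean(utils::tail(curve, 5))
  expect_lt(last5, first5)
})

# --- evaluation -----------------------------------------------------------

test_that("a perfect oracle scorer achieves MAP = MRR = 1 through the pipeline", {
  ps <- planted_sequence(seed = 19, n_patients = 200)
  sq <- ps$sequence
  for (t in c(60, 75)) {
    s_oracle <- sq$adjacency[[as.character(t + 1)]] + 0.0 # truth as scores
    q <- cegcn:::queries_from_scores(sq, t, "new_edges", s_oracle)
    if (nrow(q) == 0) next
    expect_equal(mean_average_precision(q$ap), 1)
    expect_equal(mean_reciprocal_rank(q$rr), 1)
  }
})

test_that("a constant scorer reduces to the deterministic id tie-break ordering", {
  ps <- planted_sequence(seed = 19, n_patients = 200)
  sq <- ps$sequence
  t <- 60
  s_const <- matrix(0, 14, 14)
  q <- cegcn:::queries_from_scores(sq, t, "new_edges", s_const)
  tg <- make_targets(sq, t, "new_edges")
  linked <- sq$adjacency[[as.character(t)]]
  for (row in seq_len(nrow(q))) {
    qn <- q$query_node[row]
    cands <- setdiff(1:14, qn)
    cands <- cands[linked[qn, cands] == 0] # ascending id = tie-break order
    rel <- unique(c(tg$positives[tg$positives[, 1] == qn, 2],
                    tg$positives[tg$positives[, 2] == qn, 1]))
    expect_equal(q$rr[row], reciprocal_rank(cands %in% rel))
    expect_equal(q$ap[row], average_precision(cands %in% rel))
  }
})

test_that("evaluation errors when the block holds no positive pairs", {
  # two identical snapshots: no new edges anywhere
  coh <- cohort_from_list(list(P1 = c(d1 = 45, d2 = 45),
                               P2 = c(d1 = 45, d3 = 45)),
                          n_dis = 3, age_min = 45, age_max = 50)
  sq <- build_snapshots(coh, age_min = 45, age_max = 50)
  fit <- list(split = temporal_split(sq),
              vocab = build_vocabulary(list(0L)), mode = "new_edges",
              params = init_cegcn_params(2, fast_config(seed = 1)),
              config = fast_config(seed = 1))
  class(fit) <- "cegcn_fit"
  expect_error(evaluate_model(fit, sq), "undefined")
})

test_that("fitted models evaluate deterministically and report valid metrics", {
  ps <- planted_sequence(seed = 29, n_patients = 250)
  cf <- fast_config(epochs = 15, seed = 2)
  fit <- fit_cegcn(ps$sequence, config = cf)
  m <- evaluate_model(fit, ps$sequence)
  expect_true(m$map >= 0 && m$map <= 1)
  expect_true(m$mrr >= 0 && m$mrr <= 1)
  expect_equal(m$map, mean(m$queries$ap))
  expect_equal(m$mrr, mean(m$queries$rr))
  m2 <- evaluate_model(fit, ps$sequence)
  expect_identical(m$queries, m2$queries)
  expect_s3_class(glance(m), "tbl_df")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

# --- top pairs report -----------------------------------------------------

test_that("the top-pairs report lists each pair once with non-increasing scores", {
  ps <- planted_sequence(seed = 29, n_patients = 250)
  cf <- fast_config(epochs = 10, seed = 2)
  fit <- fit_cegcn(ps$sequence, config = cf)
  full <- top_pairs_report(fit, ps$sequence, age = 70, k = choose(14, 2))
  expect_equal(nrow(full), choose(14, 2))
  keyed <- paste(pmin(full$node_i, full$node_j), pmax(full$node_i, full$node_j))
  expect_equal(anyDuplicated(keyed), 0)
  top10 <- top_pairs_report(fit, ps$sequence, age = 70, k = 10)
  expect_equal(nrow(top10), 10)
  expect_true(all(diff(top10$score) <= 0))
  expect_warning(top_pairs_report(fit, ps$sequence, age = 70, k = 1000),
                 "truncated")
})

# --- baseline, checkpoint, audit ------------------------------------------

test_that("the static-GCN baseline runs the same pipeline without weight evolution", {
  ps <- planted_sequence(seed = 37, n_patients = 150)
  cf <- fast_config(epochs = 5, seed = 3)
  bl <- fit_static_gcn(ps$sequence, config = cf)
  expect_equal(bl$config$evolve, "none")
  m <- evaluate_model(bl, ps$sequence)
  expect_true(is.finite(m$map) && is.finite(m$mrr))
  # no GRU evolution: forward embeddings use W0 at every age
  feats <- cegcn:::features_with_vocab(ps$sequence, bl$vocab)
  emb <- forward_sequence(ps$sequence, feats, bl$params, bl$config,
                          ages = 45:47)
  na <- normalize_adjacency(ps$sequence$adjacency[["46"]])
  by_hand <- gcn_forward(na,
                         gcn_forward(na, feats[["46"]], bl$params[["W0.1"]],
                                     "relu"),
                         bl$params[["W0.2"]], "identity")
  expect_equal(emb[["46"]], by_hand, tolerance = 1e-12)
})

test_that("checkpoints round-trip through JSON with identical scoring", {
  ps <- planted_sequence(seed = 41, n_patients = 150)
  cf <- fast_config(epochs = 4, seed = 8)
  fit <- fit_cegcn(ps$sequence, config = cf)
  path <- withr::local_tempfile(fileext = ".json")
  save_cegcn(fit, path)
  fit2 <- load_cegcn(path)
  r1 <- top_pairs_report(fit, ps$sequence, 70, 10)
  r2 <- top_pairs_report(fit2, ps$sequence, 70, 10)
  expect_equal(r1$score, r2$score)
  expect_equal(glance(fit)$n_params, glance(fit2)$n_params)
})

test_that("the leakage audit passes for a standard fit and training ignores test ages", {
  ps <- planted_sequence(seed = 43, n_patients = 150)
  cf <- fast_config(epochs = 3, seed = 5)
  fit <- fit_cegcn(ps$sequence, config = cf)
  audit <- leakage_audit(fit)
  expect_true(audit$pass)
  expect_true(audit$vocab_ok && audit$targets_ok)

  # stronger invariance check: rewiring every test-age snapshot must leave
  # the training trajectory bit-identical
  sq2 <- ps$sequence
  for (a in as.character(temporal_split(sq2)$test_ages)) {
    sq2$adjacency[[a]] <- adj_from_edges(14, c(1, 14))
    sq2$weights[[a]] <- adj_from_edges(14, c(1, 14))
  }
  fit2 <- fit_cegcn(sq2, config = cf)
  expect_identical(fit$loss_curve$loss, fit2$loss_curve$loss)
  expect_identical(fit$params, fit2$params)
})
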