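# Fixtures are built in code: tiny catalogs, hand-laid cohorts, random
# graphs, and a compact planted-signal simulation shared across test files.

tiny_catalog <- function(n) {
  disease_catalog(data.frame(disease_id = seq_len(n),
                             name = paste0("d", seq_len(n))))
}

# cohort from a list like list(P1 = c(d1 = 50, d2 = 55), ...)
cohort_from_list <- function(patients, n_dis, age_min = 45, age_max = 90) {
  rec <- purrr::imap_dfr(patients, function(onsets, pid) {
    tibble::tibble(patient_id = pid,
                   disease_id = as.integer(sub("^d", "", names(onsets))),
                   onset_age = as.integer(onsets))
  })
  if (nrow(rec) == 0) {
    rec <- tibble::tibble(patient_id = character(), disease_id = integer(),
                          onset_age = integer())
  }
  suppressWarnings(as_cohort(rec, tiny_catalog(n_dis), age_min, age_max))
}

# symmetric binary adjacency from an edge list (two-column matrix)
adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  if (length(edges)) {
    edges <- matrix(edges, ncol = 2, byrow = TRUE)
    a[edges] <- 1L
    a[edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  a
}

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a + t(a)
}

# independent brute-force path-of-length-2 counter (oracle for A^2)
count_paths2 <- function(a) {
  n <- nrow(a)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cnt <- 0L
    for (k in seq_len(n)) if (a[i, k] == 1 && a[k, j] == 1) cnt <- cnt + 1L
    out[i, j] <- cnt
  }
  out
}

# scalar-loop oracle for the gated weight update (independent of the
# package's matrix implementation)
gru_oracle <- function(s, w_prev, g) {
  din <- nrow(w_prev); dout <- ncol(w_prev)
  sig <- function(x) 1 / (1 + exp(-x))
  z <- r <- cand <- w_new <- matrix(0, din, dout)
  for (i in seq_len(din)) for (j in seq_len(dout)) {
    z[i, j] <- sig(sum(g$UZ[i, ] * s[, j]) + sum(g$CZ[i, ] * w_prev[, j]) + g$BZ[i])
    r[i, j] <- sig(sum(g$UR[i, ] * s[, j]) + sum(g$CR[i, ] * w_prev[, j]) + g$BR[i])
  }
  for (i in seq_len(din)) for (j in seq_len(dout)) {
    cand[i, j] <- tanh(sum(g$UW[i, ] * s[, j]) +
                       sum(g$CW[i, ] * (r[, j] * w_prev[, j])) + g$BW[i])
    w_new[i, j] <- (1 - z[i, j]) * w_prev[i, j] + z[i, j] * cand[i, j]
  }
  list(weight = w_new, update = z, reset = r, candidate = cand)
}

rand_gru <- function(din) {
  g <- list()
  for (gate in c("Z", "R", "W")) {
    g[[paste0("U", gate)]] <- matrix(rnorm(din * din, sd = 0.5), din, din)
    g[[paste0("C", gate)]] <- matrix(rnorm(din * din, sd = 0.5), din, din)
    g[[paste0("B", gate)]] <- matrix(rnorm(din), din, 1)
  }
  g
}

# a small planted-signal snapshot sequence used by several end-to-end tests
planted_sequence <- function(seed = 11, n_patients = 250, rule_strength = 1) {
  cfg <- sim_config(n_patients = n_patients, seed = seed)
  sim <- simulate_cohort(cfg)
  pl <- plant_temporal_rule(sim$records, cfg, rule_strength = rule_strength)
  coh <- suppressWarnings(as_cohort(pl$records, default_disease_catalog()))
  list(sequence = build_snapshots(coh), planted = pl$planted, config = cfg)
}

fast_config <- function(..., epochs = 25, patience = 25) {
  cegcn_config(hidden = c(8, 8), mlp_hidden = 8, epochs = epochs,
               patience = patience, ...)
}
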