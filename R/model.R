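#' Model configuration
#'
#' Collects every tunable of the CE-GCN architecture and its training loop.
#' The input feature dimension d is not set here: it equals the size of the
#' feature vocabulary and is bound when parameters are initialized.
#'
#' @param hidden Integer vector of GCN layer widths, one per layer.
#' @param mlp_hidden Width of the hidden layer of the pair-scoring MLP.
#' @param pos_weight Class weight of positive pairs in the cross-entropy
#'   loss; positives (new edges) are rare among all node pairs.
#' @param neg_ratio Negative pairs sampled per positive during training.
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs without improvement of
#'   validation MAP (or of training loss when validation MAP is undefined).
#' @param evolve `"all"` evolves every GCN layer's weights through the GRU;
#'   `"first"` evolves only the first layer; `"none"` gives the static-GCN
#'   baseline (one weight matrix per layer, shared across all ages).
#' @param seed Integer seed controlling initialization and negative sampling.
#' @return A list of class `cegcn_config`.
#' @export
cegcn_config <- function(hidden = c(32, 32), mlp_hidden = 32, pos_weight = 10,
                         neg_ratio = 5, lr = 0.01, epochs = 200, patience = 20,
                         evolve = c("all", "first", "none"), seed = 1L) {
  evolve <- match.arg(evolve)
  stopifnot(length(hidden) >= 1, all(hidden >= 1), mlp_hidden >= 1,
            pos_weight > 0, neg_ratio >= 1, lr > 0, epochs >= 1)
  structure(list(hidden = as.integer(hidden), mlp_hidden = as.integer(mlp_hidden),
                 pos_weight = pos_weight, neg_ratio = neg_ratio, lr = lr,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 evolve = evolve, seed = as.integer(seed)),
            class = "cegcn_config")
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

pkey <- function(...) paste(..., sep = ".")

#' Initialize CE-GCN parameters
#'
#' Glorot-uniform initialization of all trainable matrices: the initial GCN
#' weights W_0(l), the per-layer top-k pooling score vectors, the GRU gate
#' matrices (square, left-multiplying) and biases (column vectors), and the
#' two-layer pair-scoring MLP. Deterministic given `config$seed`.
#'
#' @param d Input feature dimension (vocabulary size).
#' @param config A [cegcn_config()].
#' @return A flat named list of parameter matrices.
#' @export
init_cegcn_params <- function(d, config) {
  dims <- c(d, config$hidden)
  L <- length(config$hidden)
  withr::with_seed(config$seed, {
    params <- list()
    for (l in seq_len(L)) {
      din <- dims[l]; dout <- dims[l + 1]
      params[[pkey("W0", l)]] <- glorot(din, dout)
      params[[pkey("pool", l)]] <- glorot(din, 1)
      for (gate in c("Z", "R", "W")) {
        params[[pkey("gru", l, paste0("U", gate))]] <- glorot(din, din)
        params[[pkey("gru", l, paste0("C", gate))]] <- glorot(din, din)
        # update gate biased towards carrying the previous weights forward,
        # so training starts close to the static regime and learns temporal
        # deviations gradually (the usual recurrent gate-bias initialization)
        params[[pkey("gru", l, paste0("B", gate))]] <-
          matrix(if (gate == "Z") -2 else 0, din, 1)
      }
    }
    h <- dims[L + 1]
    params[[pkey("mlp", "W1")]] <- glorot(2 * h, config$mlp_hidden)
    params[[pkey("mlp", "b1")]] <- matrix(0, 1, config$mlp_hidden)
    params[[pkey("mlp", "W2")]] <- glorot(config$mlp_hidden, 1)
    params[[pkey("mlp", "b2")]] <- matrix(0, 1, 1)
    params
  })
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes the GCN propagation operator D^-1/2 (A + I) D^-1/2, where D is
#' the degree matrix of A + I. The self-loop guarantees every degree is at
#' least 1, so the operator is defined even for isolated nodes; its
#' eigenvalues always lie in [-1, 1]. An empty graph yields the identity.
#'
#' @param snapshot A snapshot list with an `adjacency` element, or a binary
#'   symmetric matrix.
#' @return An n x n symmetric numeric matrix.
#' @export
normalize_adjacency <- function(snapshot) {
  a <- if (is.list(snapshot)) snapshot$adjacency else snapshot
  stopifnot(is.matrix(a), nrow(a) == ncol(a), all(a %in% c(0, 1)),
            all(diag(a) == 0))
  a_tilde <- a + diag(nrow(a))
  d_inv_sqrt <- 1 / sqrt(rowSums(a_tilde))
  a_tilde * outer(d_inv_sqrt, d_inv_sqrt)
}

#' One graph-convolution layer
#'
#' The propagation rule H_(l+1) = sigma(Ahat H_(l) W_(l)), with Ahat the
#' normalized self-looped adjacency from [normalize_adjacency()]. Hidden
#' layers use ReLU; the final layer is linear so its embeddings feed the
#' pair scorer unclipped.
#'
#' @param norm_adj n x n normalized adjacency.
#' @param embeddings n x d_in node embedding matrix H_(l).
#' @param weight d_in x d_out weight matrix W_(l).
#' @param activation `"relu"` or `"identity"`.
#' @return The n x d_out matrix H_(l+1).
#' @export
gcn_forward <- function(norm_adj, embeddings, weight,
                        activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  ev <- ag_value(embeddings); wv <- ag_value(weight)
  if (ncol(norm_adj) != nrow(ev) || ncol(ev) != nrow(wv)) {
    stop("gcn_forward: non-conformable shapes (adjacency ", ncol(norm_adj),
         ", embeddings ", nrow(ev), "x", ncol(ev), ", weight ", nrow(wv),
         "x", ncol(wv), ")", call. = FALSE)
  }
  z <- ag_mm(ag_mm(norm_adj, embeddings), weight)
  if (activation == "relu") ag_relu(z) else z
}

#' Summarize node embeddings to k rows by learned top-k pooling
#'
#' The GRU that evolves a d_in x d_out weight matrix needs an input of the
#' same shape, but the layer provides an n x d embedding matrix. The
#' reconciliation is deterministic learned top-k pooling: each node is scored
#' by the projection of its embedding onto a learned direction p
#' (y = X p / ||p||), the k highest-scoring rows are kept (ties broken by
#' ascending row index), and each kept row is scaled by the gate tanh(y_i).
#' When n < k the result is zero-padded to k rows.
#'
#' @param embeddings n x d matrix (plain or autodiff node).
#' @param k Number of rows to keep.
#' @param score_vector Learned scoring vector of length d (or d x 1 matrix).
#' @return A k x d matrix of pooled, gated rows.
#' @export
summarize_embeddings <- function(embeddings, k, score_vector) {
  p <- if (is_ag(score_vector)) score_vector else matrix(as.vector(score_vector))
  pn <- ag_l2norm(p)
  raw <- ag_mm(embeddings, p)
  y <- if (ag_value(pn)[1] > 0) ag_div_scalar(raw, pn) else raw
  yv <- as.vector(ag_value(y))
  n <- length(yv)
  idx <- order(-yv, seq_len(n))[seq_len(min(k, n))]
  out <- ag_scale_rows(ag_rows(embeddings, idx), ag_tanh(ag_rows(y, idx)))
  ag_pad_rows(out, k)
}

#' One GRU update of a GCN weight matrix
#'
#' The gated recurrent update that evolves a layer's weights along the age
#' axis: update gate Z = sigmoid(U_Z S + C_Z W + B_Z), reset gate
#' R = sigmoid(U_R S + C_R W + B_R), candidate
#' W~ = tanh(U_W S + C_W (R o W) + B_W), and new state
#' W' = (1 - Z) o W + Z o W~ (o is the Hadamard product). Every entry of W'
#' is a convex combination of the previous and candidate entries.
#'
#' @param summary The d_in x d_out pooled embedding matrix (GRU input),
#'   typically `t(summarize_embeddings(H, d_out, p))`.
#' @param prev_weight The previous weight matrix W_(t-1), d_in x d_out.
#' @param gru_params Named list with `UZ`, `CZ`, `BZ`, `UR`, `CR`, `BR`,
#'   `UW`, `CW`, `BW` (U, C square d_in x d_in; B column vectors d_in x 1).
#' @return List with `weight` (the updated matrix), and the gate activations
#'   `update`, `reset`, `candidate`.
#' @export
gru_weight_update <- function(summary, prev_weight, gru_params) {
  gp <- gru_params
  gate <- function(U, C, B) ag_sigmoid(ag_add_colbias(
    ag_add(ag_mm(U, summary), ag_mm(C, prev_weight)), B))
  z <- gate(gp$UZ, gp$CZ, gp$BZ)
  r <- gate(gp$UR, gp$CR, gp$BR)
  cand <- ag_tanh(ag_add_colbias(
    ag_add(ag_mm(gp$UW, summary), ag_mm(gp$CW, ag_hadamard(r, prev_weight))),
    gp$BW))
  w <- ag_add(ag_hadamard(ag_one_minus(z), prev_weight),
              ag_hadamard(z, cand))
  if (any(!is.finite(ag_value(w)))) {
    stop("non-finite weight after GRU update", call. = FALSE)
  }
  list(weight = w, update = z, reset = r, candidate = cand)
}

gru_layer_params <- function(params, l) {
  list(UZ = params[[pkey("gru", l, "UZ")]], CZ = params[[pkey("gru", l, "CZ")]],
       BZ = params[[pkey("gru", l, "BZ")]], UR = params[[pkey("gru", l, "UR")]],
       CR = params[[pkey("gru", l, "CR")]], BR = params[[pkey("gru", l, "BR")]],
       UW = params[[pkey("gru", l, "UW")]], CW = params[[pkey("gru", l, "CW")]],
       BW = params[[pkey("gru", l, "BW")]])
}

#' Run the evolving GCN over a snapshot sequence
#'
#' For each age in order, every layer first evolves its weight matrix through
#' the GRU (input: the top-k pooled and transposed current layer input), then
#' applies the graph convolution. With `config$evolve = "none"` the weights
#' stay at their initial values at every age (static-GCN baseline); with
#' `"first"` only layer 1 evolves.
#'
#' @param sequence A `snapshot_sequence`.
#' @param features List of n x d one-hot feature matrices, one per age (see
#'   [compute_features()]).
#' @param params Parameter list from [init_cegcn_params()] (plain matrices or
#'   autodiff nodes).
#' @param config A [cegcn_config()].
#' @param ages Ages to run over, in order; defaults to all ages of the
#'   sequence. Restricting to the training block keeps gradients free of any
#'   later-age information.
#' @return A named list (by age) of final-layer n x h embedding matrices.
#' @export
forward_sequence <- function(sequence, features, params, config,
                             ages = sequence$ages) {
  stopifnot(all(as.character(ages) %in% names(features)))
  L <- length(config$hidden)
  W <- lapply(seq_len(L), function(l) params[[pkey("W0", l)]])
  out <- vector("list", length(ages))
  names(out) <- as.character(ages)
  for (age_chr in as.character(ages)) {
    na <- normalize_adjacency(sequence$adjacency[[age_chr]])
    X <- features[[age_chr]]
    for (l in seq_len(L)) {
      evolve_l <- switch(config$evolve, all = TRUE, first = l == 1, none = FALSE)
      if (evolve_l) {
        k_out <- ncol(ag_value(W[[l]]))
        S <- ag_t(summarize_embeddings(X, k_out, params[[pkey("pool", l)]]))
        W[[l]] <- gru_weight_update(S, W[[l]], gru_layer_params(params, l))$weight
      }
      X <- gcn_forward(na, X, W[[l]],
                       activation = if (l < L) "relu" else "identity")
    }
    out[[age_chr]] <- X
  }
  out
}

#' Score node pairs with the symmetrized MLP
#'
#' Each unordered pair (i, j) is represented by the concatenation of the two
#' final-layer embeddings and passed through a two-layer MLP; the logit is
#' the average of the scores of both orderings, so score(i, j) == score(j, i)
#' exactly.
#'
#' @param embeddings n x h final-layer embedding matrix.
#' @param pairs Two-column integer matrix of node indices, i != j.
#' @param params Parameter list holding the `mlp.*` entries.
#' @return A length-`nrow(pairs)` column of logits (plain or autodiff node).
#' @export
score_pairs <- function(embeddings, pairs, params) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs[, 1] == pairs[, 2])) {
    stop("self-pairs are not scoreable", call. = FALSE)
  }
  mlp <- function(f) {
    h1 <- ag_relu(ag_add_rowbias(ag_mm(f, params[[pkey("mlp", "W1")]]),
                                 params[[pkey("mlp", "b1")]]))
    ag_add_rowbias(ag_mm(h1, params[[pkey("mlp", "W2")]]),
                   params[[pkey("mlp", "b2")]])
  }
  hi <- ag_rows(embeddings, pairs[, 1])
  hj <- ag_rows(embeddings, pairs[, 2])
  ag_scale(ag_add(mlp(ag_cbind(hi, hj)), mlp(ag_cbind(hj, hi))), 0.5)
}

#' Class-weighted cross-entropy link loss
#'
#' Mean over pairs of binary cross-entropy with logits, with the positive
#' class weighted by `pos_weight` (new edges are rare among all node pairs,
#' so unweighted loss would be dominated by easy negatives). For all-zero
#' logits and `pos_weight = 1` the loss is exactly log(2).
#'
#' @param logits Numeric vector (or column / autodiff node) of pair logits.
#' @param labels Binary vector, 1 for a true (future) edge.
#' @param pos_weight Positive-class weight, default 1.
#' @return A scalar (plain numeric, or 1 x 1 autodiff node for node input).
#' @export
link_loss <- function(logits, labels, pos_weight = 1) {
  if (length(as.vector(ag_value(logits))) == 0) {
    stop("link_loss: empty input", call. = FALSE)
  }
  stopifnot(length(as.vector(ag_value(logits))) == length(labels),
            all(labels %in% c(0, 1)))
  out <- ag_bce_logits(if (is_ag(logits)) logits else matrix(as.vector(logits)),
                       labels, pos_weight)
  if (is_ag(out)) out else out[1]
}
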