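# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every operator accepts either a plain numeric matrix or an `ag_node`; when
# all inputs are plain the operator returns a plain matrix, so the model
# forward pass is written once and reused for both inference and training.
# Nodes record their parents and a backward closure; ag_backward() runs the
# tape in reverse creation order, which is a valid topological order because
# a node can only depend on nodes created before it.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  .ag$counter <- .ag$counter + 1L
  e$id <- .ag$counter
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  class(e) <- "ag_node"
  e
}

is_ag <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_ag(x)) x$value else x

# Leaf node carrying a trainable parameter.
ag_param <- function(value) ag_node(as.matrix(value))

any_ag <- function(...) any(vapply(list(...), is_ag, logical(1)))

ag_mm <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  v <- av %*% bv
  if (!any_ag(a, b)) return(v)
  ag_node(v, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ag_add <- function(a, b) {
  v <- ag_value(a) + ag_value(b)
  if (!any_ag(a, b)) return(v)
  ag_node(v, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  v <- ag_value(a) - ag_value(b)
  if (!any_ag(a, b)) return(v)
  ag_node(v, list(a, b), function(g) list(g, -g))
}

ag_hadamard <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  v <- av * bv
  if (!any_ag(a, b)) return(v)
  ag_node(v, list(a, b), function(g) list(g * bv, g * av))
}

# 1 - a, elementwise
ag_one_minus <- function(a) {
  v <- 1 - ag_value(a)
  if (!is_ag(a)) return(v)
  ag_node(v, list(a), function(g) list(-g))
}

ag_scale <- function(a, s) { # s: plain scalar
  v <- ag_value(a) * s
  if (!is_ag(a)) return(v)
  ag_node(v, list(a), function(g) list(g * s))
}

# column-vector bias (length nrow(a)) broadcast across columns of a
ag_add_colbias <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  v <- av + as.vector(bv)
  if (!any_ag(a, b)) return(v)
  ag_node(v, list(a, b), function(g) {
    list(g, matrix(rowSums(g), ncol = 1))
  })
}

# row-vector bias (length ncol(a)) broadcast across rows of a
ag_add_rowbias <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  v <- sweep(av, 2, as.vector(bv), "+")
  if (!any_ag(a, b)) return(v)
  ag_node(v, list(a, b), function(g) {
    list(g, matrix(colSums(g), nrow = 1))
  })
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ag_value(a)))
  if (!is_ag(a)) return(s)
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(a) {
  v <- tanh(ag_value(a))
  if (!is_ag(a)) return(v)
  ag_node(v, list(a), function(g) list(g * (1 - v^2)))
}

ag_relu <- function(a) {
  av <- ag_value(a)
  v <- pmax(av, 0)
  if (!is_ag(a)) return(v)
  ag_node(v, list(a), function(g) list(g * (av > 0)))
}

ag_t <- function(a) {
  v <- t(ag_value(a))
  if (!is_ag(a)) return(v)
  ag_node(v, list(a), function(g) list(t(g)))
}

# row subset; duplicate indices accumulate gradient
ag_rows <- function(a, idx) {
  av <- ag_value(a)
  v <- av[idx, , drop = FALSE]
  if (!is_ag(a)) return(v)
  ag_node(v, list(a), function(g) {
    z <- matrix(0, nrow(av), ncol(av))
    agg <- rowsum(g, group = idx)
    z[as.integer(rownames(agg)), ] <- agg
    list(z)
  })
}

# pad with zero rows up to k rows (no-op when nrow >= k)
ag_pad_rows <- function(a, k) {
  av <- ag_value(a)
  n <- nrow(av)
  if (n >= k) return(a)
  v <- rbind(av, matrix(0, k - n, ncol(av)))
  if (!is_ag(a)) return(v)
  ag_node(v, list(a), function(g) list(g[seq_len(n), , drop = FALSE]))
}

# scale row i of a by s[i]; s is an n x 1 matrix/node
ag_scale_rows <- function(a, s) {
  av <- ag_value(a); sv <- as.vector(ag_value(s))
  v <- av * sv
  if (!any_ag(a, s)) return(v)
  ag_node(v, list(a, s), function(g) {
    list(g * sv, matrix(rowSums(g * av), ncol = 1))
  })
}

ag_cbind <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  v <- cbind(av, bv)
  if (!any_ag(a, b)) return(v)
  na <- ncol(av)
  ag_node(v, list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

# Euclidean norm of a vector (n x 1) as a 1 x 1 value
ag_l2norm <- function(a) {
  av <- ag_value(a)
  nv <- sqrt(sum(av^2))
  v <- matrix(nv, 1, 1)
  if (!is_ag(a)) return(v)
  ag_node(v, list(a), function(g) list(g[1] * av / nv))
}

# divide a matrix by a 1 x 1 scalar node
ag_div_scalar <- function(a, s) {
  av <- ag_value(a); sv <- ag_value(s)[1]
  v <- av / sv
  if (!any_ag(a, s)) return(v)
  ag_node(v, list(a, s), function(g) {
    list(g / sv, matrix(-sum(g * av) / sv^2, 1, 1))
  })
}

ag_sum <- function(a) {
  v <- matrix(sum(ag_value(a)), 1, 1)
  if (!is_ag(a)) return(v)
  ag_node(v, list(a), function(g) {
    list(matrix(g[1], nrow(ag_value(a)), ncol(ag_value(a))))
  })
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Class-weighted binary cross-entropy with logits, mean over elements.
# loss_i = w_i * (softplus(x_i) - y_i * x_i), w_i = pos_weight if y_i == 1
ag_bce_logits <- function(logits, labels, pos_weight = 1) {
  x <- as.vector(ag_value(logits))
  y <- as.numeric(labels)
  w <- ifelse(y == 1, pos_weight, 1)
  v <- matrix(mean(w * (softplus(x) - y * x)), 1, 1)
  if (!is_ag(logits)) return(v)
  n <- length(x)
  ag_node(v, list(logits), function(g) {
    list(matrix(g[1] * w * (1 / (1 + exp(-x)) - y) / n, ncol = 1))
  })
}

# Backpropagate from a scalar (1 x 1) root; fills $grad on every reachable
# ag_node, in particular on parameter leaves.
ag_backward <- function(root) {
  stopifnot(is_ag(root))
  # iterative DFS to collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- vector("list", 256L)
  nn <- 0L
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- n
    for (p in n$parents) if (is_ag(p)) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  for (n in nodes) n$grad <- NULL
  root$grad <- array(1, dim(root$value))
  for (n in nodes[ord]) {
    if (is.null(n$grad) || is.null(n$backward)) next
    gs <- n$backward(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (!is_ag(p) || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(root)
}
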