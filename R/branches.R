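# ---- graph adjacency operator -------------------------------------------
# Mean-over-neighbors operator A and its transpose, built once per graph from
# the undirected edge list. Isolated nodes get a zero neighbor mean.

graph_ops <- function(edges, n) {
  if (nrow(edges)) {
    src <- c(edges[, 1], edges[, 2])
    dst <- c(edges[, 2], edges[, 1])
  } else {
    src <- dst <- integer(0)
  }
  deg <- tabulate(dst, nbins = n)
  ops <- list(src = src, dst = dst, deg = deg, n = n)
  if (n <= 2048L) {
    # materialize the mean operator: one dense matrix product per layer is
    # much cheaper than grouped sums at nuclei-graph sizes
    A <- matrix(0, n, n)
    if (length(src)) A[cbind(dst, src)] <- 1 / deg[dst]
    ops$A <- A
  }
  ops
}

nbr_mean <- function(ops, H) {
  if (!is.null(ops$A)) return(ops$A %*% H)
  res <- matrix(0, ops$n, ncol(H))
  if (length(ops$src)) {
    rs <- rowsum(H[ops$src, , drop = FALSE], ops$dst)
    rows <- as.integer(rownames(rs))
    res[rows, ] <- rs / ops$deg[rows]
  }
  res
}

# transpose of nbr_mean: (A^T G)_u = sum over v with u in N(v) of G_v / deg_v
nbr_mean_t <- function(ops, G) {
  if (!is.null(ops$A)) return(crossprod(ops$A, G))
  res <- matrix(0, ops$n, ncol(G))
  if (length(ops$src)) {
    w <- G[ops$dst, , drop = FALSE] / ops$deg[ops$dst]
    rs <- rowsum(w, ops$src)
    rows <- as.integer(rownames(rs))
    res[rows, ] <- rs
  }
  res
}

relu <- function(x) (x > 0) * x

# ---- GraphSAGE layer -----------------------------------------------------

#' GraphSAGE convolution layer
#'
#' Computes `h'_v = act(W %*% c(h_v, mean_{u in N(v)} h_u) + b)`: each node's
#' attributes are concatenated with the mean of its neighbors' attributes and
#' passed through a learned affine map. Isolated nodes use a zero neighbor
#' mean.
#'
#' @param node_attrs N x d input attribute matrix.
#' @param edges Undirected edge matrix (m x 2, 1-based).
#' @param W Weight matrix, `d_out x 2d`.
#' @param b Bias vector of length `d_out` (default 0).
#' @param activation Apply ReLU (default TRUE); the SAGPool scoring layer
#'   uses the raw affine output.
#' @return N x d_out matrix of updated node attributes.
#' @export
sage_layer <- function(node_attrs, edges, W, b = 0, activation = TRUE) {
  if (ncol(W) != 2L * ncol(node_attrs))
    stop(sprintf("W has %d columns; expected 2 x %d", ncol(W), ncol(node_attrs)))
  ops <- graph_ops(edges, nrow(node_attrs))
  Z <- cbind(node_attrs, nbr_mean(ops, node_attrs))
  out <- sweep(Z %*% t(W), 2, rep_len(b, nrow(W)), "+")
  if (activation) relu(out) else out
}

sage_forward <- function(H, ops, W, b, activation = TRUE) {
  Z <- cbind(H, nbr_mean(ops, H))
  pre <- Z %*% t(W)
  if (any(b != 0)) pre <- pre + rep(b, each = nrow(pre))
  list(out = if (activation) relu(pre) else pre, Z = Z, pre = pre,
       activation = activation)
}

sage_backward <- function(cache, ops, W, G_out) {
  G_pre <- if (cache$activation) G_out * (cache$pre > 0) else G_out
  d_in <- ncol(cache$Z) / 2L
  G_Z <- G_pre %*% W
  list(gW = crossprod(G_pre, cache$Z),
       gb = colSums(G_pre),
       gH = G_Z[, seq_len(d_in), drop = FALSE] +
         nbr_mean_t(ops, G_Z[, d_in + seq_len(d_in), drop = FALSE]))
}

# ---- self-attention graph pooling ---------------------------------------

#' Self-attention graph pooling (SAGPool)
#'
#' Scores every node with a one-dimensional GraphSAGE layer (no activation),
#' keeps the `ceiling(pool_ratio * N)` top-scoring nodes (ties broken by node
#' index), scales the kept attributes by `tanh(score)` and induces the
#' subgraph on the kept nodes.
#'
#' @param node_attrs N x d attribute matrix.
#' @param edges Undirected edge matrix.
#' @param pool_ratio Fraction of nodes to keep, in `(0, 1]`.
#' @param score_weights `1 x 2d` scoring weights.
#' @param score_bias Scalar scoring bias (default 0).
#' @return List with `node_attrs` (kept, tanh-scaled), `edges` (re-indexed
#'   induced subgraph), `kept_index` (ascending original indices) and
#'   `scores` (all N raw scores).
#' @export
sag_pool <- function(node_attrs, edges, pool_ratio = 0.5, score_weights,
                     score_bias = 0) {
  n <- nrow(node_attrs)
  if (n == 0L) stop("cannot pool an empty graph")
  stopifnot(pool_ratio > 0, pool_ratio <= 1)
  s <- as.vector(sage_layer(node_attrs, edges, score_weights, score_bias,
                            activation = FALSE))
  n_keep <- ceiling(pool_ratio * n)
  kept <- sort(order(-s, seq_len(n))[seq_len(n_keep)])
  Hp <- node_attrs[kept, , drop = FALSE] * tanh(s[kept])
  keep_map <- integer(n); keep_map[kept] <- seq_along(kept)
  e <- edges[edges[, 1] %in% kept & edges[, 2] %in% kept, , drop = FALSE]
  e <- matrix(keep_map[e], ncol = 2, dimnames = list(NULL, c("i", "j")))
  list(node_attrs = Hp, edges = e, kept_index = kept, scores = s)
}

# ---- GCN branch ----------------------------------------------------------

#' GCN branch configuration
#'
#' Three GraphSAGE convolutions (ReLU), a single SAGPool after the third,
#' per-layer mean readouts concatenated and mapped by a fully connected
#' layer to the graph embedding `z_g`.
#'
#' @param hidden_dims Output widths of the three convolution layers
#'   (default `c(256, 128, 128)`).
#' @param out_dim Embedding dimension (default 128).
#' @param pool_ratio SAGPool keep fraction (default 0.5).
#' @param readout3 Where the third readout is taken: `"post_pool"` (default;
#'   mean over the kept, tanh-scaled nodes, so the pooling layer participates
#'   in training) or `"pre_pool"` (mean over all conv3 outputs).
#' @return A `gcn_config` list.
#' @export
gcn_config <- function(hidden_dims = c(256, 128, 128), out_dim = 128L,
                       pool_ratio = 0.5,
                       readout3 = c("post_pool", "pre_pool")) {
  stopifnot(length(hidden_dims) == 3L, all(hidden_dims >= 1), out_dim >= 1,
            pool_ratio > 0, pool_ratio <= 1)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 out_dim = as.integer(out_dim), pool_ratio = pool_ratio,
                 readout3 = match.arg(readout3)),
            class = "gcn_config")
}

#' Initialize GCN branch parameters
#'
#' Weights drawn from `N(0, sd^2)` (default sd 0.01), biases zero.
#'
#' @param in_dim Node attribute dimension.
#' @param cfg A [gcn_config()].
#' @param seed RNG seed.
#' @param sd Weight init standard deviation.
#' @return Named list of parameter matrices keyed by layer name.
#' @export
gcn_init <- function(in_dim, cfg = gcn_config(), seed = 1L, sd = 0.01) {
  d <- c(in_dim, cfg$hidden_dims)
  with_seed(seed, {
    p <- list()
    for (l in 1:3) {
      p[[paste0("W", l)]] <- matrix(stats::rnorm(d[l + 1] * 2 * d[l], 0, sd),
                                    d[l + 1], 2 * d[l])
      p[[paste0("b", l)]] <- numeric(d[l + 1])
    }
    p$Wp <- matrix(stats::rnorm(2 * d[4], 0, sd), 1, 2 * d[4])
    p$bp <- 0
    p$Wf <- matrix(stats::rnorm(cfg$out_dim * sum(d[2:4]), 0, sd),
                   cfg$out_dim, sum(d[2:4]))
    p$bf <- numeric(cfg$out_dim)
    p
  })
}

gcn_forward_cached <- function(attrs, edges, cfg, params, ops = NULL) {
  n <- nrow(attrs)
  if (is.null(ops)) ops <- graph_ops(edges, n)
  c1 <- sage_forward(attrs, ops, params$W1, params$b1)
  c2 <- sage_forward(c1$out, ops, params$W2, params$b2)
  c3 <- sage_forward(c2$out, ops, params$W3, params$b3)
  H3 <- c3$out
  sc <- sage_forward(H3, ops, params$Wp, params$bp, activation = FALSE)
  s <- as.vector(sc$out)
  n_keep <- ceiling(cfg$pool_ratio * n)
  kept <- sort(order(-s, seq_len(n))[seq_len(n_keep)])
  tk <- tanh(s[kept])
  Hp <- H3[kept, , drop = FALSE] * tk
  r1 <- colMeans(c1$out)
  r2 <- colMeans(c2$out)
  r3 <- if (cfg$readout3 == "post_pool") colMeans(Hp) else colMeans(H3)
  r <- c(r1, r2, r3)
  z <- as.vector(params$Wf %*% r + params$bf)
  list(z = z, r = r, ops = ops, c1 = c1, c2 = c2, c3 = c3, sc = sc,
       s = s, kept = kept, tk = tk, H3 = H3, n = n)
}

gcn_backward <- function(cache, cfg, params, g_z) {
  d <- cfg$hidden_dims
  n <- cache$n
  g <- list(Wf = g_z %o% cache$r, bf = g_z)
  gr <- as.vector(crossprod(params$Wf, g_z))
  gr1 <- gr[seq_len(d[1])]
  gr2 <- gr[d[1] + seq_len(d[2])]
  gr3 <- gr[d[1] + d[2] + seq_len(d[3])]

  G_H3 <- matrix(0, n, d[3])
  if (cfg$readout3 == "post_pool") {
    kept <- cache$kept; k <- length(kept); tk <- cache$tk
    G_Hp <- matrix(gr3 / k, k, d[3], byrow = TRUE)
    G_H3[kept, ] <- G_Hp * tk
    g_t <- rowSums(G_Hp * cache$H3[kept, , drop = FALSE])
    g_s <- numeric(n)
    g_s[kept] <- g_t * (1 - tk^2)
    sb <- sage_backward(cache$sc, cache$ops, params$Wp, matrix(g_s, n, 1))
    g$Wp <- sb$gW; g$bp <- sb$gb
    G_H3 <- G_H3 + sb$gH
  } else {
    G_H3 <- G_H3 + matrix(gr3 / n, n, d[3], byrow = TRUE)
    g$Wp <- params$Wp * 0; g$bp <- 0
  }

  b3 <- sage_backward(cache$c3, cache$ops, params$W3, G_H3)
  g$W3 <- b3$gW; g$b3 <- b3$gb
  G_H2 <- b3$gH + matrix(gr2 / n, n, d[2], byrow = TRUE)
  b2 <- sage_backward(cache$c2, cache$ops, params$W2, G_H2)
  g$W2 <- b2$gW; g$b2 <- b2$gb
  G_H1 <- b2$gH + matrix(gr1 / n, n, d[1], byrow = TRUE)
  b1 <- sage_backward(cache$c1, cache$ops, params$W1, G_H1)
  g$W1 <- b1$gW; g$b1 <- b1$gb
  g
}

#' GCN forward pass: nuclei graph to embedding
#'
#' Runs the three GraphSAGE convolutions, the SAGPool layer, the three mean
#' readouts and the fully connected head, returning the graph-level embedding
#' `z_g` (length `cfg$out_dim`, 128 at defaults). Deterministic given
#' parameters and input, and invariant to node relabeling.
#'
#' @param graph A [nuclei_graph()], or a plain attribute matrix (then supply
#'   `edges`).
#' @param cfg A [gcn_config()].
#' @param params Parameters from [gcn_init()].
#' @param edges Edge matrix when `graph` is a matrix.
#' @return Numeric vector of length `cfg$out_dim`.
#' @export
gcn_forward <- function(graph, cfg = gcn_config(), params, edges = NULL) {
  if (inherits(graph, "nuclei_graph")) {
    attrs <- graph$node_attrs; edges <- graph$edges
  } else {
    attrs <- graph
    if (is.null(edges)) stop("`edges` required when `graph` is a matrix")
  }
  if (nrow(attrs) == 0L) stop("empty graph")
  gcn_forward_cached(attrs, edges, cfg, params)$z
}

# ---- omics branch --------------------------------------------------------

#' Omics branch configuration
#'
#' Three parallel MLPs (one per modality) mapping to a shared embedding
#' dimension, combined elementwise.
#'
#' @param hidden Named list of hidden-layer widths per modality
#'   (defaults `c(256, 64)` each).
#' @param shared_dim Common output dimension `z_o` (default 32).
#' @param combine `"sum"` (default) or `"mean"`.
#' @return An `omics_config` list.
#' @export
omics_config <- function(hidden = list(expression = c(256, 64),
                                       mutation = c(256, 64),
                                       methylation = c(256, 64)),
                         shared_dim = 32L, combine = c("sum", "mean")) {
  stopifnot(all(c("expression", "mutation", "methylation") %in% names(hidden)),
            shared_dim >= 1)
  structure(list(hidden = hidden, shared_dim = as.integer(shared_dim),
                 combine = match.arg(combine)),
            class = "omics_config")
}

mlp_init <- function(in_dim, hidden, out_dim, sd = 0.01) {
  dims <- c(in_dim, hidden, out_dim)
  lapply(seq_len(length(dims) - 1L), function(l)
    list(W = matrix(stats::rnorm(dims[l + 1] * dims[l], 0, sd),
                    dims[l + 1], dims[l]),
         b = numeric(dims[l + 1])))
}

#' Initialize omics branch parameters
#'
#' @param in_dims Named integer vector of input feature counts per modality.
#' @param cfg An [omics_config()].
#' @param seed RNG seed.
#' @param sd Weight init standard deviation (default 0.01).
#' @return Named list of per-modality MLP parameter stacks.
#' @export
omics_init <- function(in_dims, cfg = omics_config(), seed = 1L, sd = 0.01) {
  stopifnot(all(c("expression", "mutation", "methylation") %in% names(in_dims)))
  with_seed(seed, {
    out <- lapply(c("expression", "mutation", "methylation"), function(m)
      mlp_init(in_dims[[m]], cfg$hidden[[m]], cfg$shared_dim, sd))
    names(out) <- c("expression", "mutation", "methylation")
    out
  })
}

# X: n x p matrix (rows = samples); hidden layers ReLU, output linear
mlp_forward <- function(X, layers) {
  L <- length(layers)
  caches <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    pre <- sweep(H %*% t(layers[[l]]$W), 2, layers[[l]]$b, "+")
    out <- if (l < L) relu(pre) else pre
    caches[[l]] <- list(input = H, pre = pre)
    H <- out
  }
  list(out = H, caches = caches)
}

mlp_backward <- function(fw, layers, G_out) {
  L <- length(layers)
  grads <- vector("list", L)
  G <- G_out
  for (l in rev(seq_len(L))) {
    if (l < L) G <- G * (fw$caches[[l]]$pre > 0)
    grads[[l]] <- list(W = crossprod(G, fw$caches[[l]]$input),
                       b = colSums(G))
    if (l > 1L) G <- G %*% layers[[l]]$W
  }
  grads
}

#' Omics branch forward pass
#'
#' Runs each modality's feature vector through its own MLP (ReLU hidden
#' layers, linear output) to the shared dimension and combines the three
#' outputs elementwise (`sum` by default), yielding `z_o` (length 32 at
#' defaults).
#'
#' @param x Named list with `expression`, `mutation`, `methylation`: numeric
#'   vectors (one sample) or matrices (samples x features).
#' @param cfg An [omics_config()].
#' @param params Parameters from [omics_init()].
#' @return Numeric vector of length `shared_dim` (or a samples x shared_dim
#'   matrix for matrix input).
#' @export
omics_forward <- function(x, cfg = omics_config(), params) {
  single <- !is.matrix(x$expression)
  outs <- lapply(c("expression", "mutation", "methylation"), function(m) {
    X <- if (is.matrix(x[[m]])) x[[m]] else matrix(x[[m]], nrow = 1)
    if (ncol(X) != ncol(params[[m]][[1]]$W))
      stop(sprintf("%s input has %d features; model expects %d",
                   m, ncol(X), ncol(params[[m]][[1]]$W)))
    mlp_forward(X, params[[m]])$out
  })
  z <- Reduce(`+`, outs)
  if (cfg$combine == "mean") z <- z / 3
  if (single) as.vector(z) else z
}
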