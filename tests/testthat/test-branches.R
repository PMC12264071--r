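test_that("GraphSAGE layer matches by-hand mean-aggregate computation", {
  # 3-node path 1-2-3, 2 input dims, hand-set 2x4 weights
  H <- matrix(c(1, 0,
                0, 2,
                3, 1), 3, 2, byrow = TRUE)
  edges <- rbind(c(1L, 2L), c(2L, 3L))
  W <- matrix(c(1, 0, 0.5, -1,
                0, 1, 2, 0.25), 2, 4, byrow = TRUE)
  out <- sage_layer(H, edges, W)
  nb1 <- H[2, ]; nb2 <- (H[1, ] + H[3, ]) / 2; nb3 <- H[2, ]
  expected <- rbind(pmax(0, t(W %*% c(H[1, ], nb1))),
                    pmax(0, t(W %*% c(H[2, ], nb2))),
                    pmax(0, t(W %*% c(H[3, ], nb3))))
  expect_equal(out, expected, ignore_attr = TRUE)

  # zero weights annihilate everything
  expect_equal(sage_layer(H, edges, W * 0), matrix(0, 3, 2),
               ignore_attr = TRUE)

  # single isolated node: zero neighbor mean
  H1 <- matrix(c(2, -1), 1, 2)
  e0 <- matrix(integer(0), 0, 2)
  expect_equal(as.vector(sage_layer(H1, e0, W)),
               pmax(0, as.vector(W %*% c(2, -1, 0, 0))))

  expect_error(sage_layer(H, edges, matrix(0, 2, 3)), "expected")
})

test_that("SAGPool keeps the ceiling(ratio N) top-scoring nodes with index tie-break", {
  # no edges: score reduces to the first attribute via these weights
  H <- cbind(c(3, 1, 2, 0), 0)
  e0 <- matrix(integer(0), 0, 2)
  Wp <- matrix(c(1, 0, 0, 0), 1, 4)
  res <- sag_pool(H, e0, 0.5, Wp)
  expect_identical(res$kept_index, c(1L, 3L))
  expect_equal(res$node_attrs[, 1], c(3, 2) * tanh(c(3, 2)))

  # ratio 1 keeps everyone, scaled by tanh(score)
  res1 <- sag_pool(H, e0, 1, Wp)
  expect_identical(res1$kept_index, 1:4)
  expect_equal(res1$node_attrs[, 1], H[, 1] * tanh(H[, 1]))

  # uniform scores: lowest indices win
  Hu <- cbind(rep(1, 6), 0)
  resu <- sag_pool(Hu, e0, 0.5, Wp)
  expect_identical(resu$kept_index, 1:3)

  # exact keep counts across sizes and ratios
  for (ratio in c(0.25, 0.5, 0.75, 1)) {
    for (n in c(1L, 2L, 7L, 50L, 100L)) {
      Hn <- matrix(rnorm(2 * n), n, 2)
      expect_length(sag_pool(Hn, e0, ratio, Wp)$kept_index, ceiling(ratio * n))
    }
  }

  # induced subgraph is re-indexed
  Hg <- cbind(c(5, 4, 3, 2), 0)
  eg <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  rg <- sag_pool(Hg, eg, 0.5, Wp)
  expect_identical(rg$kept_index, c(1L, 2L))
  expect_equal(unname(rg$edges), matrix(c(1L, 2L), 1, 2))
})

test_that("GCN forward has the configured output dim and permutation invariance", {
  set.seed(4)
  cfg <- gcn_config(hidden_dims = c(6, 5, 4), out_dim = 12)
  n <- 15
  attrs <- matrix(rnorm(n * 9), n, 9)
  edges <- knn_edges(matrix(rnorm(2 * n), n, 2), k = 3)
  params <- gcn_init(9, cfg, seed = 2, sd = 0.2)

  z <- gcn_forward(attrs, cfg, params, edges = edges)
  expect_length(z, 12L)
  expect_identical(z, gcn_forward(attrs, cfg, params, edges = edges))

  for (rep in 1:5) {
    perm <- sample(n)
    new_pos <- match(seq_len(n), perm)
    attrs_p <- attrs[perm, ]
    edges_p <- cbind(new_pos[edges[, 1]], new_pos[edges[, 2]])
    # edge-list reordering too
    edges_p <- edges_p[sample(nrow(edges_p)), ]
    zp <- gcn_forward(attrs_p, cfg, params, edges = edges_p)
    expect_equal(zp, z, tolerance = 1e-12)
  }

  # default configuration emits a 128-d embedding
  p128 <- gcn_init(9, gcn_config(), seed = 1)
  expect_length(gcn_forward(attrs, gcn_config(), p128, edges = edges), 128L)

  # zero attributes with zero-init biases map to the zero embedding
  expect_equal(gcn_forward(attrs * 0, cfg, params, edges = edges), rep(0, 12))
  expect_error(gcn_forward(attrs[0, , drop = FALSE], cfg, params,
                           edges = matrix(integer(0), 0, 2)), "empty")
})

test_that("GCN backward matches finite differences", {
  set.seed(9)
  cfg <- gcn_config(hidden_dims = c(5, 4, 3), out_dim = 6)
  attrs <- matrix(rnorm(8 * 7), 8, 7)
  edges <- knn_edges(matrix(rnorm(16), 8, 2), k = 3)
  params <- gcn_init(7, cfg, seed = 3, sd = 0.3)
  gz <- rnorm(6)
  cache <- pathfuse:::gcn_forward_cached(attrs, edges, cfg, params)
  grads <- pathfuse:::gcn_backward(cache, cfg, params, gz)
  loss_of <- function(pp)
    sum(gz * pathfuse:::gcn_forward_cached(attrs, edges, cfg, pp)$z)
  for (nm in names(params)) {
    idx <- if (length(params[[nm]]) > 5) sample(length(params[[nm]]), 5)
           else seq_along(params[[nm]])
    for (ii in idx) {
      h <- 1e-6
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + h
      f1 <- loss_of(pp)
      pp[[nm]][ii] <- pp[[nm]][ii] - 2 * h
      f2 <- loss_of(pp)
      expect_lt(abs((f1 - f2) / (2 * h) - grads[[nm]][ii]), 1e-5)
    }
  }
})

test_that("omics branch combines three MLPs at the shared dimension", {
  set.seed(6)
  cfg <- omics_config(hidden = list(expression = c(8, 6), mutation = c(8, 6),
                                    methylation = c(8, 6)), shared_dim = 5)
  in_dims <- c(expression = 10L, mutation = 7L, methylation = 9L)
  params <- omics_init(in_dims, cfg, seed = 2, sd = 0.3)
  x <- list(expression = rnorm(10), mutation = rbinom(7, 1, 0.5),
            methylation = rnorm(9))
  z <- omics_forward(x, cfg, params)
  expect_length(z, 5L)

  # default configuration emits 32 dims
  pdef <- omics_init(in_dims, omics_config(), seed = 1)
  expect_length(omics_forward(x, omics_config(), pdef), 32L)

  # zero inputs with zero biases give the zero embedding
  x0 <- list(expression = rep(0, 10), mutation = rep(0, 7),
             methylation = rep(0, 9))
  expect_equal(omics_forward(x0, cfg, params), rep(0, 5))

  # sum combination: zeroing two modalities leaves the third branch's output
  xe <- list(expression = x$expression, mutation = rep(0, 7),
             methylation = rep(0, 9))
  ze <- omics_forward(xe, cfg, params)
  only_e <- pathfuse:::mlp_forward(matrix(x$expression, 1), params$expression)$out
  expect_equal(ze, as.vector(only_e))

  expect_error(omics_forward(list(expression = rnorm(4), mutation = x$mutation,
                                  methylation = x$methylation), cfg, params),
               "expects")
})

test_that("MLP backward matches finite differences", {
  set.seed(8)
  layers <- pathfuse:::mlp_init(6, c(5, 4), 3, sd = 0.4)
  X <- matrix(rnorm(12), 2, 6)
  G <- matrix(rnorm(6), 2, 3)
  fw <- pathfuse:::mlp_forward(X, layers)
  gr <- pathfuse:::mlp_backward(fw, layers, G)
  loss_of <- function(ll) sum(G * pathfuse:::mlp_forward(X, ll)$out)
  for (l in seq_along(layers)) for (fld in c("W", "b")) {
    for (ii in seq_len(min(5, length(layers[[l]][[fld]])))) {
      h <- 1e-6
      lp <- layers; lp[[l]][[fld]][ii] <- lp[[l]][[fld]][ii] + h
      f1 <- loss_of(lp)
      lp[[l]][[fld]][ii] <- lp[[l]][[fld]][ii] - 2 * h
      f2 <- loss_of(lp)
      expect_lt(abs((f1 - f2) / (2 * h) - gr[[l]][[fld]][ii]), 1e-5)
    }
  }
})
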