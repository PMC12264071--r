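test_that("tile QC flags background excess and nucleus-count violations", {
  white <- tile(array(255, c(130, 130, 3)), matrix(0L, 130, 130))
  qc <- tile_qc(white, tile_qc_spec(min_nuclei = 1))
  expect_false(qc$pass)
  expect_equal(qc$background_fraction, 1)
  expect_length(qc$reasons, 2)   # background AND zero nuclei

  dark_empty <- tile(array(100, c(130, 130, 3)), matrix(0L, 130, 130))
  qc2 <- tile_qc(dark_empty, tile_qc_spec(min_nuclei = 1))
  expect_false(qc2$pass)
  expect_match(qc2$reasons, "count", all = FALSE)

  # generated tissue tile with ~5% bright rows and enough nuclei passes
  tl <- make_tiles(1, seed = 21, lambda = 40, tile_size = 200,
                   bright_fraction = 0.05)[[1]]
  qc3 <- tile_qc(tl, tile_qc_spec(0.10, 10, 200))
  expect_gt(qc3$background_fraction, 0.03)
  expect_lt(qc3$background_fraction, 0.10)
  expect_true(qc3$pass)
})

test_that("morphological features recover analytic ellipse geometry", {
  sz <- 200L
  labels <- matrix(0L, sz, sz)
  rr <- matrix(rep(1:sz, sz), sz, sz)
  cc <- t(rr)
  labels[((rr - 100) / 20)^2 + ((cc - 100) / 10)^2 <= 1] <- 7L
  tl <- tile(array(120, c(sz, sz, 3)), labels)
  f <- suppressWarnings(morphological_features(tl, 7))

  expect_length(f, 17L)
  expect_identical(names(f), morpho_feature_names())
  expect_lt(abs(f[["area"]] / (pi * 20 * 10) - 1), 0.03)
  expect_lt(abs(f[["major_axis"]] / 40 - 1), 0.03)
  expect_lt(abs(f[["minor_axis"]] / 20 - 1), 0.03)
  expect_lt(abs(f[["inscribed_radius"]] / 10 - 1), 0.08)
  # constant color region
  expect_equal(unname(f[c("r_sd", "g_sd", "b_sd", "gray_sd", "gray_range",
                          "r_range", "g_range", "b_range")]),
               rep(0, 8))
  expect_equal(f[["mean_gray"]], 120)

  expect_error(morphological_features(tl, 99), "99")
})

test_that("morphological features are invariant to relabeling and translation", {
  tl <- grid_tile(6)
  f1 <- morphological_features(tl, 3)
  relab <- tl$labels
  relab[relab == 3] <- 77L
  tl2 <- tile(tl$rgb, relab)
  f2 <- morphological_features(tl2, 77)
  expect_equal(unname(f1), unname(f2))

  # translate everything by (5, 9): interior regions unchanged
  sz <- nrow(tl$labels)
  lab3 <- matrix(0L, sz + 20, sz + 20)
  rgb3 <- array(120, c(sz + 20, sz + 20, 3))
  lab3[5 + seq_len(sz), 9 + seq_len(sz)] <- tl$labels
  f3 <- morphological_features(tile(rgb3, lab3), 3)
  expect_equal(as.vector(f1), as.vector(f3))
})

test_that("patch embedding is a deterministic seeded projection", {
  tl <- grid_tile(4)
  ctr <- attr(morphological_features(tl, 2), "centroid")
  e1 <- patch_embedding(tl, ctr, size = 64, dim = 32, seed = 5)
  e2 <- patch_embedding(tl, ctr, size = 64, dim = 32, seed = 5)
  expect_identical(e1, e2)
  expect_length(e1, 32L)
  e3 <- patch_embedding(tl, ctr, size = 64, dim = 32, seed = 6)
  expect_false(isTRUE(all.equal(e1, e3)))

  zero <- tile(array(0, c(130, 130, 3)), matrix(0L, 130, 130))
  expect_equal(patch_embedding(zero, c(65, 65), size = 64, dim = 16, seed = 1),
               rep(0, 16))
})

test_that("knn edges agree with brute force and honor the k = 5 default", {
  # 3x3 unit grid, k = 2: the corner connects to its two axis neighbors
  grid <- as.matrix(expand.grid(0:2, 0:2))
  nb <- knn_neighbors(grid, 2)
  corner <- which(grid[, 1] == 0 & grid[, 2] == 0)
  expected <- sort(which((grid[, 1] + grid[, 2]) == 1 &
                           pmax(grid[, 1], grid[, 2]) == 1))
  expect_setequal(nb[[corner]], expected)

  e2 <- knn_edges(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), k = 5)
  expect_identical(nrow(e2), 1L)

  expect_warning(e0 <- knn_edges(matrix(c(0, 0), 1, 2), k = 5), "fewer")
  expect_identical(nrow(e0), 0L)

  set.seed(13)
  for (rep in 1:8) {
    n <- sample(6:200, 1)
    pts <- matrix(runif(2 * n), n, 2)
    nb <- knn_neighbors(pts, 5)
    expect_true(all(lengths(nb) == 5L))   # pre-symmetrization degree
    D <- as.matrix(dist(pts)); diag(D) <- Inf
    i <- sample(n, 3)
    for (ii in i)
      expect_identical(nb[[ii]], order(D[ii, ], seq_len(n))[1:5])
  }
})

test_that("graph construction counts nuclei, concatenates features, is deterministic", {
  tl <- grid_tile(40)
  g <- build_graph(tl, k = 5, embed_dim = 8, seed = 3)
  expect_identical(nrow(g$node_attrs), 40L)
  expect_identical(ncol(g$node_attrs), 17L + 8L)
  expect_true(all(g$edges[, 1] != g$edges[, 2]))
  expect_false(anyDuplicated(g$edges) > 0)

  g2 <- build_graph(tl, k = 5, embed_dim = 8, seed = 3)
  expect_identical(g$node_attrs, g2$node_attrs)
  expect_identical(g$edges, g2$edges)

  expect_error(build_graph(grid_tile(1)), "single nucleus")
  empty <- tile(array(100, c(130, 130, 3)), matrix(0L, 130, 130))
  expect_error(build_graph(empty), "no nuclei")
})

test_that("graph serialization round-trips through TSV", {
  g <- build_graph(grid_tile(12), k = 3, embed_dim = 4, seed = 2,
                   tile_id = "t1", patient_id = "P7")
  dir <- withr::local_tempdir()
  write_graph(g, dir)
  g2 <- read_graph(dir, "t1")
  expect_equal(g2$node_attrs, g$node_attrs, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unname(g2$edges), unname(g$edges))
  expect_identical(g2$patient_id, "P7")
})

test_that("tile image round-trip preserves pixels and labels", {
  tl <- make_tiles(1, seed = 4, tile_size = 128)[[1]]
  rgb_path <- withr::local_tempfile(fileext = ".png")
  lab_path <- withr::local_tempfile(fileext = ".tif")
  write_tile(tl, rgb_path, lab_path)
  tl2 <- read_tile(rgb_path, lab_path)
  expect_identical(tl2$labels, tl$labels)
  expect_lt(max(abs(tl2$rgb - round(tl$rgb))), 1.5)  # 8-bit quantization
})
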