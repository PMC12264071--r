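test_that("beta to M-value transform matches the closed form and round-trips", {
  b <- om(matrix(c(0.5, 0.8, 0, 1, 0.25, 0.9), 2, 3), "methylation_beta")
  m <- beta_to_m(b, epsilon = 1e-6)
  expect_equal(unclass(m)[1, 1], 0)                       # logit symmetry point
  expect_equal(unclass(m)[2, 1], 2)                       # log2(0.8/0.2)
  expect_equal(unclass(m)[1, 2], log2(1e-6 / (1 - 1e-6))) # clipped boundary
  expect_equal(unclass(m)[2, 2], log2((1 - 1e-6) / 1e-6))
  expect_identical(dimnames(m), dimnames(b))

  # inverse recovers the clipped betas
  set.seed(7)
  bb <- om(matrix(runif(60), 6, 10), "methylation_beta")
  back <- m_to_beta(beta_to_m(bb))
  expect_lt(max(abs(unclass(back) - pmin(pmax(unclass(bb), 1e-6), 1 - 1e-6))),
            1e-10)

  bad <- matrix(c(0.2, 1.4, 0.3, 0.1), 2, 2)
  expect_error(beta_to_m(om(bad, "expression")), "methylation_beta")
  # out-of-range value caught at construction already
  expect_error(om(bad, "methylation_beta"), "\\[0, 1\\]")
})

test_that("differential filter keeps exactly the planted feature on a toy table", {
  tumor <- om(cbind(f1 = c(80, 82, 78, 81), f2 = c(10, 11, 9, 10),
                    f3 = c(55, 54, 56, 53)))
  normal <- om(cbind(f1 = c(10, 11, 9, 10), f2 = c(10, 9, 11, 10),
                     f3 = c(55, 56, 54, 55)))
  colnames(normal) <- colnames(tumor)

  # oracle: Welch t on log2(x+1), BH over the three features
  p_or <- sapply(1:3, function(j)
    t.test(log2(unclass(tumor)[, j] + 1), log2(unclass(normal)[, j] + 1))$p.value)
  q_or <- p.adjust(p_or, "BH")
  lfc_or <- log2((colMeans(unclass(tumor)) + 1) / (colMeans(unclass(normal)) + 1))
  keep_or <- abs(lfc_or) > 1 & q_or < 0.05
  expect_identical(unname(keep_or), c(TRUE, FALSE, FALSE))

  res <- differential_filter(tumor, normal, filter_spec(1, 0.05))
  expect_identical(res$features, "f1")
  expect_equal(res$report$q, unname(q_or))
  expect_equal(res$report$log2fc, unname(lfc_or))
  expect_identical(colnames(res$matrix), "f1")
})

test_that("differential filter edge cases: identical groups, unattainable threshold", {
  x <- om(matrix(rep(c(5, 6, 7, 8), 3), 4, 3))
  y <- om(matrix(rep(c(5, 6, 7, 8), 3), 4, 3))
  colnames(y) <- colnames(x)
  expect_warning(r0 <- differential_filter(x, y, filter_spec(1, 0.05)),
                 "no features")
  expect_length(r0$features, 0)

  set.seed(1)
  a <- om(matrix(rexp(40, 0.1), 4, 10))
  b <- om(matrix(rexp(40, 0.01), 4, 10))
  colnames(b) <- colnames(a)
  expect_warning(rinf <- differential_filter(a, b, filter_spec(Inf, 0.05)))
  expect_length(rinf$features, 0)
})

test_that("differential filter is permutation-equivariant in samples within groups", {
  set.seed(3)
  tumor <- om(matrix(rexp(80, 0.05), 8, 10))
  normal <- om(matrix(rexp(60, 0.05), 6, 10))
  colnames(normal) <- colnames(tumor)
  r1 <- suppressWarnings(differential_filter(tumor, normal, filter_spec(0.5, 0.2)))
  pt <- sample(8); pn <- sample(6)
  tumor_p <- om(unclass(tumor)[pt, ], samples = rownames(tumor)[pt],
                feats = colnames(tumor))
  normal_p <- om(unclass(normal)[pn, ], samples = rownames(normal)[pn],
                 feats = colnames(normal))
  r2 <- suppressWarnings(differential_filter(tumor_p, normal_p, filter_spec(0.5, 0.2)))
  expect_equal(r1$report, r2$report)
})

test_that("mutation frequency filter applies a strict cut and shrinks with it", {
  m <- om(cbind(a = c(1, 1, 1, 1, 0),   # 0.8: exactly at the cut -> dropped
                b = c(1, 1, 1, 1, 1),   # 1.0: kept for any fraction < 1
                c = c(0, 0, 0, 0, 0)),
          "mutation")
  kept <- mutation_frequency_filter(m, 0.8)
  expect_identical(colnames(kept), "b")

  expect_identical(ncol(mutation_frequency_filter(
    om(matrix(0, 4, 5), "mutation"), 0.5)), 0L)

  set.seed(5)
  big <- om(matrix(rbinom(500, 1, runif(20)), 25, 20, byrow = FALSE), "mutation")
  fr <- seq(0.1, 0.9, by = 0.1)
  sizes <- sapply(fr, function(f) ncol(mutation_frequency_filter(big, f)))
  expect_true(all(diff(sizes) <= 0))

  notbin <- om(matrix(c(0, 1, 2, 1), 2, 2))
  attr(notbin, "modality") <- "mutation"
  expect_error(mutation_frequency_filter(notbin), "binary")
})

test_that("sample intersection keeps the common sorted set and errors when empty", {
  mk <- function(ids, modality = "expression") {
    v <- matrix(seq_along(ids), length(ids), 1)
    if (modality == "mutation") v <- v * 0
    if (modality == "methylation_beta") v <- v / (max(v) + 1)
    omics_matrix(v, modality, ids, "f1")
  }
  b <- intersect_samples(mk(c("A", "B", "C")),
                         mk(c("B", "C", "D"), "mutation"),
                         mk(c("C", "B"), "methylation_beta"))
  expect_identical(rownames(b$expression), c("B", "C"))
  expect_identical(rownames(b$mutation), c("B", "C"))
  expect_identical(rownames(b$methylation), c("B", "C"))

  all3 <- intersect_samples(mk(c("A", "B")), mk(c("B", "A"), "mutation"),
                            mk(c("A", "B"), "methylation_beta"))
  expect_identical(rownames(all3$expression), c("A", "B"))

  expect_error(intersect_samples(mk(c("A")), mk(c("B"), "mutation"),
                                 mk(c("C"), "methylation_beta")),
               "no samples")
})

test_that("omics TSV and long-format mutation input round-trip", {
  set.seed(11)
  x <- om(matrix(rpois(30, 20), 5, 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(x, path)
  y <- read_omics_matrix(path, "expression")
  expect_equal(unclass(y), unclass(x))

  calls <- data.frame(gene = c("TP53", "KRAS", "TP53"),
                      sample = c("s1", "s2", "s2"))
  m <- fold_mutation_calls(calls)
  expect_identical(dim(m), c(2L, 2L))
  expect_equal(unclass(m)["s2", "TP53"], 1)
  expect_equal(unclass(m)["s1", "KRAS"], 0)
})
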