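#' Tensor fusion of the two modality embeddings
#'
#' Prepends a constant 1 to each embedding and takes their outer product:
#' `Z = (1, z_g) %o% (1, z_o)`, a `(d1 + 1) x (d2 + 1)` matrix. `Z[1, 1]` is
#' always 1, the first row carries `(1, z_o)`, the first column `(1, z_g)`,
#' and the interior block all pairwise products, so the fused tensor encodes
#' every unimodal and bimodal multiplicative interaction. At the default
#' dimensions (128, 32) the tensor has 129 x 33 = 4257 entries.
#'
#' @param z_g Graph-branch embedding.
#' @param z_o Omics-branch embedding.
#' @return The fused matrix, class `fused_tensor`.
#' @export
tensor_fuse <- function(z_g, z_o) {
  stopifnot(all(is.finite(z_g)), all(is.finite(z_o)))
  Z <- outer(c(1, z_g), c(1, z_o))
  class(Z) <- c("fused_tensor", "matrix", "array")
  Z
}

#' Flatten a fused tensor row-major
#'
#' The fixed flattening convention used by the hazard head and checkpoints:
#' row-major, i.e. `Z[1, 1], Z[1, 2], ..., Z[1, d2+1], Z[2, 1], ...`.
#'
#' @param Z A [tensor_fuse()] result.
#' @return Numeric vector of length `(d1 + 1) * (d2 + 1)`.
#' @export
flatten_fused <- function(Z) as.vector(t(unclass(Z)))

#' Linear hazard head on the fused tensor
#'
#' `theta = <W, Z> + b` with output dimension 1, the log-relative-hazard
#' score of one patient. `W` may be given in the shape of `Z` or as a vector
#' matching the row-major flattening.
#'
#' @param Z A fused tensor (matrix) or its flattened vector.
#' @param W Weights, same shape as `Z` or a flat vector.
#' @param b Scalar bias (default 0).
#' @return Scalar theta.
#' @export
hazard_head <- function(Z, W, b = 0) {
  z <- if (is.matrix(Z)) flatten_fused(Z) else as.numeric(Z)
  w <- if (is.matrix(W)) as.vector(t(W)) else as.numeric(W)
  if (length(w) != length(z))
    stop(sprintf("W has %d entries; Z has %d", length(w), length(z)))
  sum(w * z) + b
}

#' Negative Cox partial log-likelihood
#'
#' The training loss of every stage:
#' `loss = -sum over events i of (theta_i - log sum over risk set of
#' exp(theta_j))`, where the risk set of patient i is every patient j with
#' `t_j >= t_i` (Breslow convention: patients tied with i are included).
#' Minimizing this maximizes the Cox partial log-likelihood of the observed
#' event ordering. With no events the loss is 0 (with a warning): censored
#' patients alone carry no ordering information.
#'
#' @param theta Per-patient log-hazard scores.
#' @param times Survival / follow-up times.
#' @param events Event indicators (1 = death observed, 0 = censored).
#' @return Scalar loss (non-negative for any theta when every risk set has
#'   more than one member is not guaranteed; a lone event contributes 0).
#' @export
cox_pll_loss <- function(theta, times, events) {
  n <- length(theta)
  stopifnot(length(times) == n, length(events) == n,
            all(events %in% c(0, 1)))
  if (sum(events) == 0) {
    warning("no events: Cox partial likelihood is constant (loss 0)")
    return(0)
  }
  lse <- risk_set_logsumexp(theta, times)
  -sum((theta - lse)[events == 1])
}

# log sum over {j : t_j >= t_i} of exp(theta_j), per patient, tie-aware
risk_set_logsumexp <- function(theta, times) {
  n <- length(theta)
  ord <- order(times, decreasing = TRUE)
  th <- theta[ord]; tt <- times[ord]
  lse_sorted <- numeric(n)
  run_max <- -Inf; run_sum <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && tt[j + 1L] == tt[i]) j <- j + 1L
    blk <- th[i:j]
    m <- max(run_max, max(blk))
    run_sum <- run_sum * exp(run_max - m) + sum(exp(blk - m))
    run_max <- m
    lse_sorted[i:j] <- run_max + log(run_sum)
    i <- j + 1L
  }
  lse <- numeric(n)
  lse[ord] <- lse_sorted
  lse
}

#' Gradient of the Cox partial-likelihood loss
#'
#' Analytic gradient of [cox_pll_loss()] with respect to `theta`:
#' `d loss / d theta_k = -(C_k - exp(theta_k) * sum over events i with
#' t_i <= t_k of 1 / S_i)` where `S_i` is the risk-set sum of patient i.
#'
#' @inheritParams cox_pll_loss
#' @return Numeric vector, same length as `theta`.
#' @export
cox_pll_grad <- function(theta, times, events) {
  n <- length(theta)
  stopifnot(length(times) == n, length(events) == n)
  if (sum(events) == 0) return(numeric(n))
  lse <- risk_set_logsumexp(theta, times)
  inv_s <- events * exp(-lse)          # 1/S_i at events, 0 elsewhere
  ord <- order(times)                  # ascending: accumulate events with t_i <= t_k
  tt <- times[ord]
  cum <- cumsum(inv_s[ord])
  # patients tied in time share the same accumulated value (t_i <= t_k
  # includes ties, matching the Breslow risk sets)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && tt[j + 1L] == tt[i]) j <- j + 1L
    cum[i:j] <- cum[j]
    i <- j + 1L
  }
  A <- numeric(n); A[ord] <- cum
  -(events - exp(theta) * A)
}

#' Aggregate tile embeddings into one patient embedding
#'
#' @param z_list Non-empty list of equal-length tile embeddings.
#' @param combine `"mean"` (default) or `"max"`, elementwise.
#' @return One embedding vector.
#' @export
patient_embedding <- function(z_list, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  if (length(z_list) == 0L) stop("no tile embeddings to aggregate")
  M <- do.call(cbind, z_list)
  if (combine == "mean") rowMeans(M) else apply(M, 1, max)
}
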