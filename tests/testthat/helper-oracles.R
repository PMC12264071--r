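# Independent brute-force oracles used across the suite. These deliberately
# enumerate definitions directly (risk sets, all pairs, product-limit) and
# share no code with the implementation paths they check.

# Cox partial log-likelihood by explicit R_ij enumeration
bf_cox_loss <- function(theta, times, events) {
  s <- 0
  for (i in seq_along(theta)) {
    if (events[i] == 1) {
      risk_set <- which(times >= times[i])
      s <- s + theta[i] - log(sum(exp(theta[risk_set])))
    }
  }
  -s
}

# Harrell's C by explicit all-pairs enumeration
bf_cindex <- function(theta, times, events) {
  n <- length(theta)
  conc <- ties <- comp <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (times[i] == times[j]) {
      if (events[i] + events[j] != 1) next
      hi <- if (events[i] == 1) i else j   # the event patient should score higher
      lo <- if (events[i] == 1) j else i
    } else {
      first <- if (times[i] < times[j]) i else j
      if (events[first] == 0) next
      hi <- first
      lo <- if (first == i) j else i
    }
    comp <- comp + 1
    if (theta[hi] > theta[lo]) conc <- conc + 1
    else if (theta[hi] == theta[lo]) ties <- ties + 1
  }
  if (comp == 0) stop("no comparable pairs")
  (conc + 0.5 * ties) / comp
}

# Kaplan-Meier product-limit by direct recursion over distinct times
bf_km <- function(times, events) {
  ts <- sort(unique(times))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(times >= ts[k])
    d <- sum(times == ts[k] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# central finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# tile with nuclei planted on a regular grid (exact count, no overlap)
grid_tile <- function(n, radius = 5, spacing = 16, value = 120) {
  side <- ceiling(sqrt(n))
  sz <- max(128L, side * spacing + 2L * spacing)
  labels <- matrix(0L, sz, sz)
  rgb <- array(value, c(sz, sz, 3))
  k <- 0L
  for (i in seq_len(side)) for (j in seq_len(side)) {
    if (k >= n) break
    k <- k + 1L
    cr <- spacing * i; cc <- spacing * j
    for (r in (cr - radius):(cr + radius)) for (c2 in (cc - radius):(cc + radius))
      if ((r - cr)^2 + (c2 - cc)^2 <= radius^2) labels[r, c2] <- k
  }
  tile(rgb, labels)
}

# small omics matrix constructor; keeps existing dimnames when present
om <- function(values, modality = "expression", samples = NULL, feats = NULL) {
  if (is.null(samples))
    samples <- if (!is.null(rownames(values))) rownames(values)
               else paste0("S", seq_len(nrow(values)))
  if (is.null(feats))
    feats <- if (!is.null(colnames(values))) colnames(values)
             else paste0("f", seq_len(ncol(values)))
  omics_matrix(values, modality, samples, feats)
}
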