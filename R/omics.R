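#' Construct an omics matrix
#'
#' A thin validated container for a samples x features matrix of one omics
#' modality. Rows are samples, columns are features; dimnames carry the ids.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param modality One of `"expression"`, `"mutation"`, `"methylation_beta"`,
#'   `"methylation_M"`. Mutation matrices must be binary; beta-values must lie
#'   in `[0, 1]`.
#' @param sample_ids,feature_ids Optional identifier vectors; default to the
#'   dimnames of `values`.
#'
#' @return An object of class `omics_matrix`: the matrix with a `modality`
#'   attribute and validated ids.
#' @export
omics_matrix <- function(values, modality = c("expression", "mutation",
                                              "methylation_beta", "methylation_M"),
                         sample_ids = rownames(values),
                         feature_ids = colnames(values)) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("sample and feature ids are required (as dimnames or arguments)")
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != nrow(values)")
  if (length(feature_ids) != ncol(values))
    stop("length(feature_ids) != ncol(values)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (ncol(values) > 0 && anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (modality == "mutation" && length(values) &&
      !all(values %in% c(0, 1)))
    stop("mutation matrix must be binary (0/1)")
  if (modality == "methylation_beta" && length(values) &&
      (anyNA(values) || any(values < 0) || any(values > 1)))
    stop("methylation beta-values must lie in [0, 1]")
  dimnames(values) <- list(as.character(sample_ids), as.character(feature_ids))
  structure(values, modality = modality, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d samples x %d features\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  invisible(x)
}

modality_of <- function(x) attr(x, "modality")

#' Restrict an omics matrix to a feature subset
#'
#' @param x An `omics_matrix`.
#' @param features Character vector of feature ids to keep; original column
#'   order is preserved regardless of the order given here.
#' @return An `omics_matrix` with the kept columns.
#' @export
subset_features <- function(x, features) {
  stopifnot(inherits(x, "omics_matrix"))
  keep <- colnames(x)[colnames(x) %in% features]
  omics_matrix(unclass(x)[, keep, drop = FALSE], modality = modality_of(x),
               sample_ids = rownames(x), feature_ids = keep)
}

#' Beta-value to M-value transform
#'
#' Maps methylation beta-values onto the approximately homoscedastic M-value
#' scale, `M = log2(b / (1 - b))`, after clipping betas into
#' `[epsilon, 1 - epsilon]` so boundary values stay finite.
#'
#' @param beta An `omics_matrix` with modality `methylation_beta`.
#' @param epsilon Clipping margin, strictly positive (default `1e-6`).
#' @return An `omics_matrix` with modality `methylation_M`, same shape and ids.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  stopifnot(inherits(beta, "omics_matrix"))
  if (modality_of(beta) != "methylation_beta")
    stop("beta_to_m() expects a methylation_beta matrix")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive number")
  bad <- which(is.na(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta-value outside [0, 1] at sample '%s', feature '%s'",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]))
  }
  b <- pmin(pmax(unclass(beta), epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  omics_matrix(m, modality = "methylation_M",
               sample_ids = rownames(beta), feature_ids = colnames(beta))
}

#' Inverse of the M-value transform
#'
#' @param m An `omics_matrix` with modality `methylation_M`.
#' @return Beta-values `2^M / (2^M + 1)` as a `methylation_beta` matrix.
#' @export
m_to_beta <- function(m) {
  stopifnot(inherits(m, "omics_matrix"), modality_of(m) == "methylation_M")
  b <- 1 / (1 + 2^(-unclass(m)))
  omics_matrix(b, modality = "methylation_beta",
               sample_ids = rownames(m), feature_ids = colnames(m))
}

#' Differential-feature filter settings
#'
#' @param lfc_threshold Minimum absolute log2 fold change (default 1).
#' @param fdr_threshold Benjamini-Hochberg adjusted p-value cut-off
#'   (default 0.05).
#' @param mutation_min_fraction Minimum mutation frequency for
#'   [mutation_frequency_filter()] (default 0.8, applied strictly).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(lfc_threshold = 1, fdr_threshold = 0.05,
                        mutation_min_fraction = 0.8) {
  stopifnot(is.numeric(lfc_threshold), length(lfc_threshold) == 1L,
            lfc_threshold >= 0,
            is.numeric(fdr_threshold), length(fdr_threshold) == 1L,
            fdr_threshold > 0, fdr_threshold < 1,
            is.numeric(mutation_min_fraction),
            mutation_min_fraction > 0, mutation_min_fraction <= 1)
  structure(list(lfc_threshold = lfc_threshold,
                 fdr_threshold = fdr_threshold,
                 mutation_min_fraction = mutation_min_fraction),
            class = "filter_spec")
}

#' Tumor-versus-normal differential feature filter
#'
#' Keeps features whose absolute log2 fold change between tumor and normal
#' exceeds `spec$lfc_threshold` and whose Welch t-test p-value, adjusted by
#' Benjamini-Hochberg, is below `spec$fdr_threshold`. The fold change is
#' computed on group mean values with a pseudocount
#' (`log2((mean_t + pc) / (mean_n + pc))`); for matrices already on a log-like
#' scale (M-values) use `lfc_method = "difference"`, which takes the plain
#' mean difference instead. The t-test runs on `log2(x + 1)` by default, the
#' conventional variance-stabilised scale for counts; use
#' `test_scale = "raw"` for data already on a test-ready scale.
#'
#' @param tumor,normal `omics_matrix` objects sharing the same feature ids;
#'   at least two samples per group.
#' @param spec A [filter_spec()].
#' @param lfc_method `"ratio"` (pseudocounted mean ratio) or `"difference"`.
#' @param pseudocount Pseudocount added to group means under
#'   `lfc_method = "ratio"` (default 1).
#' @param test_scale `"log2p1"` or `"raw"`.
#' @return A list with `features` (kept ids, original order), `matrix` (the
#'   tumor matrix restricted to kept features) and `report` (per-feature
#'   data frame: `feature`, `log2fc`, `p`, `q`, `kept`).
#' @export
differential_filter <- function(tumor, normal, spec = filter_spec(),
                                lfc_method = c("ratio", "difference"),
                                pseudocount = 1,
                                test_scale = c("log2p1", "raw")) {
  stopifnot(inherits(tumor, "omics_matrix"), inherits(normal, "omics_matrix"),
            inherits(spec, "filter_spec"))
  lfc_method <- match.arg(lfc_method)
  test_scale <- match.arg(test_scale)
  if (!identical(colnames(tumor), colnames(normal)))
    stop("tumor and normal must share identical feature ids")
  if (nrow(tumor) < 2L || nrow(normal) < 2L)
    stop("need at least two samples per group")

  xt <- unclass(tumor); xn <- unclass(normal)
  mt <- colMeans(xt); mn <- colMeans(xn)
  lfc <- if (lfc_method == "ratio") {
    log2((mt + pseudocount) / (mn + pseudocount))
  } else {
    mt - mn
  }

  tt <- if (test_scale == "log2p1") log2(xt + 1) else xt
  tn <- if (test_scale == "log2p1") log2(xn + 1) else xn
  p <- vapply(seq_len(ncol(tt)), function(j) {
    a <- tt[, j]; b <- tn[, j]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  kept <- abs(lfc) > spec$lfc_threshold & q < spec$fdr_threshold
  kept[is.na(kept)] <- FALSE

  if (!any(kept))
    warning("differential_filter: no features passed the thresholds")
  features <- colnames(tumor)[kept]
  list(features = features,
       matrix = subset_features(tumor, features),
       report = data.frame(feature = colnames(tumor),
                           log2fc = unname(lfc), p = unname(p), q = unname(q),
                           kept = unname(kept), row.names = NULL))
}

#' Mutation-frequency filter
#'
#' Keeps mutation sites whose frequency (column mean of the binary matrix)
#' is strictly greater than `min_fraction` — "over" the cut, so a site at
#' exactly the threshold is dropped.
#'
#' @param mut A binary `omics_matrix` with modality `mutation`.
#' @param min_fraction Frequency cut in `(0, 1]`.
#' @return The filtered `omics_matrix`; the per-feature frequencies are
#'   attached as attribute `"frequencies"`.
#' @export
mutation_frequency_filter <- function(mut, min_fraction = 0.8) {
  stopifnot(inherits(mut, "omics_matrix"))
  if (modality_of(mut) != "mutation")
    stop("mutation_frequency_filter() expects a mutation matrix")
  if (length(mut) && !all(unclass(mut) %in% c(0, 1)))
    stop("mutation matrix must be binary (0/1)")
  freq <- colMeans(unclass(mut))
  out <- subset_features(mut, colnames(mut)[freq > min_fraction])
  attr(out, "frequencies") <- freq
  out
}

#' Intersect samples across the three omics modalities
#'
#' Restricts expression, mutation and methylation matrices to the samples
#' present in all three, in sorted (deterministic) order.
#'
#' @param expression,mutation,methylation `omics_matrix` objects.
#' @return An `omics_bundle`: a list of the three matrices with identical,
#'   identically ordered sample ids.
#' @export
intersect_samples <- function(expression, mutation, methylation) {
  for (m in list(expression, mutation, methylation))
    stopifnot(inherits(m, "omics_matrix"))
  common <- sort(Reduce(intersect, list(rownames(expression),
                                        rownames(mutation),
                                        rownames(methylation))))
  if (length(common) == 0L)
    stop("no samples are shared across the three modalities")
  take <- function(m) omics_matrix(unclass(m)[common, , drop = FALSE],
                                   modality = modality_of(m),
                                   sample_ids = common,
                                   feature_ids = colnames(m))
  structure(list(expression = take(expression),
                 mutation = take(mutation),
                 methylation = take(methylation)),
            class = "omics_bundle")
}

#' @export
print.omics_bundle <- function(x, ...) {
  cat(sprintf("<omics_bundle> %d samples | expression %d, mutation %d, methylation %d features\n",
              nrow(x$expression), ncol(x$expression), ncol(x$mutation),
              ncol(x$methylation)))
  invisible(x)
}

#' Read / write omics matrices as TSV
#'
#' Layout: first column is the sample id, header row carries feature ids.
#'
#' @param path File path (tab-separated).
#' @param modality Modality tag for the returned matrix.
#' @return `read_omics_matrix` returns an `omics_matrix`;
#'   `write_omics_matrix` invisibly returns `path`.
#' @export
read_omics_matrix <- function(path, modality) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  omics_matrix(vals, modality = modality, sample_ids = ids,
               feature_ids = colnames(df)[-1L])
}

#' @rdname read_omics_matrix
#' @param x An `omics_matrix` to write.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(sample_id = rownames(x), unclass(x),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fold a long-format mutation table into a binary matrix
#'
#' Accepts MAF-like long records (one row per observed mutation) with a gene
#' and a sample column and returns the samples x genes 0/1 matrix.
#'
#' @param calls Data frame with at least the columns named by `gene_col`
#'   and `sample_col`.
#' @param gene_col,sample_col Column names (defaults `"gene"`, `"sample"`).
#' @return An `omics_matrix` with modality `mutation`.
#' @export
fold_mutation_calls <- function(calls, gene_col = "gene", sample_col = "sample") {
  stopifnot(is.data.frame(calls),
            all(c(gene_col, sample_col) %in% names(calls)))
  samples <- sort(unique(as.character(calls[[sample_col]])))
  genes <- sort(unique(as.character(calls[[gene_col]])))
  m <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(calls[[sample_col]], samples),
          match(calls[[gene_col]], genes))] <- 1
  omics_matrix(m, modality = "mutation")
}
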