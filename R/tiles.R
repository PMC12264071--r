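#' Histology tile with nuclei instance labels
#'
#' @param rgb H x W x 3 numeric array of 8-bit intensities (0-255).
#' @param labels H x W integer matrix; 0 = background, k > 0 = nucleus k.
#'   Label ids must be positive but need not be contiguous.
#' @return A `tile` object.
#' @export
tile <- function(rgb, labels) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("`rgb` must be an H x W x 3 array")
  if (!is.matrix(labels) || !all(dim(labels) == dim(rgb)[1:2]))
    stop("`labels` must be an H x W matrix matching `rgb`")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("rgb intensities must lie in [0, 255]")
  structure(list(rgb = rgb, labels = labels), class = "tile")
}

#' @export
print.tile <- function(x, ...) {
  cat(sprintf("<tile> %d x %d px, %d nuclei\n", nrow(x$labels), ncol(x$labels),
              length(tile_label_ids(x))))
  invisible(x)
}

tile_label_ids <- function(tile) {
  u <- unique(as.vector(tile$labels))
  sort(u[u > 0])
}

# Conventional luminance used to separate background (glass) from tissue.
luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Tile quality-control settings
#'
#' @param max_background_fraction Maximum tolerated fraction of background
#'   pixels (default 0.10); a tile at or above the cut fails.
#' @param min_nuclei,max_nuclei Accepted nucleus-count interval, the
#'   operational reading of "moderate nuclei density" (defaults 10 and 2000
#'   for a 1000 x 1000 tile).
#' @param background_luminance 8-bit luminance above which a pixel counts as
#'   background glass (default 220).
#' @return A `tile_qc_spec` list.
#' @export
tile_qc_spec <- function(max_background_fraction = 0.10,
                         min_nuclei = 10, max_nuclei = 2000,
                         background_luminance = 220) {
  stopifnot(max_background_fraction > 0, max_background_fraction < 1,
            min_nuclei <= max_nuclei)
  structure(list(max_background_fraction = max_background_fraction,
                 min_nuclei = min_nuclei, max_nuclei = max_nuclei,
                 background_luminance = background_luminance),
            class = "tile_qc_spec")
}

#' Tile quality control
#'
#' Fails a tile when the background fraction (pixels brighter than the
#' background luminance threshold) reaches `max_background_fraction`, or the
#' nucleus count falls outside `[min_nuclei, max_nuclei]`. Never raises on a
#' valid tile; all violated rules are enumerated.
#'
#' @param x A [tile()].
#' @param spec A [tile_qc_spec()].
#' @return A list: `pass` (logical), `reasons` (character, empty on pass),
#'   `background_fraction`, `n_nuclei`.
#' @export
tile_qc <- function(x, spec = tile_qc_spec()) {
  stopifnot(inherits(x, "tile"), inherits(spec, "tile_qc_spec"))
  bg <- mean(luminance(x$rgb) > spec$background_luminance)
  n <- length(tile_label_ids(x))
  reasons <- character(0)
  if (bg >= spec$max_background_fraction)
    reasons <- c(reasons, sprintf(
      "background fraction %.3f >= %.3f", bg, spec$max_background_fraction))
  if (n < spec$min_nuclei)
    reasons <- c(reasons, sprintf("nucleus count %d < %d", n, spec$min_nuclei))
  if (n > spec$max_nuclei)
    reasons <- c(reasons, sprintf("nucleus count %d > %d", n, spec$max_nuclei))
  list(pass = length(reasons) == 0L, reasons = reasons,
       background_fraction = bg, n_nuclei = n)
}

#' Names of the 17 morphological features, in their fixed order
#' @export
morpho_feature_names <- function() {
  c("area", "minor_axis", "major_axis", "inscribed_radius",
    "mean_r", "mean_g", "mean_b", "mean_gray", "gray_range",
    "r_range", "g_range", "b_range", "r_sd", "g_sd", "b_sd",
    "gray_sd", "nearest_dist")
}

# Centroids (row, col) of every labelled nucleus, in sorted label order.
all_centroids <- function(labels) {
  idx <- which(labels > 0)
  lab <- labels[idx]
  rc <- arrayInd(idx, dim(labels))
  sums <- rowsum(rc, lab)
  counts <- as.vector(table(lab))
  cent <- sums / counts
  rownames(cent) <- rownames(sums)
  cent[order(as.numeric(rownames(cent))), , drop = FALSE]
}

# Maximum inscribed-circle radius of a pixel region: the largest distance
# from an interior pixel to the region's complement (computed on a 1-pixel
# padded bounding box so regions touching the tile border stay bounded).
inscribed_radius <- function(rc) {
  r0 <- min(rc[, 1]) - 1L; r1 <- max(rc[, 1]) + 1L
  c0 <- min(rc[, 2]) - 1L; c1 <- max(rc[, 2]) + 1L
  h <- r1 - r0 + 1L; w <- c1 - c0 + 1L
  mask <- matrix(FALSE, h, w)
  mask[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- TRUE
  comp <- which(!mask, arr.ind = TRUE)
  reg <- which(mask, arr.ind = TRUE)
  # nearest complement pixel is always adjacent to the region, so restricting
  # the complement to a dilation ring would be an optimization; regions are
  # small enough that the direct form is fine
  d2 <- outer(reg[, 1], comp[, 1], "-")^2 + outer(reg[, 2], comp[, 2], "-")^2
  row_min <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
  sqrt(max(row_min))
}

sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

morpho_one <- function(x, label_id, centroids) {
  idx <- which(x$labels == label_id)
  if (length(idx) == 0L)
    stop(sprintf("label id %s not present in mask", format(label_id)))
  rc <- arrayInd(idx, dim(x$labels))
  area <- nrow(rc)
  ctr <- colMeans(rc)

  # second-moment (image-moment) ellipse; axis lengths 4*sqrt(eigenvalue)
  # so a filled ellipse with semi-axes (a, b) yields major 2a, minor 2b
  mu <- stats::cov(rc) * (area - 1) / area
  if (area == 1L) mu <- matrix(0, 2, 2)
  ev <- eigen(mu, symmetric = TRUE, only.values = TRUE)$values
  major <- 4 * sqrt(max(ev[1], 0))
  minor <- 4 * sqrt(max(ev[2], 0))

  insc <- inscribed_radius(rc)

  r <- x$rgb[cbind(rc, 1L)]
  g <- x$rgb[cbind(rc, 2L)]
  b <- x$rgb[cbind(rc, 3L)]
  gray <- 0.299 * r + 0.587 * g + 0.114 * b

  if (nrow(centroids) > 1L) {
    others <- centroids[rownames(centroids) != as.character(label_id), ,
                        drop = FALSE]
    nnd <- sqrt(min((others[, 1] - ctr[1])^2 + (others[, 2] - ctr[2])^2))
  } else {
    warning("single nucleus in tile: nearest-cell distance set to 0")
    nnd <- 0
  }

  v <- c(area, minor, major, insc,
         mean(r), mean(g), mean(b), mean(gray), diff(range(gray)),
         diff(range(r)), diff(range(g)), diff(range(b)),
         sd0(r), sd0(g), sd0(b), sd0(gray), nnd)
  names(v) <- morpho_feature_names()
  list(morpho = v, centroid = ctr)
}

#' Morphological features of one nucleus
#'
#' Computes the 17-feature vector for a labelled nucleus: area (px^2), minor
#' and major axis lengths of the second-moment ellipse (px), maximum
#' inscribed-circle radius (px), per-channel and gray mean / range / standard
#' deviation, and the centroid distance to the nearest other nucleus.
#'
#' @param x A [tile()].
#' @param label_id Instance label present in the mask.
#' @return Named numeric vector of length 17, ordered as
#'   [morpho_feature_names()]. The nucleus centroid (row, col) is attached as
#'   attribute `"centroid"`.
#' @export
morphological_features <- function(x, label_id) {
  stopifnot(inherits(x, "tile"))
  cent <- all_centroids(x$labels)
  res <- morpho_one(x, label_id, cent)
  structure(res$morpho, centroid = res$centroid)
}

# cache for random-projection matrices (regenerating a 1024 x 12288 draw per
# nucleus would dominate run time)
.pf_proj_cache <- new.env(parent = emptyenv())

projection_matrix <- function(seed, dim, len) {
  key <- sprintf("s%d_d%d_l%d", seed, dim, len)
  if (!is.null(.pf_proj_cache[[key]])) return(.pf_proj_cache[[key]])
  P <- with_seed(seed, matrix(stats::rnorm(dim * len), dim, len) / sqrt(len))
  rm(list = setdiff(ls(.pf_proj_cache), key), envir = .pf_proj_cache)
  .pf_proj_cache[[key]] <- P
  P
}

#' Patch embedding of the region around a nucleus
#'
#' Default encoder: a seeded, fixed Gaussian random projection of the
#' flattened, zero-mean `size x size` RGB patch centered on the nucleus
#' (zero-padded at tile borders) to `dim` values. Deterministic for a fixed
#' seed; any drop-in encoder with the same signature can replace it via the
#' `encoder` argument of [build_graph()].
#'
#' @param x A [tile()].
#' @param centroid Numeric (row, col) center of the patch.
#' @param size Patch side length in px, even (default 64).
#' @param dim Embedding dimension (default 1024).
#' @param seed Seed fixing the projection.
#' @return Numeric vector of length `dim`.
#' @export
patch_embedding <- function(x, centroid, size = 64L, dim = 1024L, seed = 1L) {
  stopifnot(inherits(x, "tile"), size %% 2 == 0, size > 0, dim > 0)
  h <- nrow(x$labels); w <- ncol(x$labels)
  r0 <- round(centroid[1]) - size / 2 + 1L
  c0 <- round(centroid[2]) - size / 2 + 1L
  patch <- array(0, c(size, size, 3))
  rr <- max(1L, r0):min(h, r0 + size - 1L)
  cc <- max(1L, c0):min(w, c0 + size - 1L)
  if (length(rr) > 0 && length(cc) > 0)
    patch[rr - r0 + 1L, cc - c0 + 1L, ] <- x$rgb[rr, cc, , drop = FALSE]
  v <- as.vector(patch)
  v <- v - mean(v)
  P <- projection_matrix(as.integer(seed), as.integer(dim), length(v))
  as.numeric(P %*% v)
}

#' K-nearest-neighbor lists and edges over nucleus centroids
#'
#' `knn_neighbors` returns, for every node, the indices of its
#' `min(k, N - 1)` nearest Euclidean neighbors with a deterministic tie-break
#' by (distance, node index). `knn_edges` symmetrizes those directed
#' neighborhoods into an undirected edge set.
#'
#' @param centroids N x 2 matrix of (row, col) positions.
#' @param k Neighbors per node (default 5).
#' @return `knn_neighbors`: list of integer vectors. `knn_edges`: integer
#'   matrix with columns `i`, `j` (`i < j`), unique rows, sorted; a 0-row
#'   matrix with a warning when N < 2.
#' @export
knn_neighbors <- function(centroids, k = 5L) {
  n <- nrow(centroids)
  D <- as.matrix(stats::dist(centroids))
  diag(D) <- Inf
  lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))
    ord[seq_len(min(k, n - 1L))]
  })
}

#' @rdname knn_neighbors
#' @export
knn_edges <- function(centroids, k = 5L) {
  n <- nrow(centroids)
  if (n < 2L) {
    warning("fewer than 2 nodes: no edges")
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  nb <- knn_neighbors(centroids, k)
  i <- rep(seq_len(n), lengths(nb))
  j <- unlist(nb)
  e <- cbind(i = pmin(i, j), j = pmax(i, j))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Node-attributed nuclei spatial graph
#'
#' @param node_attrs N x (17 + E) attribute matrix (morphology then
#'   embedding).
#' @param edges m x 2 undirected edge matrix (1-based node indices,
#'   `i < j`, unique, no self-loops).
#' @param centroids N x 2 centroid matrix.
#' @param tile_id,patient_id Identifiers.
#' @return A `nuclei_graph` object.
#' @export
nuclei_graph <- function(node_attrs, edges, centroids,
                         tile_id = "tile", patient_id = NA_character_) {
  n <- nrow(node_attrs)
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    canon <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(canon)) stop("duplicate edges")
  }
  stopifnot(nrow(centroids) == n)
  structure(list(node_attrs = node_attrs, edges = edges,
                 centroids = centroids, tile_id = tile_id,
                 patient_id = patient_id),
            class = "nuclei_graph")
}

#' @export
print.nuclei_graph <- function(x, ...) {
  cat(sprintf("<nuclei_graph> %s: %d nodes (%d attrs), %d edges\n",
              x$tile_id, nrow(x$node_attrs), ncol(x$node_attrs),
              nrow(x$edges)))
  invisible(x)
}

#' Build the nuclei spatial graph of a tile
#'
#' Extracts the 17 morphological features and the patch embedding for every
#' nucleus, concatenates them into node attributes (length `17 + embed_dim`,
#' 1041 at defaults), and connects nuclei by symmetrized k-nearest-neighbor
#' edges over their centroids.
#'
#' @param x A [tile()]; must contain at least two nuclei.
#' @param k Neighbors per nucleus (default 5).
#' @param embed_dim Patch-embedding dimension (default 1024).
#' @param seed Seed for the default patch encoder.
#' @param patch_size Side of the embedding patch (default 64).
#' @param tile_id,patient_id Identifiers stored on the graph.
#' @param encoder Optional replacement encoder
#'   `function(tile, centroid) -> numeric(embed_dim)`.
#' @return A [nuclei_graph()].
#' @export
build_graph <- function(x, k = 5L, embed_dim = 1024L, seed = 1L,
                        patch_size = 64L, tile_id = "tile",
                        patient_id = NA_character_, encoder = NULL) {
  stopifnot(inherits(x, "tile"))
  labs <- tile_label_ids(x)
  if (length(labs) == 0L) stop("tile contains no nuclei")
  if (length(labs) == 1L) stop("tile contains a single nucleus; need >= 2 to build a graph")
  cent <- all_centroids(x$labels)
  if (is.null(encoder))
    encoder <- function(tl, ctr)
      patch_embedding(tl, ctr, size = patch_size, dim = embed_dim, seed = seed)
  feats <- lapply(labs, function(id) morpho_one(x, id, cent))
  morpho <- do.call(rbind, lapply(feats, `[[`, "morpho"))
  centroids <- do.call(rbind, lapply(feats, `[[`, "centroid"))
  embeds <- do.call(rbind, lapply(seq_along(labs), function(i)
    encoder(x, centroids[i, ])))
  attrs <- cbind(morpho, embeds)
  colnames(attrs) <- c(morpho_feature_names(),
                       paste0("embed_", seq_len(ncol(embeds))))
  nuclei_graph(attrs, knn_edges(centroids, k), centroids,
               tile_id = tile_id, patient_id = patient_id)
}

#' Serialize / load a nuclei graph
#'
#' On-disk layout under `dir`: `<prefix>_nodes.tsv` (node id, centroid,
#' 17 morphology columns), `<prefix>_edges.tsv` (i, j) and
#' `<prefix>_embed.tsv` (embedding matrix). All files are plain TSV.
#'
#' @param graph A [nuclei_graph()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; defaults to the tile id.
#' @return `write_graph` invisibly returns the directory; `read_graph`
#'   returns the [nuclei_graph()].
#' @export
write_graph <- function(graph, dir, prefix = graph$tile_id) {
  stopifnot(inherits(graph, "nuclei_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- morpho_feature_names()
  nodes <- data.frame(id = seq_len(nrow(graph$node_attrs)),
                      row = graph$centroids[, 1], col = graph$centroids[, 2],
                      graph$node_attrs[, nm, drop = FALSE],
                      check.names = FALSE, row.names = NULL)
  utils::write.table(nodes, file.path(dir, paste0(prefix, "_nodes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(graph$edges),
                     file.path(dir, paste0(prefix, "_edges.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emb <- graph$node_attrs[, setdiff(colnames(graph$node_attrs), nm),
                          drop = FALSE]
  utils::write.table(as.data.frame(emb),
                     file.path(dir, paste0(prefix, "_embed.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(tile_id = graph$tile_id, patient_id = graph$patient_id)
  utils::write.table(meta, file.path(dir, paste0(prefix, "_meta.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_graph
#' @export
read_graph <- function(dir, prefix) {
  nodes <- utils::read.delim(file.path(dir, paste0(prefix, "_nodes.tsv")),
                             check.names = FALSE)
  edges <- as.matrix(utils::read.delim(
    file.path(dir, paste0(prefix, "_edges.tsv"))))
  emb <- as.matrix(utils::read.delim(
    file.path(dir, paste0(prefix, "_embed.tsv")), check.names = FALSE))
  meta <- utils::read.delim(file.path(dir, paste0(prefix, "_meta.tsv")),
                            colClasses = "character")
  attrs <- cbind(as.matrix(nodes[, morpho_feature_names(), drop = FALSE]),
                 emb)
  if (nrow(edges) == 0L) edges <- matrix(integer(0), 0, 2)
  nuclei_graph(attrs, edges,
               centroids = as.matrix(nodes[, c("row", "col")]),
               tile_id = meta$tile_id[1], patient_id = meta$patient_id[1])
}

#' Read / write a tile as image files
#'
#' The RGB image is an 8-bit PNG; the instance label mask a 16-bit grayscale
#' TIFF (8-bit PNG cannot hold more than 255 label ids).
#'
#' @param rgb_path,labels_path File paths.
#' @export
read_tile <- function(rgb_path, labels_path) {
  rgb <- round(png::readPNG(rgb_path) * 255)
  if (length(dim(rgb)) == 3L && dim(rgb)[3] == 4L) rgb <- rgb[, , 1:3]
  labels <- round(tiff::readTIFF(labels_path) * 65535)
  tile(rgb, matrix(as.integer(labels), nrow(labels), ncol(labels)))
}

#' @rdname read_tile
#' @param x A [tile()] to write.
#' @export
write_tile <- function(x, rgb_path, labels_path) {
  stopifnot(inherits(x, "tile"))
  png::writePNG(x$rgb / 255, rgb_path)
  tiff::writeTIFF(x$labels / 65535, labels_path, bits.per.sample = 16L)
  invisible(rgb_path)
}
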