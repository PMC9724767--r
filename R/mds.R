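#' Pairwise Euclidean distances between samples
#'
#' Distances are computed between sample columns over all probes in the
#' supplied (typically signature-restricted) beta matrix. Missing values
#' must be imputed first.
#'
#' @param m Beta matrix (probes x samples) with no missing values.
#' @return A symmetric samples x samples distance matrix with zero
#'   diagonal.
#' @export
euclidean_distances <- function(m) {
  validate_beta_matrix(m)
  if (anyNA(m))
    stop("matrix contains missing values; run impute_missing() first")
  as.matrix(stats::dist(t(m), method = "euclidean"))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix, eigendecomposes it, and
#' returns the top-k principal coordinates scaled by the square roots of
#' their eigenvalues. On Euclidean-realizable input with full k this
#' reproduces the distances exactly. The sign of each coordinate column is
#' fixed so that its largest-magnitude entry is positive, making embeddings
#' reproducible.
#'
#' @param D Symmetric distance matrix with zero diagonal (sample ids as
#'   dimnames).
#' @param k Number of dimensions (default 2); must not exceed the number of
#'   positive eigenvalues of the centred Gram matrix.
#' @return Object of class \code{mds_embedding}: \code{sample_ids},
#'   \code{coordinates} (samples x k, columns centred), \code{eigenvalues}
#'   (all, descending), and \code{negative_eigenvalues} kept for
#'   diagnostics.
#' @export
classical_mds <- function(D, k = 2) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) ||
      any(abs(diag(D)) > 1e-12))
    stop("D must be a symmetric distance matrix with zero diagonal")
  if (k < 1) stop("k must be >= 1")
  n <- nrow(D)
  fit <- stats::cmdscale(D, k = min(k, n - 1), eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > max(eig) * 1e-10)
  if (k > n_pos)
    stop("k = ", k, " exceeds the number of positive eigenvalues; ",
         "maximum usable k is ", n_pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  ids <- rownames(D)
  if (is.null(ids)) ids <- sprintf("sample_%d", seq_len(n))
  dimnames(coords) <- list(ids, sprintf("dim%d", seq_len(k)))
  structure(list(sample_ids = ids, coordinates = coords,
                 eigenvalues = sort(eig, decreasing = TRUE),
                 negative_eigenvalues = sum(eig < 0)),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("Classical MDS embedding: %d samples in %d dimensions\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  ev <- x$eigenvalues[x$eigenvalues > 0]
  cat(sprintf("  variance along kept axes: %s\n",
              paste(sprintf("%.1f%%",
                            100 * x$eigenvalues[seq_len(ncol(x$coordinates))] /
                              sum(ev)), collapse = ", ")))
  invisible(x)
}

#' Plot an MDS embedding
#'
#' Scatter of the first two embedding dimensions, coloured by group when
#' labels are given.
#'
#' @param x An \code{mds_embedding}.
#' @param labels Optional per-sample group labels (order of
#'   \code{x$sample_ids}).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mds_embedding <- function(x, labels = NULL, ...) {
  co <- x$coordinates
  if (ncol(co) < 2) co <- cbind(co, 0)
  col <- if (is.null(labels)) "grey30" else as.integer(factor(labels)) + 1L
  graphics::plot(co[, 1], co[, 2], col = col, pch = 19,
                 xlab = "MDS dimension 1", ylab = "MDS dimension 2", ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))) + 1L, pch = 19,
                     bty = "n")
  invisible(x)
}

#' Cluster-separation metrics for an embedding
#'
#' Silhouette coefficients (Euclidean, on the embedding coordinates) per
#' sample and per group, plus the ratio of between-centroid distance to
#' mean within-group spread. Groups with a single sample have no defined
#' silhouette and are flagged.
#'
#' @param embedding An [classical_mds()] result.
#' @param labels Per-sample group labels, in \code{embedding$sample_ids}
#'   order.
#' @return A list: \code{silhouette} (data.frame sample_id, group, width),
#'   \code{mean_silhouette}, \code{group_silhouette} (named means),
#'   \code{centroid_spread_ratio}, \code{singleton_groups}.
#' @export
separation_metrics <- function(embedding, labels) {
  stopifnot(inherits(embedding, "mds_embedding"))
  co <- embedding$coordinates
  if (length(labels) != nrow(co))
    stop("labels must match the number of embedded samples")
  f <- factor(labels)
  if (nlevels(f) < 2)
    stop("separation metrics need at least 2 groups")
  singletons <- names(which(table(f) < 2))
  keep <- !(f %in% singletons)
  if (nlevels(droplevels(f[keep])) < 2)
    stop("fewer than 2 groups with >= 2 samples; silhouette undefined")
  sil <- cluster::silhouette(as.integer(droplevels(f[keep])),
                             stats::dist(co[keep, , drop = FALSE]))
  widths <- sil[, "sil_width"]
  df <- data.frame(sample_id = embedding$sample_ids[keep],
                   group = as.character(f[keep]), width = widths,
                   stringsAsFactors = FALSE)
  centroids <- apply(co, 2, function(v) tapply(v, f, mean))
  spread <- tapply(seq_along(f), f, function(i) {
    cen <- colMeans(co[i, , drop = FALSE])
    mean(sqrt(rowSums(sweep(co[i, , drop = FALSE], 2, cen)^2)))
  })
  cd <- mean(stats::dist(centroids))
  ratio <- cd / mean(spread, na.rm = TRUE)
  list(silhouette = df,
       mean_silhouette = mean(widths),
       group_silhouette = tapply(df$width, df$group, mean),
       centroid_spread_ratio = unname(ratio),
       singleton_groups = singletons)
}

#' Write embedding coordinates to TSV
#' @param embedding An \code{mds_embedding}.
#' @param path Output path (columns sample_id, dim1..dimk).
#' @return \code{path}, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "mds_embedding"))
  co <- embedding$coordinates
  out <- data.frame(sample_id = embedding$sample_ids,
                    apply(co, 2, formatC, digits = 15, format = "g"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
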