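#' Hierarchical clustering with Pearson distance and average linkage
#'
#' Agglomerative (UPGMA) clustering of samples or features on the distance
#' `1 - r`, `r` being the Pearson correlation between item profiles. The
#' `1 - r` distance is invariant to per-item affine rescaling with positive
#' slope, so clustering reflects profile shape, not level.
#'
#' @param expr log2 feature x sample matrix.
#' @param axis `"samples"` (default) clusters columns; `"features"` clusters
#'   rows.
#' @return A `lnc_dendrogram` wrapping the [stats::hclust()] result
#'   (`merge`, `height`, `order`, item labels).
#' @export
pearson_average_hclust <- function(expr, axis = c("samples", "features")) {
  axis <- match.arg(axis)
  check_expr(expr, min_samples = if (axis == "samples") 2L else 1L)
  m <- if (axis == "samples") expr else t(expr)
  if (ncol(m) < 2L) rlang::abort("Need >= 2 items to cluster.")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    rlang::abort(sprintf("Zero-variance item(s): %s",
                         paste(head(colnames(m)[sds == 0], 5), collapse = ", ")))
  }
  d <- as.dist(1 - cor(m))
  hc <- hclust(d, method = "average")
  structure(list(hclust = hc, axis = axis, labels = colnames(m)),
            class = "lnc_dendrogram")
}

#' @export
print.lnc_dendrogram <- function(x, ...) {
  cat(sprintf("<lnc_dendrogram> %d %s, average linkage on 1 - Pearson r\n",
              length(x$labels), x$axis))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' @param dend A `lnc_dendrogram` from [pearson_average_hclust()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Tibble with `item` and `cluster` (integer labels 1..k).
#' @export
cut_tree <- function(dend, k) {
  stopifnot(inherits(dend, "lnc_dendrogram"))
  n <- length(dend$labels)
  k <- check_count(k, "k")
  if (k > n) rlang::abort("`k` cannot exceed the number of items.")
  cl <- cutree(dend$hclust, k = k)
  tibble::tibble(item = dend$labels, cluster = unname(cl))
}

#' Export a dendrogram as Newick
#'
#' @param dend A `lnc_dendrogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "lnc_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Principal component analysis by singular value decomposition
#'
#' Column-centers the sample profiles (features are centered, not scaled)
#' and decomposes by SVD. Component signs are fixed so the largest-magnitude
#' loading of each component is positive, making outputs deterministic.
#'
#' @param expr log2 feature x sample matrix (samples are observations).
#' @param n_components Number of components to retain
#'   (`<= min(n_samples, n_features)`).
#' @param center Center each feature before decomposition (default `TRUE`).
#' @return A `pca_result` list: `scores` (samples x components tibble),
#'   `loadings` (features x components matrix), `explained` (variance
#'   fractions).
#' @export
pca_svd <- function(expr, n_components = 3L, center = TRUE) {
  check_expr(expr, min_samples = 2L)
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(dim(expr))) {
    rlang::abort("`n_components` exceeds min(n_features, n_samples).")
  }
  pc <- prcomp(t(expr), center = center, scale. = FALSE)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| entry positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  structure(list(
    scores = dplyr::bind_cols(
      tibble::tibble(sample_id = colnames(expr)),
      tibble::as_tibble(scores)
    ),
    loadings = load,
    explained = expl
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; explained: %s\n",
              length(x$explained),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @describeIn pca_svd Scatter plot of two principal components.
#' @param object A `pca_result`.
#' @param x_comp,y_comp Components to draw.
#' @param colour Optional vector (one value per sample) mapped to colour.
#' @param ... Unused.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, x_comp = 1L, y_comp = 2L,
                                colour = NULL, ...) {
  df <- object$scores
  xn <- paste0("PC", x_comp)
  yn <- paste0("PC", y_comp)
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xn]], .data[[yn]])) +
    ggplot2::geom_point(
      if (!is.null(colour)) ggplot2::aes(colour = .data$colour)
    ) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xn, 100 * object$explained[x_comp]),
      y = sprintf("%s (%.1f%%)", yn, 100 * object$explained[y_comp]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}
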