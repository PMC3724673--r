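# Correlation-matrix PCA of frequency matrices, complete-linkage
# clustering for the heatmap row ordering, and PC-vs-covariate OLS.

# Accepts either a matrix with genome rownames or a tibble whose first
# column (or a column named genome_id) holds the ids.
as_freq_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix must have genome ids as rownames")
    return(x)
  }
  x <- as.data.frame(x)
  idcol <- if ("genome_id" %in% names(x)) "genome_id" else names(x)[1]
  ids <- as.character(x[[idcol]])
  m <- as.matrix(x[setdiff(names(x), idcol)])
  rownames(m) <- ids
  m
}

#' Correlation-matrix PCA of a frequency matrix
#'
#' Principal component analysis of genomes-by-categories proportions using
#' the correlation matrix: every column is centred and scaled to unit
#' variance before the eigendecomposition, so each amino acid or codon
#' contributes equally regardless of its mean abundance. Zero-variance
#' columns are dropped with a warning. Eigenvector signs are arbitrary in
#' principle; to make runs reproducible PC1 is oriented to correlate
#' positively with `%AT` when `at` is supplied, and every remaining
#' component is oriented so its largest-magnitude loading is positive.
#'
#' @param x Frequency matrix: genomes x categories, as a matrix with
#'   rownames or a tibble with a `genome_id` column (rows should sum to 1).
#' @param at Optional per-genome %AT vector (aligned with the rows) used to
#'   orient the first component.
#' @return An object of class `cb_pca` with elements `scores` (tibble:
#'   `genome_id`, `PC1`, ...), `loadings` (tibble: `category`, `PC1`, ...),
#'   `variance_fraction`, `sdev`, `center`, `scale` and `dropped` (names of
#'   zero-variance columns).
#' @export
pca_correlation <- function(x, at = NULL) {
  m <- as_freq_matrix(x)
  if (nrow(m) < 3L) abort("correlation-matrix PCA needs at least 3 genomes")
  v <- apply(m, 2, var)
  dropped <- colnames(m)[v == 0]
  if (length(dropped)) {
    warn(paste0("dropping zero-variance column(s): ", paste(dropped, collapse = ", ")))
    m <- m[, v > 0, drop = FALSE]
  }
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  # deterministic sign convention
  for (j in seq_len(ncol(p$rotation))) {
    flip <- FALSE
    if (j == 1L && !is.null(at)) {
      flip <- cor(p$x[, 1], at) < 0
    } else {
      l <- p$rotation[, j]
      flip <- l[which.max(abs(l))] < 0
    }
    if (flip) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    scores = as_tibble(p$x, rownames = "genome_id"),
    loadings = as_tibble(p$rotation, rownames = "category"),
    variance_fraction = vf,
    sdev = p$sdev,
    center = p$center,
    scale = p$scale,
    dropped = dropped
  ), class = "cb_pca")
}

#' @export
print.cb_pca <- function(x, ...) {
  cat("Correlation-matrix PCA:", nrow(x$scores), "genomes,",
      nrow(x$loadings), "categories\n")
  vf <- round(100 * x$variance_fraction[seq_len(min(5, length(x$variance_fraction)))], 1)
  cat("Variance explained (%):", paste(vf, collapse = ", "),
      if (length(x$variance_fraction) > 5) "...\n" else "\n")
  invisible(x)
}

#' Regress a principal component on a covariate
#'
#' Ordinary least squares of per-genome component scores on a numeric
#' covariate (e.g. %AT) or a categorical one (e.g. phylum, dummy-coded).
#' Reports the coefficient of determination and the overall F-test p-value.
#'
#' @param scores Numeric vector of per-genome scores.
#' @param covariate Numeric vector or factor/character of the same length.
#' @return One-row tibble: `r_squared`, `p_value`, `df`, `n`.
#' @export
regress_component_on_covariate <- function(scores, covariate) {
  if (length(scores) != length(covariate)) abort("inputs must have equal length")
  if (is.character(covariate)) covariate <- factor(covariate)
  if ((is.factor(covariate) && nlevels(droplevels(covariate)) < 2L) ||
      (is.numeric(covariate) && var(covariate) == 0)) {
    abort("covariate is constant: degenerate model")
  }
  fit <- lm(scores ~ covariate)
  s <- summary(fit)
  p <- unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3], lower.tail = FALSE))
  tibble(r_squared = s$r.squared, p_value = p,
         df = unname(s$fstatistic[2]), n = length(scores))
}

#' Complete-linkage clustering of genomes
#'
#' Agglomerative hierarchical clustering of the rows of a frequency matrix
#' with Euclidean distance and complete linkage (merges by farthest pair),
#' the combination used for composition heatmaps. Rows are sorted by genome
#' id before clustering so that ties are broken deterministically.
#'
#' @param x Frequency matrix as in [pca_correlation()].
#' @return Object of class `cb_dendrogram`: a list with the underlying
#'   `hclust` object, `labels`, and `leaf_order` (genome ids in dendrogram
#'   order).
#' @export
cluster_genomes <- function(x) {
  m <- as_freq_matrix(x)
  if (nrow(m) < 2L) abort("clustering needs at least 2 genomes")
  if (anyDuplicated(rownames(m))) abort("duplicate genome ids")
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  structure(list(hclust = hc, labels = rownames(m),
                 leaf_order = hc$labels[hc$order]),
            class = "cb_dendrogram")
}

#' @export
print.cb_dendrogram <- function(x, ...) {
  cat("Complete-linkage dendrogram over", length(x$labels), "genomes\n")
  cat("Merge heights:", paste(signif(range(x$hclust$height), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from the complete-linkage merge heights.
#' Requires the `ape` package.
#'
#' @param dendrogram A [cluster_genomes()] result.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the 'ape' package")
  }
  phy <- ape::as.phylo(dendrogram$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Order a frequency matrix and its annotations for heatmap rendering
#'
#' Permutes the rows of a frequency matrix to dendrogram leaf order and
#' aligns per-genome annotations (%AT, phylum) as side-bar tables, the
#' plot-ready inputs of a clustered composition heatmap.
#'
#' @param x Frequency matrix as in [pca_correlation()].
#' @param dendrogram A [cluster_genomes()] result over the same genomes.
#' @param annotations Tibble with `genome_id` plus annotation columns
#'   (e.g. `at_fraction`, `phylum`).
#' @param dir Optional directory; when given, `heatmap_matrix.tsv` and
#'   `heatmap_annotations.tsv` are written there.
#' @return List with `matrix` (tibble in leaf order) and `annotations`.
#' @export
export_heatmap_inputs <- function(x, dendrogram, annotations, dir = NULL) {
  m <- as_freq_matrix(x)
  ord <- dendrogram$leaf_order
  if (!setequal(rownames(m), ord)) abort("matrix and dendrogram genomes differ")
  if (!setequal(annotations$genome_id, ord)) abort("annotation genomes differ")
  m <- m[ord, , drop = FALSE]
  ann <- annotations[match(ord, annotations$genome_id), , drop = FALSE]
  out <- list(matrix = as_tibble(m, rownames = "genome_id"), annotations = ann)
  if (!is.null(dir)) {
    write_results_tsv(out$matrix, file.path(dir, "heatmap_matrix.tsv"))
    write_results_tsv(out$annotations, file.path(dir, "heatmap_annotations.tsv"))
  }
  out
}

#' @rdname pca_correlation
#' @param x A `cb_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.cb_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"category",
                      names_to = "component", values_to = "loading")
}

#' @rdname pca_correlation
#' @exportS3Method generics::glance
#' @export
glance.cb_pca <- function(x, ...) {
  tibble(n_genomes = nrow(x$scores),
         n_categories = nrow(x$loadings),
         pc1_variance_fraction = x$variance_fraction[1],
         pc2_variance_fraction = x$variance_fraction[2],
         n_dropped_columns = length(x$dropped))
}

#' @rdname pca_correlation
#' @param object A `cb_pca` object.
#' @param colour_by Optional per-genome vector mapped to point colour.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cb_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  lab <- function(j) sprintf("PC%d (%.1f%%)", j, 100 * object$variance_fraction[j])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour_by)) {
    df$colour_by <- colour_by
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$colour_by)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Plot a dendrogram as ggplot segments
#'
#' @param object A `cb_dendrogram` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cb_dendrogram <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_y <- hc$height
  segs <- vector("list", nrow(hc$merge))
  getx <- function(v) if (v < 0) xpos[-v] else node_x[v]
  gety <- function(v) if (v < 0) 0 else node_y[v]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- getx(a); xb <- getx(b)
    node_x[i] <- (xa + xb) / 2
    segs[[i]] <- tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(gety(a), gety(b), node_y[i]), yend = c(node_y[i], node_y[i], node_y[i])
    )
  }
  segdf <- dplyr::bind_rows(segs)
  leaves <- tibble(x = xpos, label = hc$labels)
  ggplot2::ggplot(segdf) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "Complete-linkage height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
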