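## Sample-level global structure: Pearson correlation with average-linkage
## clustering, and PCA of the (log-transformed) expression matrix.

apply_transform <- function(v, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (transform == "log2p1") log2(v + 1) else v
}

#' Pairwise Pearson correlation between samples, with clustering
#'
#' Computes the full symmetric matrix of Pearson correlation coefficients
#' between sample expression profiles (after an optional `log2(x + 1)`
#' transform, the default, since tag counts span orders of magnitude) and
#' clusters the samples by average linkage on the distance `1 - r`.
#'
#' @param x a `"norm_matrix"` or numeric matrix (loci x samples).
#' @param transform `"log2p1"` (default) or `"none"`.
#' @param allow_constant if `FALSE` (default), a zero-variance sample
#'   profile is an error; if `TRUE`, its correlations are `NA`
#'   and clustering is skipped.
#' @return An object of class `"sample_similarity"`: list with
#'   `sample_ids`, `correlation` (symmetric, unit diagonal) and `hclust`
#'   (average-linkage merge tree, or `NULL` if `NA`s were allowed through).
#' @export
sample_correlation <- function(x, transform = c("log2p1", "none"),
                               allow_constant = FALSE) {
  v <- apply_transform(as_values(x), transform)
  if (ncol(v) < 2L) stop("need at least 2 samples")
  if (nrow(v) < 2L) stop("need at least 2 loci")
  sds <- apply(v, 2L, stats::sd)
  hc <- NULL
  if (any(sds == 0)) {
    if (!allow_constant)
      stop("constant expression profile (zero variance) for sample(s): ",
           paste(colnames(v)[sds == 0], collapse = ", "))
    r <- suppressWarnings(stats::cor(v))
  } else {
    r <- stats::cor(v)
    diag(r) <- 1
    hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  }
  structure(list(sample_ids = colnames(v), correlation = r, hclust = hc),
            class = "sample_similarity")
}

#' @export
print.sample_similarity <- function(x, digits = 3, ...) {
  cat("Pairwise Pearson correlation between",
      length(x$sample_ids), "samples\n")
  print(round(x$correlation, digits))
  invisible(x)
}

#' Export the sample dendrogram as a Newick string
#'
#' @param x a `"sample_similarity"` from [sample_correlation()].
#' @param path optional file to write to.
#' @return The Newick string, invisibly when written to file.
#' @export
similarity_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "sample_similarity"))
  if (is.null(x$hclust)) stop("no clustering available (NA correlations)")
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Principal component analysis of a DGE matrix
#'
#' Singular value decomposition of the (optionally log2(x+1)-transformed,
#' locus-centered) matrix with samples as observations.  The sign of every
#' component is fixed so that its largest-magnitude loading is positive,
#' making results deterministic across platforms.
#'
#' @param x a `"norm_matrix"` or numeric matrix (loci x samples).
#' @param transform `"log2p1"` (default) or `"none"`.
#' @param center centre each locus across samples (default `TRUE`).
#' @return An object of class `"dge_pca"`: list with `scores`
#'   (samples x components), `loadings` (loci x components) and
#'   `variance_explained` (per-component variances summing to the total
#'   variance of the transformed matrix).
#' @export
dge_pca <- function(x, transform = c("log2p1", "none"), center = TRUE) {
  v <- apply_transform(as_values(x), transform)
  if (ncol(v) < 2L) stop("need at least 2 samples")
  if (all(v == 0)) stop("all-zero matrix")
  p <- stats::prcomp(t(v), center = center, scale. = FALSE)
  ## deterministic sign: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  p$rotation[, flip] <- -p$rotation[, flip, drop = FALSE]
  p$x[, flip] <- -p$x[, flip, drop = FALSE]
  structure(list(scores = p$x, loadings = p$rotation,
                 variance_explained = p$sdev^2),
            class = "dge_pca")
}

#' @export
print.dge_pca <- function(x, ...) {
  ve <- x$variance_explained
  cat("PCA of DGE matrix:", nrow(x$scores), "samples,",
      length(ve), "components\n")
  cat("Proportion of variance:",
      paste(sprintf("%.3f", ve / sum(ve)), collapse = " "), "\n")
  invisible(x)
}

#' Scatter plot of two principal components
#'
#' @param pca a `"dge_pca"`.
#' @param i,j component indices to plot on x and y.
#' @param ... passed to [graphics::plot()].
#' @return `NULL`, invisibly.
#' @export
pca_plot <- function(pca, i = 1, j = 2, ...) {
  stopifnot(inherits(pca, "dge_pca"))
  s <- pca$scores
  ve <- pca$variance_explained / sum(pca$variance_explained)
  graphics::plot(s[, i], s[, j], type = "n",
                 xlab = sprintf("PC%d (%.1f%%)", i, 100 * ve[i]),
                 ylab = sprintf("PC%d (%.1f%%)", j, 100 * ve[j]), ...)
  graphics::text(s[, i], s[, j], labels = rownames(s))
  invisible(NULL)
}
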