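#' Define a two-group contrast
#'
#' @param group_r,group_g disjoint, non-empty sample-id sets; `group_r`
#'   plays the role of R (numerator of M), `group_g` of G.
#' @param label_r,label_g display names for the two groups.
#' @return A list of class `"contrast"`.
#' @examples
#' genotype_contrast <- contrast(c("A", "B", "E", "F"), c("C", "D"),
#'                               "C600", "Roberta")
#' @export
contrast <- function(group_r, group_g, label_r = "R", label_g = "G") {
  group_r <- as.character(group_r)
  group_g <- as.character(group_g)
  if (!length(group_r) || !length(group_g))
    stop("both groups must be non-empty")
  if (length(intersect(group_r, group_g)))
    stop("groups overlap: ",
         paste(intersect(group_r, group_g), collapse = ", "))
  structure(list(group_r = group_r, group_g = group_g,
                 label_r = label_r, label_g = label_g),
            class = "contrast")
}

#' M and A statistics for a pair of mean expression values
#'
#' `M = log2(R + c) - log2(G + c)` is the log-ratio and
#' `A = (log2(R + c) + log2(G + c)) / 2` the average log expression, for
#' pseudocount `c`.
#'
#' @param mean_r,mean_g non-negative mean normalized tag counts
#'   (vectorized).
#' @param pseudocount non-negative pseudocount `c` (default 0).
#' @return A list with numeric elements `m` and `a`.
#' @examples
#' ma_stats(474, 147)  # vernalized vs untreated worked example
#' @export
ma_stats <- function(mean_r, mean_g, pseudocount = 0) {
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  if (any(mean_r < 0) || any(mean_g < 0)) stop("means must be non-negative")
  if (any(mean_r + pseudocount <= 0) || any(mean_g + pseudocount <= 0))
    stop("zero mean with zero pseudocount: M and A are undefined")
  lr <- log2(mean_r + pseudocount)
  lg <- log2(mean_g + pseudocount)
  list(m = lr - lg, a = (lr + lg) / 2)
}

#' Two-group differential expression with a pooled-variance t-test
#'
#' For each locus, a two-sided pooled-variance Student t-test on
#' `log2(normalized + pseudocount)` between the two groups of the
#' contrast.  The pooled variance is floored at `var_floor` (on the log2
#' scale) so that loci with identical values in every sample get a zero
#' statistic and p-value 1 rather than a 0/0.  No multiple-testing
#' correction is applied to the DE call (a Benjamini-Hochberg FDR column
#' is emitted for information only).
#'
#' @param x a `"norm_matrix"` or numeric matrix (loci x samples).
#' @param contrast a [contrast()]; both groups need at least 2 samples.
#' @param alpha significance threshold for the `is_de` flag (default
#'   0.01, on the raw p-value).
#' @param pseudocount pseudocount for the log transform, the M/A
#'   statistics and the test (default 1).
#' @param var_floor minimum pooled variance on the log2 scale.
#' @return A `data.frame` of class `"de_table"` with columns `locus_id`,
#'   `mean_r`, `mean_g`, `m`, `a`, `statistic`, `df`, `p_value`,
#'   `bh_fdr`, `is_de`.
#' @export
genotype_de <- function(x, contrast, alpha = 0.01, pseudocount = 1,
                        var_floor = 1e-8) {
  stopifnot(inherits(contrast, "contrast"))
  v <- as_values(x)
  miss <- setdiff(c(contrast$group_r, contrast$group_g), colnames(v))
  if (length(miss))
    stop("contrast samples not in matrix: ", paste(miss, collapse = ", "))
  n1 <- length(contrast$group_r)
  n2 <- length(contrast$group_g)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples for the t-test; for single-sample ",
         "groups use the fold-change statistics from ma_stats() directly")
  lx <- log2(v + pseudocount)
  xr <- lx[, contrast$group_r, drop = FALSE]
  xg <- lx[, contrast$group_g, drop = FALSE]
  m1 <- rowMeans(xr)
  m2 <- rowMeans(xg)
  ss1 <- rowSums((xr - m1)^2)
  ss2 <- rowSums((xg - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- pmax((ss1 + ss2) / df, var_floor)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  mean_r <- rowMeans(v[, contrast$group_r, drop = FALSE])
  mean_g <- rowMeans(v[, contrast$group_g, drop = FALSE])
  ma <- ma_stats(mean_r, mean_g, pseudocount)
  out <- data.frame(locus_id = rownames(v), mean_r = mean_r,
                    mean_g = mean_g, m = ma$m, a = ma$a,
                    statistic = tstat, df = df, p_value = p,
                    bh_fdr = stats::p.adjust(p, method = "BH"),
                    is_de = p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  attr(out, "alpha") <- alpha
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("de_table", "data.frame")
  out
}

#' Full MA/DE table with an optional large-locus restriction
#'
#' Runs [genotype_de()] on all loci and, when `large_locus_ids` is given,
#' reports the restriction of the same table to that subset (as used for
#' "large transcript loci" MA plots), with the DE count of each.
#'
#' @inheritParams genotype_de
#' @param large_locus_ids optional character vector of locus ids; must be
#'   a subset of the matrix loci.
#' @return A list with elements `full` (the complete `"de_table"`),
#'   `large` (the restricted table or `NULL`), `n_de_full` and
#'   `n_de_large`.
#' @export
ma_table <- function(x, contrast, large_locus_ids = NULL, alpha = 0.01,
                     pseudocount = 1, var_floor = 1e-8) {
  full <- genotype_de(x, contrast, alpha = alpha,
                      pseudocount = pseudocount, var_floor = var_floor)
  large <- NULL
  n_de_large <- NA_integer_
  if (!is.null(large_locus_ids)) {
    stray <- setdiff(large_locus_ids, full$locus_id)
    if (length(stray))
      stop("large_locus_ids not in matrix: ",
           paste(utils::head(stray, 10L), collapse = ", "),
           if (length(stray) > 10L) ", ...")
    large <- full[full$locus_id %in% large_locus_ids, , drop = FALSE]
    rownames(large) <- NULL
    n_de_large <- sum(large$is_de)
  }
  list(full = full, large = large,
       n_de_full = sum(full$is_de), n_de_large = n_de_large)
}

#' MA scatter plot of a DE table
#'
#' Average log expression A on the x-axis, log-ratio M on the y-axis, DE
#' loci highlighted.
#'
#' @param de a `"de_table"` from [genotype_de()].
#' @param ... passed to [graphics::plot()].
#' @return `NULL`, invisibly.
#' @export
ma_plot <- function(de, ...) {
  stopifnot(inherits(de, "de_table"))
  graphics::plot(de$a, de$m, pch = 20, cex = 0.4,
                 col = ifelse(de$is_de, "red", "grey40"),
                 xlab = "A (average log2 expression)",
                 ylab = "M (log2 ratio)", ...)
  graphics::abline(h = 0, col = "blue")
  invisible(NULL)
}
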