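#' Configuration of the locus screens
#'
#' @param expression_floor minimum normalized tag count for a locus to
#'   count as "expressed" (default 10, the matrix retention floor).
#' @param correlation_threshold Pearson threshold for the seed-locus
#'   screen, in (0, 1] (default 0.95).
#' @param induction_fold minimum fold increase under treatment for the
#'   induction screen (default 2).
#' @param similarity_max_fold maximum max/min fold spread across untreated
#'   samples still counting as "similar expression" (default 1.5).
#' @param pseudocount pseudocount used in every fold-change ratio
#'   (default 1), taming zeros.
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(expression_floor = 10,
                          correlation_threshold = 0.95,
                          induction_fold = 2,
                          similarity_max_fold = 1.5,
                          pseudocount = 1) {
  if (correlation_threshold <= 0 || correlation_threshold > 1)
    stop("'correlation_threshold' must be in (0, 1]")
  if (induction_fold < 1) stop("'induction_fold' must be >= 1")
  if (similarity_max_fold < 1) stop("'similarity_max_fold' must be >= 1")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  if (expression_floor < 0) stop("'expression_floor' must be >= 0")
  structure(list(expression_floor = expression_floor,
                 correlation_threshold = correlation_threshold,
                 induction_fold = induction_fold,
                 similarity_max_fold = similarity_max_fold,
                 pseudocount = pseudocount),
            class = "screen_config")
}

#' Pseudocounted fold change
#'
#' `(numerator + c) / (denominator + c)` with the pseudocount `c`.
#'
#' @param numerator,denominator non-negative values (vectorized).
#' @param pseudocount non-negative pseudocount (default 1).
#' @return Numeric fold change(s).
#' @examples
#' fold_change(1410, 474)  # ~3-fold GA enhancement on top of vernalization
#' @export
fold_change <- function(numerator, denominator, pseudocount = 1) {
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  if (any(denominator + pseudocount <= 0))
    stop("zero denominator with zero pseudocount")
  (numerator + pseudocount) / (denominator + pseudocount)
}

#' Rank loci by up-regulation in a vernalized sample
#'
#' Restricts to loci expressed (at or above `expression_floor`) in both
#' the non-vernalized and the vernalized sample, then ranks by
#' pseudocounted fold change vernalized / non-vernalized, descending.
#' Ties are broken by vernalized-sample expression, then locus id.
#'
#' @param x a `"norm_matrix"` or numeric matrix.
#' @param vern_sample,nonvern_sample sample ids.
#' @param config a [screen_config()].
#' @return A `data.frame` of class `"screen_report"` with columns
#'   `locus_id`, `nonvern`, `vern`, `fold` and `rank`.
#' @export
rank_vernalization_response <- function(x, vern_sample, nonvern_sample,
                                        config = screen_config()) {
  v <- as_values(x)
  miss <- setdiff(c(vern_sample, nonvern_sample), colnames(v))
  if (length(miss)) stop("unknown sample id: ", paste(miss, collapse = ", "))
  vv <- v[, vern_sample]
  nv <- v[, nonvern_sample]
  keep <- vv >= config$expression_floor & nv >= config$expression_floor
  fold <- fold_change(vv[keep], nv[keep], config$pseudocount)
  ids <- rownames(v)[keep]
  ord <- order(-fold, -vv[keep], ids)
  out <- data.frame(locus_id = ids[ord], nonvern = nv[keep][ord],
                    vern = vv[keep][ord], fold = fold[ord],
                    rank = seq_along(ord),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "screen") <- "vernalization_rank"
  attr(out, "config") <- config
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Seed-locus correlation screen
#'
#' Pearson correlation between every locus profile and the profile of a
#' chosen seed locus, over exactly the listed samples.  Loci with
#' `r >= correlation_threshold` form the positive set, loci with
#' `r <= -correlation_threshold` the negative set; the seed itself is
#' excluded from both.  Constant (zero-variance) candidate profiles have
#' undefined correlation and are excluded, counted in `n_skipped`.
#'
#' @param x a `"norm_matrix"` or numeric matrix.
#' @param seed_locus locus id of the seed.
#' @param samples ordered sample ids over which to correlate; at least 3.
#'   The classical choice is the four samples of the genotype carrying the
#'   full treatment series; using all six samples sharpens the screen
#'   (with only 4 points, the null distribution of r is uniform, so even
#'   r >= 0.95 admits about 2.5% of unrelated loci).
#' @param config a [screen_config()].
#' @return A list of class `"correlation_screen"` with `positive` and
#'   `negative` (data frames `locus_id`, `r`, ordered by decreasing
#'   `|r|`), `r` (named vector over all testable loci), `n_skipped`,
#'   `seed_locus` and `samples`.
#' @export
correlation_screen <- function(x, seed_locus, samples,
                               config = screen_config()) {
  v <- as_values(x)
  if (!seed_locus %in% rownames(v))
    stop("seed locus not in matrix: ", seed_locus)
  miss <- setdiff(samples, colnames(v))
  if (length(miss)) stop("unknown sample id: ", paste(miss, collapse = ", "))
  if (length(samples) < 3L)
    stop("need at least 3 samples for a meaningful correlation")
  v <- v[, samples, drop = FALSE]
  seed_profile <- v[seed_locus, ]
  if (stats::sd(seed_profile) == 0)
    stop("seed locus profile is constant over the chosen samples")
  cand <- v[setdiff(rownames(v), seed_locus), , drop = FALSE]
  sds <- apply(cand, 1L, stats::sd)
  testable <- cand[sds > 0, , drop = FALSE]
  r <- drop(stats::cor(t(testable), seed_profile))
  names(r) <- rownames(testable)
  thr <- config$correlation_threshold
  mk <- function(sel) {
    d <- data.frame(locus_id = names(r)[sel], r = unname(r[sel]),
                    stringsAsFactors = FALSE)
    d[order(-abs(d$r), d$locus_id), , drop = FALSE]
  }
  out <- list(positive = mk(r >= thr), negative = mk(r <= -thr),
              r = r, n_skipped = sum(sds == 0),
              seed_locus = seed_locus, samples = samples)
  class(out) <- "correlation_screen"
  out
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("Seed-locus correlation screen (seed:", x$seed_locus,
      "; samples:", paste(x$samples, collapse = ", "), ")\n")
  cat("  positive set:", nrow(x$positive), "loci; negative set:",
      nrow(x$negative), "loci;", x$n_skipped, "constant loci skipped\n")
  invisible(x)
}

#' Multi-condition GA-induction screen
#'
#' A locus passes when (i) its expression is similar across all untreated
#' samples (max/min pseudocounted ratio at most `similarity_max_fold`),
#' (ii) every treated/untreated pair shows at least `induction_fold`
#' pseudocounted induction, and (iii) it reaches `expression_floor` in at
#' least one treated sample.  This isolates a generalized treatment
#' response independent of genetic background or prior vernalization.
#'
#' @param x a `"norm_matrix"` or numeric matrix.
#' @param pairs list of length-2 character vectors
#'   `c(untreated sample, treated sample)`; the default is the canonical
#'   `(A,B), (C,D), (E,F)` layout.
#' @param config a [screen_config()].
#' @return A `data.frame` of class `"screen_report"`: one row per passing
#'   locus with the untreated spread (`untreated_spread`), the per-pair
#'   folds (`fold_<treated>_vs_<untreated>`), ordered by decreasing
#'   minimum fold.  The full per-locus evidence for all loci is attached
#'   as the `"evidence"` attribute.
#' @export
ga_induction_screen <- function(x,
                                pairs = list(c("A", "B"), c("C", "D"),
                                             c("E", "F")),
                                config = screen_config()) {
  v <- as_values(x)
  if (!length(pairs)) stop("need at least one (untreated, treated) pair")
  if (any(lengths(pairs) != 2L))
    stop("each pair must be c(untreated, treated)")
  untreated <- vapply(pairs, `[`, character(1), 1L)
  treated <- vapply(pairs, `[`, character(1), 2L)
  all_samp <- c(untreated, treated)
  if (anyDuplicated(all_samp))
    stop("sample(s) appear in more than one role: ",
         paste(unique(all_samp[duplicated(all_samp)]), collapse = ", "))
  miss <- setdiff(all_samp, colnames(v))
  if (length(miss)) stop("unknown sample id: ", paste(miss, collapse = ", "))
  pc <- config$pseudocount
  u <- v[, untreated, drop = FALSE] + pc
  g <- v[, treated, drop = FALSE] + pc
  spread <- apply(u, 1L, max) / apply(u, 1L, min)
  folds <- g / u
  colnames(folds) <- paste0("fold_", treated, "_vs_", untreated)
  similar <- spread <= config$similarity_max_fold
  induced <- rowSums(folds >= config$induction_fold) == ncol(folds)
  expressed <- apply(v[, treated, drop = FALSE], 1L, max) >=
    config$expression_floor
  pass <- similar & induced & expressed
  evidence <- data.frame(locus_id = rownames(v),
                         untreated_spread = spread, folds,
                         similar = similar, induced = induced,
                         expressed = expressed, pass = pass,
                         row.names = NULL, stringsAsFactors = FALSE)
  out <- evidence[pass, c("locus_id", "untreated_spread",
                          colnames(folds)), drop = FALSE]
  out <- out[order(-apply(out[, colnames(folds), drop = FALSE], 1L, min),
                   out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screen") <- "ga_induction"
  attr(out, "config") <- config
  attr(out, "evidence") <- evidence
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Plot expression profiles relative to the per-locus mean
#'
#' Line plot of each listed locus across the chosen samples, each profile
#' divided by its own mean, with one locus optionally highlighted — the
#' standard display for seed-correlated locus sets.
#'
#' @param x a `"norm_matrix"` or numeric matrix.
#' @param locus_ids loci to draw.
#' @param samples sample ids, in display order.
#' @param highlight optional locus id drawn in red on top.
#' @param ... passed to [graphics::matplot()].
#' @return `NULL`, invisibly.
#' @export
profile_plot <- function(x, locus_ids, samples = colnames(as_values(x)),
                         highlight = NULL, ...) {
  v <- as_values(x)[locus_ids, samples, drop = FALSE]
  rel <- v / rowMeans(v)
  graphics::matplot(t(rel), type = "l", lty = 1, col = "steelblue",
                    xaxt = "n", xlab = "sample",
                    ylab = "expression relative to locus mean", ...)
  graphics::axis(1, at = seq_along(samples), labels = samples)
  if (!is.null(highlight))
    graphics::lines(seq_along(samples),
                    rel[match(highlight, locus_ids), ],
                    col = "red", lwd = 2)
  invisible(NULL)
}
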