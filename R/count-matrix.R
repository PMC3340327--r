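#' Construct a tag-count matrix
#'
#' Container for integer sequence-tag counts, loci in rows and samples in
#' columns, together with the per-sample total number of uniquely mappable
#' reads used as the normalization denominator.
#'
#' @param counts numeric matrix of non-negative integer tag counts with
#'   locus ids as row names and sample ids as column names.
#' @param total_mappable per-sample positive totals of uniquely mappable
#'   reads, in column order (optionally named by sample).  When `NULL`
#'   the column sums of `counts` are used.
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts` and `total_mappable`.
#' @examples
#' m <- matrix(c(0L, 5L, 12L, 3L, 7L, 9L), nrow = 3,
#'             dimnames = list(paste0("Locus_", 1:3), c("A", "B")))
#' count_matrix(m)
#' @export
count_matrix <- function(counts, total_mappable = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have locus row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate locus id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("'counts' must be finite and numeric")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  if (any(counts != round(counts))) stop("'counts' must be integers")
  if (is.null(total_mappable)) total_mappable <- colSums(counts)
  if (!is.null(names(total_mappable))) {
    if (!setequal(names(total_mappable), colnames(counts)))
      stop("'total_mappable' names do not match sample ids")
    total_mappable <- total_mappable[colnames(counts)]
  } else {
    if (length(total_mappable) != ncol(counts))
      stop("'total_mappable' must have one entry per sample")
    names(total_mappable) <- colnames(counts)
  }
  if (any(!is.finite(total_mappable)) || any(total_mappable <= 0))
    stop("'total_mappable' must be positive for every sample")
  structure(list(counts = counts, total_mappable = total_mappable),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat("Tag-count matrix:", nrow(x$counts), "loci x",
      ncol(x$counts), "samples\n")
  cat("Samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  cat("Total mappable reads:",
      paste(format(x$total_mappable, big.mark = ","), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a sample design table
#'
#' @param sample_id character vector of unique sample ids.
#' @param genotype character vector of genotype labels.
#' @param vernalized logical vector; was the sample vernalized?
#' @param ga logical vector; was the sample GA-treated?
#' @return A `data.frame` of class `"sample_design"`.
#' @seealso [beet_design()] for the canonical six-sample layout.
#' @export
sample_design <- function(sample_id, genotype, vernalized, ga) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample id in design: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  d <- data.frame(sample_id = as.character(sample_id),
                  genotype = as.character(genotype),
                  vernalized = as.logical(vernalized),
                  ga = as.logical(ga),
                  stringsAsFactors = FALSE)
  if (any(is.na(d$vernalized)) || any(is.na(d$ga)))
    stop("'vernalized' and 'ga' must be TRUE/FALSE")
  class(d) <- c("sample_design", "data.frame")
  d
}

#' The canonical six-sample shoot apex design
#'
#' Samples A-F: C600 untreated, C600 + GA, Roberta untreated,
#' Roberta + GA, C600 vernalized, C600 vernalized + GA.
#'
#' @return A [sample_design()] with six rows.
#' @export
beet_design <- function() {
  sample_design(sample_id = c("A", "B", "C", "D", "E", "F"),
                genotype = c("C600", "C600", "Roberta", "Roberta",
                             "C600", "C600"),
                vernalized = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
                ga = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
}

#' Normalize tag counts to tags per 10 million mappable reads
#'
#' Each count is divided by its sample's total number of uniquely mappable
#' reads and multiplied by the scale constant (10 million), so libraries of
#' different sequencing depth become comparable.  When the denominators are
#' the column sums, every normalized column sums exactly to the scale
#' constant.
#'
#' @param x a [count_matrix()].
#' @param scale scale constant; fixed at 10,000,000 by convention.
#' @return An object of class `"norm_matrix"`: list with `values` (numeric
#'   matrix, tags per `scale` mappable reads), `total_mappable` and `scale`.
#' @export
normalize_tags <- function(x, scale = 1e7) {
  stopifnot(inherits(x, "count_matrix"))
  if (any(x$total_mappable <= 0)) stop("zero or negative denominator")
  values <- sweep(x$counts, 2L, x$total_mappable, "/") * scale
  structure(list(values = values, total_mappable = x$total_mappable,
                 scale = scale),
            class = "norm_matrix")
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

#' @export
print.norm_matrix <- function(x, ...) {
  cat("Normalized DGE matrix:", nrow(x$values), "loci x",
      ncol(x$values), "samples (tags per",
      format(x$scale, big.mark = ","), "mappable reads)\n")
  invisible(x)
}

## Accept either a norm_matrix or a plain numeric matrix downstream.
as_values <- function(x) {
  if (inherits(x, "norm_matrix")) return(x$values)
  if (inherits(x, "count_matrix")) return(x$counts)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a 'norm_matrix', 'count_matrix' or numeric matrix")
}

## Rebuild an object of the same flavour as x with a row subset.
subset_rows <- function(x, keep) {
  if (inherits(x, "norm_matrix")) {
    out <- x
    out$values <- x$values[keep, , drop = FALSE]
    return(out)
  }
  if (inherits(x, "count_matrix")) {
    out <- x
    out$counts <- x$counts[keep, , drop = FALSE]
    return(out)
  }
  x[keep, , drop = FALSE]
}

#' Retain loci with a minimum tag count in at least one sample
#'
#' Keeps exactly the rows whose maximum value across samples is greater
#' than or equal to `min_tag` (ties at the threshold are retained).  By
#' default this is applied to normalized values, reproducing the
#' "tag count of 10 or above in at least one sample" rule; it works
#' identically on a raw [count_matrix()] for sensitivity analysis.
#'
#' @param x a `"norm_matrix"`, [count_matrix()] or numeric matrix.
#' @param min_tag non-negative threshold (default 10).
#' @return Object of the same class as `x`, with rows filtered and row
#'   order preserved.
#' @export
filter_min_tag <- function(x, min_tag = 10) {
  if (!is.numeric(min_tag) || length(min_tag) != 1L || min_tag < 0)
    stop("'min_tag' must be a single non-negative number")
  v <- as_values(x)
  keep <- apply(v, 1L, max) >= min_tag
  subset_rows(x, keep)
}

#' Read a tag-count matrix and its design table
#'
#' The matrix file is tab-delimited with a header row of sample ids and a
#' first column of locus ids.  The design file is tab-delimited with
#' columns `sample_id`, `genotype`, `vernalized`, `ga`.  An optional
#' two-column file (`sample_id`, `total_mappable`) supplies the
#' normalization denominators; without it, column sums are used.
#'
#' @param path path to the tab-delimited count matrix.
#' @param design_path path to the tab-delimited design table.
#' @param total_mappable_path optional path to the per-sample totals.
#' @return A list with elements `counts` (a [count_matrix()]) and
#'   `design` (a [sample_design()]).
#' @export
read_count_matrix <- function(path, design_path,
                              total_mappable_path = NULL) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  if (!file.exists(design_path))
    stop("design file not found: ", design_path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("count matrix needs a locus column plus samples")
  locus <- tab[[1L]]
  if (anyDuplicated(locus)) {
    dups <- unique(locus[duplicated(locus)])
    stop("duplicate locus id in ", path, ": ", paste(dups, collapse = ", "))
  }
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop("malformed count in ", path, " at line ", b[1L] + 1L,
         " (locus '", locus[b[1L]], "', sample '",
         colnames(raw)[b[2L]], "'): '", raw[b[1L], b[2L]], "'")
  }
  dimnames(num) <- list(locus, colnames(raw))

  design <- read_sample_design(design_path)
  missing_in_design <- setdiff(colnames(num), design$sample_id)
  missing_in_matrix <- setdiff(design$sample_id, colnames(num))
  if (length(missing_in_design) || length(missing_in_matrix))
    stop("sample ids differ between matrix and design; ",
         "matrix-only: {", paste(missing_in_design, collapse = ", "),
         "}, design-only: {", paste(missing_in_matrix, collapse = ", "), "}")
  design <- design[match(colnames(num), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL

  tm <- NULL
  if (!is.null(total_mappable_path)) {
    tm_tab <- utils::read.delim(total_mappable_path, header = TRUE,
                                check.names = FALSE)
    if (ncol(tm_tab) < 2L)
      stop("total-mappable file needs columns: sample id, total")
    tm <- as.numeric(tm_tab[[2L]])
    names(tm) <- as.character(tm_tab[[1L]])
  }
  list(counts = count_matrix(num, total_mappable = tm), design = design)
}

read_sample_design <- function(path) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "vernalized", "ga")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design table missing column(s): ", paste(miss, collapse = ", "))
  sample_design(d$sample_id, d$genotype,
                parse_logical(d$vernalized), parse_logical(d$ga))
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "yes", "1")
}

#' Write a count matrix, normalized matrix or design table
#'
#' Tab-delimited, header row of sample ids, first column `locus_id`.
#'
#' @param x a [count_matrix()], `"norm_matrix"` or [sample_design()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dge_table <- function(x, path) {
  if (inherits(x, "count_matrix") || inherits(x, "norm_matrix")) {
    v <- as_values(x)
    out <- data.frame(locus_id = rownames(v), v, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (is.data.frame(x)) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else stop("don't know how to write an object of class ",
              paste(class(x), collapse = "/"))
  invisible(path)
}

#' Write the per-sample total-mappable-read denominators
#'
#' @param x a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_total_mappable <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  utils::write.table(
    data.frame(sample_id = names(x$total_mappable),
               total_mappable = unname(x$total_mappable)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
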