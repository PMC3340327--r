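## BLAST tabular (outfmt 6) consumption: parsing, stringency filtering,
## overlap/Venn accounting and best-hit annotation.

outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
outfmt6_numeric <- c("pident", "length", "mismatch", "gapopen", "qstart",
                     "qend", "sstart", "send", "evalue", "bitscore")

#' Read tabular homology-search output (BLAST outfmt 6)
#'
#' Parses the 12-column tab-separated BLAST report dialect (`qseqid
#' sseqid pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore`); extra columns are retained verbatim as `extra1`, `extra2`,
#' ...  Comment lines starting with `#` are skipped; malformed rows are
#' reported with their line number.
#'
#' @param path input file.
#' @param dialect currently only `"outfmt6"`.
#' @return A `data.frame` of class `"blast_hits"`.
#' @export
read_blast_hits <- function(path, dialect = "outfmt6") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hits file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("line ", lineno[which(nf < 12L)[1L]], ": expected >= 12 ",
         "tab-separated columns, found ", nf[which(nf < 12L)[1L]])
  ncol_all <- max(nf)
  m <- t(vapply(fields, function(f) c(f, rep("", ncol_all - length(f))),
                character(ncol_all)))
  cn <- c(outfmt6_cols,
          if (ncol_all > 12L) paste0("extra", seq_len(ncol_all - 12L)))
  d <- as.data.frame(m, stringsAsFactors = FALSE)
  names(d) <- cn
  for (col in outfmt6_numeric) {
    num <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(num))
      stop("line ", lineno[which(is.na(num))[1L]], ": non-numeric '",
           col, "' value '", d[[col]][which(is.na(num))[1L]], "'")
    d[[col]] <- num
  }
  validate_hits(d, lineno)
  class(d) <- c("blast_hits", "data.frame")
  d
}

empty_hits <- function() {
  d <- as.data.frame(stats::setNames(
    c(list(character(0), character(0)),
      rep(list(numeric(0)), length(outfmt6_numeric))),
    outfmt6_cols), stringsAsFactors = FALSE)
  class(d) <- c("blast_hits", "data.frame")
  d
}

validate_hits <- function(d, lineno = seq_len(nrow(d))) {
  bad <- which(d$pident < 0 | d$pident > 100)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": percent identity out of [0, 100]")
  bad <- which(d$length < 1)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": alignment length must be >= 1")
  bad <- which(d$evalue < 0)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": negative E-value")
  invisible(d)
}

#' Write hits back to the tabular outfmt-6 dialect
#'
#' @param hits a `"blast_hits"` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Stringency-filter homology hits
#'
#' Retains hits with alignment length at least `min_overlap` bp AND
#' percent identity at least `min_identity` AND (when `max_evalue` is
#' given) E-value at most `max_evalue`.  All thresholds are inclusive.
#'
#' @param hits a `"blast_hits"` data frame.
#' @param min_overlap minimum alignment length in bp (default 100).
#' @param min_identity minimum percent identity (default 98).
#' @param max_evalue optional inclusive E-value ceiling.
#' @return The surviving hits, same class, row order preserved.
#' @export
stringency_filter <- function(hits, min_overlap = 100, min_identity = 98,
                              max_evalue = NULL) {
  if (min_identity < 0 || min_identity > 100)
    stop("'min_identity' must be in [0, 100]")
  if (min_overlap < 0) stop("'min_overlap' must be >= 0")
  keep <- hits$length >= min_overlap & hits$pident >= min_identity
  if (!is.null(max_evalue)) keep <- keep & hits$evalue <= max_evalue
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap (Venn) accounting between query and subject universes
#'
#' Given filtered hits and the complete id universes on each side, counts
#' ids with at least one surviving hit ("common", counted on the
#' configurable `side`), the unmatched queries and the unmatched
#' subjects — the three numbers of the classical comparison Venn — plus
#' the query-to-subject mapping and the queries matching more than one
#' subject (redundancy accounting).
#'
#' @param hits a `"blast_hits"` data frame (typically already through
#'   [stringency_filter()]).
#' @param query_universe,subject_universe complete id sets; every hit id
#'   must belong to its universe.
#' @param side `"subject"` (default) counts `n_common` as matched
#'   subjects (locus-side accounting), `"query"` as matched queries
#'   (EST-side accounting).
#' @return An object of class `"overlap_accounting"`: list with
#'   `n_common`, `n_query_only`, `n_subject_only`, `n_matched_queries`,
#'   `n_matched_subjects`, `query_to_subjects` (named list) and
#'   `multi_subject_queries`.
#' @export
overlap_accounting <- function(hits, query_universe, subject_universe,
                               side = c("subject", "query")) {
  side <- match.arg(side)
  stray_q <- setdiff(unique(hits$qseqid), query_universe)
  if (length(stray_q))
    stop("hit query id(s) outside the query universe: ",
         paste(utils::head(stray_q, 10L), collapse = ", "))
  stray_s <- setdiff(unique(hits$sseqid), subject_universe)
  if (length(stray_s))
    stop("hit subject id(s) outside the subject universe: ",
         paste(utils::head(stray_s, 10L), collapse = ", "))
  q2s <- lapply(split(hits$sseqid, hits$qseqid), unique)
  matched_q <- names(q2s)
  matched_s <- unique(hits$sseqid)
  out <- list(
    n_common = if (side == "subject") length(matched_s) else length(matched_q),
    n_query_only = length(setdiff(query_universe, matched_q)),
    n_subject_only = length(setdiff(subject_universe, matched_s)),
    n_matched_queries = length(matched_q),
    n_matched_subjects = length(matched_s),
    query_to_subjects = q2s,
    multi_subject_queries = matched_q[lengths(q2s) >= 2L],
    side = side)
  class(out) <- "overlap_accounting"
  out
}

#' @export
print.overlap_accounting <- function(x, ...) {
  cat("Overlap accounting (common counted on the", x$side, "side):\n")
  cat("  common:", x$n_common, " query-only:", x$n_query_only,
      " subject-only:", x$n_subject_only, "\n")
  cat("  matched queries:", x$n_matched_queries,
      " matched subjects:", x$n_matched_subjects,
      " multi-subject queries:", length(x$multi_subject_queries), "\n")
  invisible(x)
}

#' Best-hit annotation per query
#'
#' For each query, the hit with the smallest E-value among those at or
#' below `max_evalue`; ties broken by higher bit score, then by subject id
#' lexicographically.  Queries with no surviving hit are absent.
#'
#' @param hits a `"blast_hits"` data frame.
#' @param max_evalue inclusive E-value ceiling (default `1e-10`).
#' @return A `data.frame` with one row per annotated query: `qseqid`,
#'   `sseqid`, `evalue`, `bitscore` plus any retained extra columns.
#' @export
best_hit_annotation <- function(hits, max_evalue = 1e-10) {
  h <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (!nrow(h)) {
    out <- as.data.frame(h)[, c("qseqid", "sseqid", "evalue", "bitscore")]
    return(out)
  }
  ord <- order(h$qseqid, h$evalue, -h$bitscore, h$sseqid)
  h <- h[ord, , drop = FALSE]
  best <- h[!duplicated(h$qseqid), , drop = FALSE]
  extra <- grep("^extra", names(best), value = TRUE)
  out <- as.data.frame(best)[, c("qseqid", "sseqid", "evalue", "bitscore",
                                 extra), drop = FALSE]
  rownames(out) <- NULL
  out
}
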