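#' Construct a transcript set
#'
#' @param transcript_id unique transcript identifiers.
#' @param locus_id locus identifier of each transcript (a locus groups
#'   alternative assembled transcripts from one presumed gene).
#' @param length transcript length in bp, positive integers.
#' @return A `data.frame` of class `"transcript_set"`.
#' @export
transcript_set <- function(transcript_id, locus_id, length) {
  if (anyDuplicated(transcript_id))
    stop("duplicate transcript id: ",
         paste(unique(transcript_id[duplicated(transcript_id)]),
               collapse = ", "))
  if (any(is.na(locus_id)) || any(!nzchar(as.character(locus_id))))
    stop("every transcript needs a locus id")
  if (any(!is.finite(length)) || any(length < 1) ||
      any(length != round(length)))
    stop("'length' must be positive integers (bp)")
  d <- data.frame(transcript_id = as.character(transcript_id),
                  locus_id = as.character(locus_id),
                  length = as.integer(length),
                  stringsAsFactors = FALSE)
  class(d) <- c("transcript_set", "data.frame")
  d
}

#' Read a transcript set from a table or FASTA file
#'
#' Tab-delimited tables have columns `transcript_id`, `locus_id`,
#' `length` (the length column may be omitted only in FASTA mode, where
#' lengths come from the sequences).  In FASTA mode the locus of a
#' transcript is taken from `locus_pattern` applied to the record name
#' (default: the name up to the last `.` suffix, as in `Locus_1.2`).
#'
#' @param path input file.
#' @param format `"table"` or `"fasta"`.
#' @param locus_pattern regular expression whose removal from a FASTA
#'   record name yields the locus id.
#' @return A [transcript_set()].
#' @export
read_transcript_set <- function(path, format = c("table", "fasta"),
                                locus_pattern = "\\.[0-9]+$") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "table") {
    d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("transcript_id", "locus_id", "length")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("transcript table missing column(s): ",
           paste(miss, collapse = ", "))
    return(transcript_set(d$transcript_id, d$locus_id, d$length))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  transcript_set(ids, sub(locus_pattern, "", ids), Biostrings::width(seqs))
}

#' Write a transcript set
#'
#' Tab-delimited table, or FASTA when the set carries sequences (as
#' produced by [simulate_transcript_set()] with `sequences = TRUE`).
#'
#' @param ts a [transcript_set()].
#' @param path output file.
#' @param format `"table"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_transcript_set <- function(ts, path, format = c("table", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(ts, "transcript_set"))
  if (format == "table") {
    utils::write.table(as.data.frame(ts), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    seqs <- attr(ts, "sequences")
    if (is.null(seqs)) stop("transcript set carries no sequences")
    Biostrings::writeXStringSet(seqs, path)
  }
  invisible(path)
}

#' N50 of a set of sequence lengths
#'
#' The length-weighted median: the length at which the cumulative sum of
#' lengths, taken in descending order, first reaches half the total.
#' Equivalently, the largest length L such that sequences of length >= L
#' together cover at least half the assembly.
#'
#' @param lengths non-empty vector of positive lengths (bp).
#' @return The N50 in bp.
#' @examples
#' n50(c(4, 3, 3, 2, 2, 2))  # cumulative 4, 7, 10 vs half-total 8 -> 3
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length set: N50 undefined")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("'lengths' must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= cs[length(cs)] / 2)[1L]]
}

#' Classify large transcripts and large loci
#'
#' A transcript is "large" when its length exceeds `min_length` (strictly,
#' by default: > 0.5 kb); a locus is large when at least one of its
#' transcripts is.  When the transcript set carries a `read_support`
#' column, transcripts must additionally have at least `min_reads`
#' supporting reads (by default the requirement is derived from length
#' alone: a > 500 bp assembly from 100 bp reads already implies >= 6
#' independent reads).
#'
#' @param ts a [transcript_set()].
#' @param min_length length threshold in bp (default 500).
#' @param strict if `TRUE` (default) the comparison is `>`, else `>=`.
#' @param min_reads optional minimum read support, only enforced when the
#'   set has a `read_support` column.
#' @return A list with `large_transcript_ids`, `large_locus_ids`,
#'   `n_large_transcripts`, `n_large_loci`.
#' @export
classify_large <- function(ts, min_length = 500, strict = TRUE,
                           min_reads = NULL) {
  stopifnot(inherits(ts, "transcript_set"))
  big <- if (strict) ts$length > min_length else ts$length >= min_length
  if (!is.null(min_reads) && "read_support" %in% names(ts))
    big <- big & ts$read_support >= min_reads
  lt <- ts$transcript_id[big]
  ll <- unique(ts$locus_id[big])
  list(large_transcript_ids = lt, large_locus_ids = ll,
       n_large_transcripts = length(lt), n_large_loci = length(ll))
}

#' Summary statistics of a transcript set
#'
#' Transcript and locus tallies, N50 over all transcript lengths, N50 over
#' per-locus representative lengths (each locus's longest transcript), the
#' large-transcript classification and the length range.
#'
#' @param ts a [transcript_set()].
#' @param min_length large-transcript threshold in bp (default 500).
#' @return An object of class `"assembly_stats"`: a list with
#'   `n_transcripts`, `n_loci`, `n50_transcripts`, `n50_loci`,
#'   `large_transcript_ids`, `large_locus_ids`, `min_length_bp`,
#'   `max_length_bp`, `total_length_bp`.  On an empty set the counts are
#'   zero and the N50 fields `NA`.
#' @export
assembly_summary <- function(ts, min_length = 500) {
  stopifnot(inherits(ts, "transcript_set"))
  if (nrow(ts) == 0L) {
    out <- list(n_transcripts = 0L, n_loci = 0L,
                n50_transcripts = NA_real_, n50_loci = NA_real_,
                large_transcript_ids = character(0),
                large_locus_ids = character(0),
                min_length_bp = NA_real_, max_length_bp = NA_real_,
                total_length_bp = 0)
    class(out) <- "assembly_stats"
    return(out)
  }
  rep_len_per_locus <- tapply(ts$length, ts$locus_id, max)
  cl <- classify_large(ts, min_length = min_length)
  out <- list(n_transcripts = nrow(ts),
              n_loci = length(unique(ts$locus_id)),
              n50_transcripts = n50(ts$length),
              n50_loci = n50(as.numeric(rep_len_per_locus)),
              large_transcript_ids = cl$large_transcript_ids,
              large_locus_ids = cl$large_locus_ids,
              min_length_bp = min(ts$length),
              max_length_bp = max(ts$length),
              total_length_bp = sum(as.numeric(ts$length)))
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly summary:\n")
  cat("  transcripts:", x$n_transcripts, " loci:", x$n_loci, "\n")
  cat("  N50 (transcripts):", x$n50_transcripts,
      "bp; N50 (loci, longest transcript):", x$n50_loci, "bp\n")
  cat("  large (>0.5 kb): ", length(x$large_transcript_ids),
      " transcripts in ", length(x$large_locus_ids), " loci\n", sep = "")
  cat("  length range:", x$min_length_bp, "-", x$max_length_bp,
      "bp; total:", x$total_length_bp, "bp\n")
  invisible(x)
}
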