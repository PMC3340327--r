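hit_row <- function(q = "q1", s = "s1", pid = 98, len = 150,
                    evalue = 1e-20, bits = 200) {
  paste(q, s, pid, len, 2, 0, 1, len, 1, len,
        format(evalue, scientific = TRUE), bits, sep = "\t")
}

write_hits_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("outfmt-6 rows parse field by field", {
  path <- write_hits_file(c("# comment line",
                            "q1\ts2\t98.00\t150\t3\t0\t1\t150\t10\t159\t1e-30\t277"))
  hits <- read_blast_hits(path)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$qseqid, "q1")
  expect_identical(hits$pident, 98)
  expect_identical(hits$length, 150)
  expect_identical(hits$evalue, 1e-30)

  empty <- read_blast_hits(write_hits_file(character(0)))
  expect_identical(nrow(empty), 0L)

  short <- write_hits_file(c(hit_row(), "q2\ts1\t98"))
  expect_error(read_blast_hits(short), "line 2")
  bad <- write_hits_file(c(hit_row(),
                           "q2\ts1\tninety\t150\t2\t0\t1\t150\t1\t150\t1e-5\t100"))
  expect_error(read_blast_hits(bad), "pident")
})

test_that("stringency thresholds are inclusive on both overlap and identity", {
  path <- write_hits_file(c(
    hit_row("q1", "s1", pid = 99, len = 99),     # 99 bp overlap: dropped
    hit_row("q2", "s2", pid = 98.0, len = 150),  # exactly 98%: kept
    hit_row("q3", "s3", pid = 97.9, len = 200),  # identity too low
    hit_row("q4", "s4", pid = 100, len = 100, evalue = 1e-10)))
  hits <- read_blast_hits(path)
  filt <- stringency_filter(hits)
  expect_setequal(filt$qseqid, c("q2", "q4"))
  # e-value ceiling is inclusive: a hit at exactly 1e-10 survives
  withe <- stringency_filter(hits, max_evalue = 1e-10)
  expect_true("q4" %in% withe$qseqid)
})

test_that("filtering is monotone and composes to the strictest thresholds", {
  set.seed(91)
  n <- 200
  hits <- data.frame(qseqid = sprintf("q%d", sample(50, n, TRUE)),
                     sseqid = sprintf("s%d", sample(50, n, TRUE)),
                     pident = runif(n, 80, 100),
                     length = sample(50:300, n, TRUE),
                     mismatch = 0, gapopen = 0, qstart = 1, qend = 1,
                     sstart = 1, send = 1,
                     evalue = 10^runif(n, -50, 0),
                     bitscore = runif(n, 50, 300),
                     stringsAsFactors = FALSE)
  class(hits) <- c("blast_hits", "data.frame")
  loose <- stringency_filter(hits, min_overlap = 80, min_identity = 90)
  tight <- stringency_filter(hits, min_overlap = 120, min_identity = 95)
  expect_lte(nrow(tight), nrow(loose))
  expect_true(all(interaction(tight$qseqid, tight$sseqid) %in%
                    interaction(loose$qseqid, loose$sseqid)))
  composed <- stringency_filter(
    stringency_filter(hits, min_overlap = 120, min_identity = 90),
    min_overlap = 80, min_identity = 95)
  expect_identical(nrow(composed), nrow(tight))
})

test_that("overlap accounting partitions both universes", {
  path <- write_hits_file(c(hit_row("q1", "s2"), hit_row("q1", "s3"),
                            hit_row("q2", "s3")))
  hits <- read_blast_hits(path)
  acc <- overlap_accounting(hits, query_universe = c("q1", "q2", "q3"),
                            subject_universe = c("s1", "s2", "s3", "s4"))
  expect_identical(acc$n_common, 2L)        # s2, s3 matched
  expect_identical(acc$n_query_only, 1L)    # q3
  expect_identical(acc$n_subject_only, 2L)  # s1, s4
  expect_identical(acc$multi_subject_queries, "q1")
  # conservation: matched + only = universe, on each side
  expect_identical(acc$n_matched_subjects + acc$n_subject_only, 4L)
  expect_identical(acc$n_matched_queries + acc$n_query_only, 3L)
  # query-side accounting counts matched queries instead
  qacc <- overlap_accounting(hits, c("q1", "q2", "q3"),
                             c("s1", "s2", "s3", "s4"), side = "query")
  expect_identical(qacc$n_common, 2L)

  none <- overlap_accounting(hits[0, ], c("q1", "q2"), c("s1"))
  expect_identical(none$n_common, 0L)
  expect_identical(none$n_query_only, 2L)
  expect_identical(none$n_subject_only, 1L)

  # a hit whose query (q2) is missing from the stated universe is an error
  expect_error(overlap_accounting(hits, "q1", c("s2", "s3")), "q2")
})

test_that("best-hit annotation applies the cutoff and tie rules", {
  path <- write_hits_file(c(
    hit_row("q1", "sA", evalue = 1e-20, bits = 100),
    hit_row("q1", "sB", evalue = 1e-5, bits = 400),
    hit_row("q2", "sC", evalue = 1e-3),
    hit_row("q3", "sD", evalue = 1e-12, bits = 80),
    hit_row("q3", "sE", evalue = 1e-12, bits = 90)))
  best <- best_hit_annotation(read_blast_hits(path), max_evalue = 1e-10)
  expect_identical(best$sseqid[best$qseqid == "q1"], "sA")
  expect_false("q2" %in% best$qseqid)       # no hit under the cutoff
  expect_identical(best$sseqid[best$qseqid == "q3"], "sE")  # bit score wins
})

test_that("hits survive a write/read round trip bit-exactly", {
  path <- write_hits_file(c(hit_row("q1", "s1", pid = 98.35, len = 123,
                                    evalue = 3.7e-21, bits = 217.5),
                            hit_row("q2", "s2")))
  hits <- read_blast_hits(path)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_blast_hits(hits, out)
  expect_identical(read_blast_hits(out), hits)
})
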