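#' Configuration for the synthetic count generator
#'
#' Describes a six-sample (by default) factorial DGE experiment with
#' planted effects: genotype-differential loci, vernalization-responsive
#' loci, GA-induced loci, and a seed locus with positively and negatively
#' co-expressed partner loci.  The defaults emulate the shoot-apex study
#' conditions: library sizes in the 13.786-20.360 million uniquely
#' mappable read range, a log-normal baseline with median 64 tags per 10
#' million reads and a 2 log2-unit spread, negative-binomial counts at
#' biological-coefficient-of-variation 0.1 (dispersion 0.01, the
#' conventional level for libraries prepared from near-identical pooled
#' material), and four-fold planted effects.
#'
#' Planted-effect loci draw their baseline from the same log-normal
#' truncated below at `planted_baseline_min` tags per 10 million reads: an
#' effect planted underneath the detection floor of 10 tags would be
#' unobservable by construction and tells us nothing about the screens.
#'
#' @param n_loci number of loci to simulate.
#' @param design a [sample_design()]; defaults to [beet_design()].
#' @param library_sizes per-sample totals of mappable reads; when `NULL`,
#'   drawn uniformly from `[13786000, 20360000]`.
#' @param baseline_mean_log2,baseline_sd_log2 mean and sd of the log2
#'   baseline expression (tags per 10 million mappable reads).
#' @param dispersion negative-binomial overdispersion; variance is
#'   `mu + dispersion * mu^2`.  `0` gives Poisson counts.
#' @param planted_genotype_fold fold change (>= 1) for genotype loci;
#'   planted symmetrically, half up in each genotype.
#' @param planted_vern_fold fold change (>= 1) applied to
#'   vernalization-responsive loci in vernalized samples.
#' @param planted_ga_fold fold change (>= 2) applied to GA-induced loci in
#'   GA-treated samples.
#' @param n_genotype_de,n_vern_up,n_ga_up,n_seed_partners_pos,n_seed_partners_neg
#'   planted set sizes; the sets are disjoint and, together with the seed
#'   locus, must fit within `n_loci`.
#' @param seed_profile per-sample relative expression of the seed locus
#'   (recycled names from the design); the default is modeled on a
#'   vernalization-induced, GA-enhanced profile.
#' @param seed_partner_log_sd sd of the Gaussian noise (natural-log scale)
#'   added to partner-locus profiles.
#' @param planted_baseline_min minimum baseline (tags per 10 million) for
#'   planted-effect loci.
#' @param seed integer RNG seed; identical configurations give
#'   bit-identical output.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_loci = 5000,
                              design = beet_design(),
                              library_sizes = NULL,
                              baseline_mean_log2 = 6,
                              baseline_sd_log2 = 2,
                              dispersion = 0.01,
                              planted_genotype_fold = 4,
                              planted_vern_fold = 4,
                              planted_ga_fold = 4,
                              n_genotype_de = 50,
                              n_vern_up = 50,
                              n_ga_up = 50,
                              n_seed_partners_pos = 50,
                              n_seed_partners_neg = 10,
                              seed_profile = c(A = 1, B = 0.37, C = 0.8,
                                               D = 0.3, E = 3.2, F = 9.6),
                              seed_partner_log_sd = 0.05,
                              planted_baseline_min = 32,
                              seed = 1L) {
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1)
    stop("'n_loci' must be a positive integer")
  if (!inherits(design, "sample_design")) stop("'design' must be a sample_design")
  if (nrow(design) < 2L) stop("design must contain at least 2 samples")
  if (!is.null(library_sizes)) {
    if (length(library_sizes) != nrow(design) || any(library_sizes <= 0))
      stop("'library_sizes' must be one positive value per sample")
  }
  if (baseline_sd_log2 < 0) stop("'baseline_sd_log2' must be >= 0")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (planted_genotype_fold < 1) stop("'planted_genotype_fold' must be >= 1")
  if (planted_vern_fold < 1) stop("'planted_vern_fold' must be >= 1")
  if (planted_ga_fold < 2) stop("'planted_ga_fold' must be >= 2")
  sizes <- c(n_genotype_de, n_vern_up, n_ga_up,
             n_seed_partners_pos, n_seed_partners_neg)
  if (any(sizes < 0)) stop("planted set sizes must be non-negative")
  n_seed <- as.integer(n_seed_partners_pos + n_seed_partners_neg > 0)
  if (sum(sizes) + n_seed > n_loci)
    stop("planted locus sets (", sum(sizes) + n_seed,
         ") exceed 'n_loci' (", n_loci, ")")
  if (seed_partner_log_sd < 0) stop("'seed_partner_log_sd' must be >= 0")
  structure(list(n_loci = as.integer(n_loci), design = design,
                 library_sizes = library_sizes,
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 dispersion = dispersion,
                 planted_genotype_fold = planted_genotype_fold,
                 planted_vern_fold = planted_vern_fold,
                 planted_ga_fold = planted_ga_fold,
                 n_genotype_de = as.integer(n_genotype_de),
                 n_vern_up = as.integer(n_vern_up),
                 n_ga_up = as.integer(n_ga_up),
                 n_seed_partners_pos = as.integer(n_seed_partners_pos),
                 n_seed_partners_neg = as.integer(n_seed_partners_neg),
                 seed_profile = seed_profile,
                 seed_partner_log_sd = seed_partner_log_sd,
                 planted_baseline_min = planted_baseline_min,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## log2-normal baseline, optionally left-truncated (inverse-CDF draw so a
## single runif stream keeps the generator deterministic).
rbaseline <- function(n, mean_log2, sd_log2, min_value = NULL) {
  if (n == 0L) return(numeric(0))
  if (sd_log2 == 0) return(rep(2^mean_log2, n))
  lo <- 0
  if (!is.null(min_value))
    lo <- stats::pnorm(log2(min_value), mean_log2, sd_log2)
  u <- stats::runif(n, min = lo, max = 1)
  2^stats::qnorm(u, mean_log2, sd_log2)
}

#' Simulate a tag-count matrix with planted effects
#'
#' Draws negative-binomial (Poisson when `dispersion = 0`) tag counts whose
#' expectation for locus `l` in sample `s` is
#' `library_size[s] / 1e7 * baseline[l] * fold factors`, where the fold
#' factors encode the planted genotype, vernalization and GA effects, and
#' seed-partner loci follow a positive (or negative-affine) transform of
#' the seed locus profile with configurable log-scale noise.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `counts` (a [count_matrix()] whose
#'   denominators are the drawn library sizes), `design` (the
#'   [sample_design()]) and `truth` (a data frame with columns `locus_id`,
#'   `class` and `fold`; `class` is one of `null`, `genotype_de`,
#'   `vern_up`, `ga_up`, `seed`, `seed_partner_pos`, `seed_partner_neg`,
#'   and `fold` is the planted fold on the second genotype / treated
#'   samples, `NA` where not applicable).
#' @examples
#' sim <- simulate_counts(simulation_config(n_loci = 200, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  design <- config$design
  n_samp <- nrow(design)
  n_loci <- config$n_loci
  lib <- config$library_sizes
  if (is.null(lib))
    lib <- round(stats::runif(n_samp, 13786000, 20360000))
  names(lib) <- design$sample_id

  locus_ids <- sprintf("Locus_%05d", seq_len(n_loci))
  class <- rep("null", n_loci)
  fold <- rep(NA_real_, n_loci)

  n_seed <- as.integer(config$n_seed_partners_pos +
                       config$n_seed_partners_neg > 0)
  n_planted <- config$n_genotype_de + config$n_vern_up + config$n_ga_up +
    config$n_seed_partners_pos + config$n_seed_partners_neg + n_seed
  planted_idx <- sample.int(n_loci, n_planted)
  take <- function(n) {
    if (n == 0L) return(integer(0))
    out <- planted_idx[seq_len(n)]
    planted_idx <<- planted_idx[-seq_len(n)]
    out
  }
  idx_geno <- take(config$n_genotype_de)
  idx_vern <- take(config$n_vern_up)
  idx_ga <- take(config$n_ga_up)
  idx_seed <- take(n_seed)
  idx_pos <- take(config$n_seed_partners_pos)
  idx_neg <- take(config$n_seed_partners_neg)
  class[idx_geno] <- "genotype_de"
  class[idx_vern] <- "vern_up"
  class[idx_ga] <- "ga_up"
  class[idx_seed] <- "seed"
  class[idx_pos] <- "seed_partner_pos"
  class[idx_neg] <- "seed_partner_neg"

  baseline <- rbaseline(n_loci, config$baseline_mean_log2,
                        config$baseline_sd_log2)
  is_planted <- class != "null"
  baseline[is_planted] <- rbaseline(sum(is_planted),
                                    config$baseline_mean_log2,
                                    config$baseline_sd_log2,
                                    min_value = config$planted_baseline_min)

  ## per-locus x per-sample expected normalized expression
  rel <- matrix(1, n_loci, n_samp,
                dimnames = list(locus_ids, design$sample_id))
  geno2 <- design$genotype != design$genotype[1L]  # second genotype samples
  if (length(idx_geno)) {
    up_first <- idx_geno[seq_len(ceiling(length(idx_geno) / 2))]
    up_second <- setdiff(idx_geno, up_first)
    rel[up_first, geno2] <- rel[up_first, geno2, drop = FALSE] /
      config$planted_genotype_fold
    rel[up_second, geno2] <- rel[up_second, geno2, drop = FALSE] *
      config$planted_genotype_fold
    fold[up_first] <- 1 / config$planted_genotype_fold
    fold[up_second] <- config$planted_genotype_fold
  }
  if (length(idx_vern)) {
    rel[idx_vern, design$vernalized] <-
      rel[idx_vern, design$vernalized, drop = FALSE] * config$planted_vern_fold
    fold[idx_vern] <- config$planted_vern_fold
  }
  if (length(idx_ga)) {
    rel[idx_ga, design$ga] <-
      rel[idx_ga, design$ga, drop = FALSE] * config$planted_ga_fold
    fold[idx_ga] <- config$planted_ga_fold
  }
  seed_rel <- rep_len(unname(config$seed_profile), n_samp)
  if (length(idx_seed)) rel[idx_seed, ] <- rep(seed_rel, each = 1L)
  if (length(idx_pos)) {
    noise <- matrix(stats::rnorm(length(idx_pos) * n_samp,
                                 sd = config$seed_partner_log_sd),
                    length(idx_pos), n_samp)
    rel[idx_pos, ] <- outer(rep(1, length(idx_pos)), seed_rel) * exp(noise)
  }
  if (length(idx_neg)) {
    neg_rel <- max(seed_rel) + min(seed_rel) - seed_rel  # exact r = -1
    neg_rel <- neg_rel / mean(neg_rel)
    noise <- matrix(stats::rnorm(length(idx_neg) * n_samp,
                                 sd = config$seed_partner_log_sd),
                    length(idx_neg), n_samp)
    rel[idx_neg, ] <- outer(rep(1, length(idx_neg)), neg_rel) * exp(noise)
  }

  mu <- (baseline * rel) %*% diag(lib / 1e7)
  dimnames(mu) <- list(locus_ids, design$sample_id)
  counts <- if (config$dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
  counts <- matrix(counts, n_loci, n_samp, dimnames = dimnames(mu))

  truth <- data.frame(locus_id = locus_ids, class = class, fold = fold,
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, total_mappable = lib),
       design = design, truth = truth)
}

#' Simulate a transcript set for assembly statistics
#'
#' Emits transcript records (transcript id, locus id, length) with lengths
#' drawn uniformly from `length_range`; locus ids form a surjection from
#' transcripts (every locus receives at least one transcript).  Optionally
#' attaches random-nucleotide sequences of the drawn lengths.
#'
#' @param n_transcripts number of transcripts (> 0).
#' @param n_loci number of distinct loci (defaults to about 70% of
#'   `n_transcripts`); must not exceed `n_transcripts`.
#' @param length_range inclusive range of transcript lengths in bp.
#' @param sequences if `TRUE`, attach random ACGT sequences.
#' @param seed integer RNG seed.
#' @return A [transcript_set()]; when `sequences = TRUE` it carries a
#'   `DNAStringSet` in the `"sequences"` attribute.
#' @export
simulate_transcript_set <- function(n_transcripts,
                                    n_loci = max(1L, round(0.7 * n_transcripts)),
                                    length_range = c(100L, 9000L),
                                    sequences = FALSE, seed = 1L) {
  if (!is.numeric(n_transcripts) || length(n_transcripts) != 1L ||
      n_transcripts < 1)
    stop("'n_transcripts' must be a positive integer")
  if (n_loci > n_transcripts) stop("'n_loci' cannot exceed 'n_transcripts'")
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1L] > length_range[2L])
    stop("'length_range' must be an increasing pair of positive lengths")
  set.seed(seed)
  n_transcripts <- as.integer(n_transcripts)
  n_loci <- as.integer(n_loci)
  ## surjective transcript -> locus map: each locus once, the rest random
  locus_of <- c(seq_len(n_loci),
                sample.int(n_loci, n_transcripts - n_loci, replace = TRUE))
  locus_of <- locus_of[sample.int(n_transcripts)]
  lengths <- sample(seq.int(length_range[1L], length_range[2L]),
                    n_transcripts, replace = TRUE)
  ts <- transcript_set(transcript_id = sprintf("Transcript_%05d",
                                               seq_len(n_transcripts)),
                       locus_id = sprintf("Locus_%05d", locus_of),
                       length = lengths)
  if (sequences) {
    seqs <- vapply(lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), character(1))
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- ts$transcript_id
    attr(ts, "sequences") <- dss
  }
  ts
}

#' Write a simulated experiment to tab-delimited files
#'
#' Writes `counts.tsv`, `design.tsv`, `total_mappable.tsv` and `truth.tsv`
#' under `dir`.
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             total_mappable = file.path(dir, "total_mappable.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_dge_table(sim$counts, paths[["counts"]])
  write_dge_table(as.data.frame(sim$design), paths[["design"]])
  write_total_mappable(sim$counts, paths[["total_mappable"]])
  write_dge_table(sim$truth, paths[["truth"]])
  invisible(paths)
}
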