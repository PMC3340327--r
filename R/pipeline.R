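#' Configuration of the end-to-end pipeline
#'
#' Bundles the inputs (file paths or a [simulation_config()]) with every
#' stage threshold.  The defaults reproduce the canonical analysis:
#' minimum tag 10, alpha 0.01, correlation 0.95, induction fold 2,
#' homology stringency 100 bp / 98% identity, proteome E-value cutoff
#' 1e-10 and the 500 bp large-transcript floor.
#'
#' @param out_dir output directory for all stage tables and the manifest.
#' @param counts_path,design_path,total_mappable_path input files for a
#'   real count matrix (see [read_count_matrix()]); ignored when
#'   `simulation` is given.
#' @param simulation optional [simulation_config()]; when supplied, the
#'   count matrix is generated and the truth table written alongside.
#' @param min_tag retention floor for [filter_min_tag()].
#' @param alpha,pseudocount DE-test settings for [genotype_de()].
#' @param genotype_r genotype treated as R in the contrast; defaults to
#'   the genotype with the most samples.
#' @param screen a [screen_config()].
#' @param seed_locus seed locus for [correlation_screen()]; defaults to
#'   the simulated seed locus when there is one, otherwise the screen is
#'   skipped.
#' @param correlation_samples samples for the correlation screen;
#'   defaults to the samples of the fully treated genotype.
#' @param transcripts_path,hits_path optional inputs enabling the
#'   assembly and homology stages.
#' @param min_overlap,min_identity,max_evalue homology stringency.
#' @param large_min_length large-transcript threshold (bp).
#' @param stages stages to run, a subset of the default vector.
#' @param seed RNG seed recorded in the manifest.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            counts_path = NULL, design_path = NULL,
                            total_mappable_path = NULL,
                            simulation = NULL,
                            min_tag = 10, alpha = 0.01, pseudocount = 1,
                            genotype_r = NULL,
                            screen = screen_config(),
                            seed_locus = NULL,
                            correlation_samples = NULL,
                            transcripts_path = NULL, hits_path = NULL,
                            min_overlap = 100, min_identity = 98,
                            max_evalue = 1e-10,
                            large_min_length = 500,
                            stages = c("normalize", "structure", "de",
                                       "screens", "assembly", "homology"),
                            seed = 1L) {
  if (is.null(simulation) && (is.null(counts_path) || is.null(design_path)))
    stop("either 'simulation' or 'counts_path' + 'design_path' required")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys are [pipeline_config()] arguments; the optional
#' `simulation:` and `screen:` mappings are passed to
#' [simulation_config()] and [screen_config()].
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation))
    y$simulation <- do.call(simulation_config, y$simulation)
  if (!is.null(y$screen)) y$screen <- do.call(screen_config, y$screen)
  do.call(pipeline_config, y)
}

#' Run the DGE pipeline end to end
#'
#' Executes normalize -> filter -> global structure -> differential
#' expression -> screens (-> assembly and homology statistics when inputs
#' are given), writing every stage table under `config$out_dir` together
#' with `manifest.json` recording the configuration, seed, per-stage locus
#' counts and an MD5 checksum of every written file.  Re-running an
#' identical configuration on identical inputs reproduces identical
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (list with `stages`, `counts_in_out`,
#'   `files`, `config_summary`, `seed`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage_counts <- list()
  ran <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$out_dir, name)
    write_dge_table(x, p)
    files <<- c(files, p)
    p
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- input -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- run_stage("simulate", simulate_counts(config$simulation))
    cm <- sim$counts
    design <- sim$design
    truth <- sim$truth
    emit(cm, "counts.tsv")
    emit(as.data.frame(design), "design.tsv")
    emit(truth, "truth.tsv")
    ran <- c(ran, "simulate")
  } else {
    inp <- run_stage("read", read_count_matrix(config$counts_path,
                                               config$design_path,
                                               config$total_mappable_path))
    cm <- inp$counts
    design <- inp$design
  }
  stage_counts$loci_in <- nrow(cm$counts)

  ## --- normalize + filter ------------------------------------------------
  nm <- run_stage("normalize", {
    nm <- normalize_tags(cm)
    filter_min_tag(nm, min_tag = config$min_tag)
  })
  stage_counts$loci_retained <- nrow(nm$values)
  emit(nm, "normalized_filtered.tsv")
  ran <- c(ran, "normalize")

  ## --- global structure --------------------------------------------------
  if ("structure" %in% config$stages) {
    run_stage("structure", {
      sim_out <- sample_correlation(nm)
      p <- file.path(config$out_dir, "sample_correlation.tsv")
      utils::write.table(round(sim_out$correlation, 10), p, sep = "\t",
                         quote = FALSE)
      files <- c(files, p)
      p <- file.path(config$out_dir, "sample_dendrogram.nwk")
      similarity_newick(sim_out, p)
      files <- c(files, p)
      pca <- dge_pca(nm)
      emit(data.frame(sample_id = rownames(pca$scores), pca$scores,
                      check.names = FALSE), "pca_scores.tsv")
      emit(data.frame(component = seq_along(pca$variance_explained),
                      variance = pca$variance_explained),
           "pca_variance.tsv")
    })
    ran <- c(ran, "structure")
  }

  ## --- differential expression -------------------------------------------
  if ("de" %in% config$stages) {
    de <- run_stage("de", {
      geno_r <- config$genotype_r
      if (is.null(geno_r))
        geno_r <- names(which.max(table(design$genotype)))
      other <- setdiff(unique(design$genotype), geno_r)
      if (length(other) != 1L)
        stop("need exactly two genotypes for the genotype contrast")
      ctr <- contrast(design$sample_id[design$genotype == geno_r],
                      design$sample_id[design$genotype == other],
                      geno_r, other)
      genotype_de(nm, ctr, alpha = config$alpha,
                  pseudocount = config$pseudocount)
    })
    stage_counts$n_de <- sum(de$is_de)
    emit(as.data.frame(de), "genotype_de.tsv")
    ran <- c(ran, "de")
  }

  ## --- screens -----------------------------------------------------------
  if ("screens" %in% config$stages) {
    run_stage("screens", {
      ## treated/untreated pairs: within each genotype x vernalization
      ## stratum holding one GA and one non-GA sample
      strata <- split(seq_len(nrow(design)),
                      paste(design$genotype, design$vernalized))
      pairs <- list()
      for (s in strata) {
        u <- design$sample_id[s][!design$ga[s]]
        g <- design$sample_id[s][design$ga[s]]
        if (length(u) == 1L && length(g) == 1L)
          pairs <- c(pairs, list(c(u, g)))
      }
      if (length(pairs)) {
        ga <- ga_induction_screen(nm, pairs = pairs, config = config$screen)
        emit(as.data.frame(ga), "ga_induction.tsv")
        stage_counts$n_ga_induced <- nrow(ga)
      }
      vsamp <- design$sample_id[design$vernalized & !design$ga]
      nsamp <- design$sample_id[!design$vernalized & !design$ga &
                                design$genotype %in%
                                  design$genotype[design$vernalized]]
      if (length(vsamp) >= 1L && length(nsamp) >= 1L) {
        vr <- rank_vernalization_response(nm, vsamp[1L], nsamp[1L],
                                          config = config$screen)
        emit(as.data.frame(vr), "vernalization_rank.tsv")
      }
      seed_locus <- config$seed_locus
      if (is.null(seed_locus) && !is.null(truth)) {
        sl <- truth$locus_id[truth$class == "seed"]
        if (length(sl) == 1L && sl %in% rownames(nm$values))
          seed_locus <- sl
      }
      if (!is.null(seed_locus)) {
        csamp <- config$correlation_samples
        if (is.null(csamp)) {
          full_geno <- design$genotype[design$vernalized][1L]
          csamp <- design$sample_id[design$genotype %in% full_geno]
          if (length(csamp) < 3L) csamp <- design$sample_id
        }
        cs <- correlation_screen(nm, seed_locus, csamp,
                                 config = config$screen)
        emit(cs$positive, "correlated_positive.tsv")
        emit(cs$negative, "correlated_negative.tsv")
        stage_counts$n_corr_pos <- nrow(cs$positive)
        stage_counts$n_corr_neg <- nrow(cs$negative)
      }
    })
    ran <- c(ran, "screens")
  }

  ## --- assembly statistics ------------------------------------------------
  if ("assembly" %in% config$stages && !is.null(config$transcripts_path)) {
    run_stage("assembly", {
      ts <- read_transcript_set(config$transcripts_path)
      st <- assembly_summary(ts, min_length = config$large_min_length)
      flat <- data.frame(
        key = c("n_transcripts", "n_loci", "n50_transcripts", "n50_loci",
                "n_large_transcripts", "n_large_loci", "min_length_bp",
                "max_length_bp", "total_length_bp"),
        value = c(st$n_transcripts, st$n_loci, st$n50_transcripts,
                  st$n50_loci, length(st$large_transcript_ids),
                  length(st$large_locus_ids), st$min_length_bp,
                  st$max_length_bp, st$total_length_bp))
      emit(flat, "assembly_stats.tsv")
    })
    ran <- c(ran, "assembly")
  }

  ## --- homology ----------------------------------------------------------
  if ("homology" %in% config$stages && !is.null(config$hits_path)) {
    run_stage("homology", {
      hits <- read_blast_hits(config$hits_path)
      filt <- stringency_filter(hits, min_overlap = config$min_overlap,
                                min_identity = config$min_identity)
      p <- file.path(config$out_dir, "hits_filtered.tsv")
      write_blast_hits(filt, p)
      files <- c(files, p)
      emit(best_hit_annotation(hits, max_evalue = config$max_evalue),
           "best_hits.tsv")
    })
    ran <- c(ran, "homology")
  }

  manifest <- list(
    package = "apexdge",
    version = as.character(utils::packageVersion("apexdge")),
    seed = config$seed,
    stages = ran,
    counts_in_out = stage_counts,
    config_summary = list(min_tag = config$min_tag, alpha = config$alpha,
                          pseudocount = config$pseudocount,
                          screen = unclass(config$screen),
                          min_overlap = config$min_overlap,
                          min_identity = config$min_identity,
                          max_evalue = config$max_evalue,
                          large_min_length = config$large_min_length,
                          simulated = !is.null(config$simulation)),
    files = lapply(stats::setNames(files, basename(files)), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
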