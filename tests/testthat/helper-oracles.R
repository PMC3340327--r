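# Independent oracles and small fixture builders, kept deliberately
# separate from the implementation paths they check.

# Textbook Pearson correlation via raw sums (vs stats::cor inside the
# package).
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Brute-force N50: scan every candidate length for the definition
# "largest L such that sequences of length >= L cover half the total".
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  ok <- vapply(sort(unique(lengths)), function(L)
    sum(lengths[lengths >= L]) >= total / 2, logical(1))
  max(sort(unique(lengths))[ok])
}

# Pooled-variance t via stats::t.test (vs the vectorized formula inside
# genotype_de).
t_oracle <- function(x, y) {
  unname(stats::t.test(x, y, var.equal = TRUE)$statistic)
}

# A random log-normal expression matrix with locus/sample names.
rand_matrix <- function(n_loci, samples, seed, mean_log2 = 6, sd_log2 = 1) {
  set.seed(seed)
  matrix(2^rnorm(n_loci * length(samples), mean_log2, sd_log2),
         nrow = n_loci,
         dimnames = list(sprintf("L%04d", seq_len(n_loci)), samples))
}

# A simulation with planted sets scaled down for small n_loci.
small_sim_config <- function(n_loci, seed, ...) {
  simulation_config(n_loci = n_loci, n_genotype_de = 8, n_vern_up = 8,
                    n_ga_up = 8, n_seed_partners_pos = 6,
                    n_seed_partners_neg = 2, seed = seed, ...)
}

# A tiny count_matrix from literal values.
tiny_counts <- function(values, samples = LETTERS[seq_len(ncol(values))],
                        total_mappable = NULL) {
  dimnames(values) <- list(sprintf("Locus_%d", seq_len(nrow(values))),
                           samples)
  count_matrix(values, total_mappable = total_mappable)
}
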