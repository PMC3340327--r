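test_that("duplicated samples correlate perfectly and merge first", {
  v <- rand_matrix(50, c("S1", "S3"), seed = 1)
  v <- cbind(v, S2 = v[, "S1"])[, c("S1", "S2", "S3")]
  sim <- sample_correlation(v, transform = "none")
  expect_equal(sim$correlation["S1", "S2"], 1, tolerance = 1e-12)
  first_pair <- sort(sim$hclust$labels[-sim$hclust$merge[1, ]])
  expect_identical(first_pair, c("S1", "S2"))
  expect_equal(sim$hclust$height[1], 0, tolerance = 1e-12)
})

test_that("Pearson correlation is invariant to positive rescaling", {
  v <- rand_matrix(80, LETTERS[1:4], seed = 2)
  w <- v
  w[, "B"] <- w[, "B"] * 7.5
  expect_equal(sample_correlation(v, transform = "none")$correlation,
               sample_correlation(w, transform = "none")$correlation,
               tolerance = 1e-12)
})

test_that("correlations match the textbook formula on random matrices", {
  for (s in 1:5) {
    v <- rand_matrix(1000, LETTERS[1:6], seed = 100 + s)
    r <- sample_correlation(v, transform = "none")$correlation
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(r[i, j], pearson_oracle(v[, i], v[, j]),
                   tolerance = 1e-10)
    }
  }
})

test_that("zero-variance samples are an error unless allowed through", {
  v <- rand_matrix(20, c("A", "B"), seed = 3)
  v <- cbind(v, FLAT = rep(5, 20))
  expect_error(sample_correlation(v, transform = "none"), "FLAT")
  sim <- sample_correlation(v, transform = "none", allow_constant = TRUE)
  expect_true(all(is.na(sim$correlation["FLAT", c("A", "B")])))
})

test_that("genotype dominates sample similarity on planted data", {
  cfg <- simulation_config(n_loci = 2000, n_genotype_de = 400,
                           n_vern_up = 0, n_ga_up = 0,
                           n_seed_partners_pos = 0, n_seed_partners_neg = 0,
                           planted_genotype_fold = 4, seed = 17)
  nm <- filter_min_tag(normalize_tags(simulate_counts(cfg)$counts))
  sim <- sample_correlation(nm)
  r <- sim$correlation
  expect_true(all(r[upper.tri(r)] > 0 & r[upper.tri(r)] < 1))
  cross <- r[c("A", "B", "E", "F"), c("C", "D")]
  within <- r[c("A", "B", "E", "F"), c("A", "B", "E", "F")]
  expect_lt(max(cross), min(within[upper.tri(within)]))
})

test_that("PCA satisfies the SVD identities and sign convention", {
  v <- rand_matrix(20, LETTERS[1:6], seed = 9)
  p <- dge_pca(v)
  lv <- log2(v + 1)
  # variance explained sums to the total variance of the transformed matrix
  expect_equal(sum(p$variance_explained), sum(apply(lv, 1, var)),
               tolerance = 1e-8)
  # components orthogonal
  ip <- crossprod(p$loadings)
  expect_equal(ip, diag(ncol(ip)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvalues of the locus covariance matrix agree (covariance oracle)
  ev <- eigen(cov(t(lv)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(p$variance_explained, ev[seq_along(p$variance_explained)],
               tolerance = 1e-8)
  # largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(p$loadings))) {
    l <- p$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }
})

test_that("PCA scores are stable under locus reordering and duplication", {
  v <- rand_matrix(30, LETTERS[1:5], seed = 21)
  p1 <- dge_pca(v)
  p2 <- dge_pca(v[rev(seq_len(nrow(v))), ])
  expect_equal(p1$scores, p2$scores, tolerance = 1e-8)

  w <- cbind(v, A2 = v[, "A"])
  ps <- dge_pca(w)
  expect_equal(ps$scores["A", ], ps$scores["A2", ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(dge_pca(matrix(0, 3, 3,
                              dimnames = list(1:3, c("a", "b", "c")))),
               "all-zero")
})

test_that("the leading component separates a planted genotype axis", {
  cfg <- simulation_config(n_loci = 1500, n_genotype_de = 300,
                           n_vern_up = 0, n_ga_up = 0,
                           n_seed_partners_pos = 0, n_seed_partners_neg = 0,
                           planted_genotype_fold = 4, seed = 23)
  sim <- simulate_counts(cfg)
  nm <- filter_min_tag(normalize_tags(sim$counts))
  p <- dge_pca(nm)
  s1 <- p$scores[, 1]
  rob <- sim$design$sample_id[sim$design$genotype == "Roberta"]
  c600 <- setdiff(sim$design$sample_id, rob)
  expect_identical(length(unique(sign(s1[rob]))), 1L)
  expect_identical(length(unique(sign(s1[c600]))), 1L)
  expect_true(sign(s1[rob][1]) != sign(s1[c600][1]))
})

test_that("component order follows planted effect sizes on the full design", {
  # genotype > vernalization > GA planted at 4 : 2 : 1.5 fold
  cfg <- simulation_config(n_loci = 3000, n_genotype_de = 300,
                           n_vern_up = 300, n_ga_up = 300,
                           n_seed_partners_pos = 0, n_seed_partners_neg = 0,
                           planted_genotype_fold = 4, planted_vern_fold = 2,
                           planted_ga_fold = 2, seed = 29)
  sim <- simulate_counts(cfg)
  nm <- filter_min_tag(normalize_tags(sim$counts))
  p <- dge_pca(nm)
  scores <- p$scores
  d <- sim$design
  sep <- function(s, grp)  # between-group gap on one component
    abs(mean(s[d$sample_id[grp]]) - mean(s[d$sample_id[!grp]]))
  geno_axis <- which.max(vapply(1:5, function(k)
    sep(scores[, k], d$genotype == "Roberta"), numeric(1)))
  vern_axis <- which.max(vapply(1:5, function(k)
    sep(scores[, k], d$vernalized), numeric(1)))
  expect_lte(geno_axis, vern_axis)
})
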