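vals4 <- function(...) {
  v <- rbind(...)
  colnames(v) <- c("A", "B", "E", "F")[seq_len(ncol(v))]
  v
}

test_that("vernalization ranking requires expression on both sides", {
  v <- vals4("only_vern" = c(0, 0, 500, 0),
             "rav_like"  = c(147, 55, 474, 1410),
             "mild"      = c(100, 80, 110, 90),
             "silent"    = c(1, 2, 3, 4))
  rep <- rank_vernalization_response(v, vern_sample = "E",
                                     nonvern_sample = "A")
  # locus expressed only in the vernalized sample is excluded
  expect_false("only_vern" %in% rep$locus_id)
  expect_false("silent" %in% rep$locus_id)
  # 474/147 outranks 110/100
  expect_identical(rep$locus_id, c("rav_like", "mild"))
  expect_lt(rep$fold[2], rep$fold[1])
  expect_error(rank_vernalization_response(v, "Z", "A"), "unknown")
  # everything below floor: empty report
  empty <- rank_vernalization_response(v / 1000, "E", "A")
  expect_identical(nrow(empty), 0L)
})

test_that("exact linear and negative-affine transforms hit r = +/-1", {
  seedp <- c(147, 55, 474, 1410)
  v <- vals4(seed = seedp, twice = 2 * seedp, anti = 1500 - seedp,
             flat = rep(3, 4), noise = c(200, 180, 210, 190))
  scr <- correlation_screen(v, "seed", samples = colnames(v))
  expect_true("twice" %in% scr$positive$locus_id)
  expect_equal(scr$r[["twice"]], 1, tolerance = 1e-12)
  expect_true("anti" %in% scr$negative$locus_id)
  expect_equal(scr$r[["anti"]], -1, tolerance = 1e-12)
  expect_false("seed" %in% c(scr$positive$locus_id, scr$negative$locus_id))
  expect_identical(scr$n_skipped, 1L)  # the constant locus
})

test_that("screen correlations match the textbook Pearson formula", {
  seedp <- c(147, 55, 474, 1410)
  cand <- c(150, 60, 400, 1200)
  v <- vals4(seed = seedp, cand = cand)
  scr <- correlation_screen(v, "seed", samples = colnames(v))
  r_oracle <- pearson_oracle(cand, seedp)
  expect_equal(scr$r[["cand"]], r_oracle, tolerance = 1e-10)
  expect_identical("cand" %in% scr$positive$locus_id, r_oracle >= 0.95)

  # every locus of a random 4-sample matrix agrees with the oracle
  m <- rand_matrix(300, c("A", "B", "E", "F"), seed = 51)
  scr <- correlation_screen(m, rownames(m)[1], samples = colnames(m))
  for (i in seq(2, 300, by = 13)) {
    expect_equal(scr$r[[rownames(m)[i]]],
                 pearson_oracle(m[i, ], m[1, ]), tolerance = 1e-10)
  }
})

test_that("correlation screen validates its inputs", {
  v <- vals4(seed = c(1, 2, 3, 4), other = c(4, 3, 2, 1))
  expect_error(correlation_screen(v, "missing", colnames(v)), "missing")
  expect_error(correlation_screen(v, "seed", c("A", "B")), "3 samples")
  flat <- vals4(seed = rep(2, 4), other = c(4, 3, 2, 1))
  expect_error(correlation_screen(flat, "seed", colnames(flat)), "constant")
})

test_that("the GA-induction predicate matches hand evaluation", {
  v <- rbind(pass  = c(100, 200, 100, 210, 100, 250),
             skew  = c(100, 300, 10, 30, 100, 300),
             weak  = c(100, 150, 100, 210, 100, 250),
             zero  = rep(0, 6))
  colnames(v) <- LETTERS[1:6]
  # pseudocount 0 so the hand-computed ratios 2.0, 2.1, 2.5 are exact
  rep <- ga_induction_screen(v, config = screen_config(pseudocount = 0))
  # similar untreated (100,100,100) and >= 2-fold in every pair: passes
  expect_identical(rep$locus_id, "pass")
  ev <- attr(rep, "evidence")
  expect_false(ev$similar[ev$locus_id == "skew"])   # 10-fold spread
  expect_false(ev$induced[ev$locus_id == "weak"])   # one pair below 2-fold
  expect_false(ev$expressed[ev$locus_id == "zero"]) # expression floor
  expect_error(ga_induction_screen(v, pairs = list(c("A", "B"), c("B", "C"))),
               "more than one role")
})

test_that("screen predicates are pure and re-checkable", {
  m <- abs(rand_matrix(400, LETTERS[1:6], seed = 52, mean_log2 = 5))
  cfg <- screen_config()
  rep <- ga_induction_screen(m, config = cfg)
  ev <- attr(rep, "evidence")
  pc <- cfg$pseudocount
  for (id in ev$locus_id[ev$pass]) {
    u <- m[id, c("A", "C", "E")] + pc
    g <- m[id, c("B", "D", "F")] + pc
    expect_lte(max(u) / min(u), cfg$similarity_max_fold)
    expect_true(all(g / u >= cfg$induction_fold))
  }
  expect_setequal(rep$locus_id, ev$locus_id[ev$pass])
})

test_that("tightening any threshold never grows a passing set", {
  for (s in 1:3) {
    m <- rand_matrix(500, LETTERS[1:6], seed = 60 + s, sd_log2 = 0.6)
    loose <- ga_induction_screen(m, config = screen_config(
      induction_fold = 1.2, similarity_max_fold = 3, expression_floor = 5))
    for (cfg in list(screen_config(induction_fold = 1.5,
                                   similarity_max_fold = 3,
                                   expression_floor = 5),
                     screen_config(induction_fold = 1.2,
                                   similarity_max_fold = 2,
                                   expression_floor = 5),
                     screen_config(induction_fold = 1.2,
                                   similarity_max_fold = 3,
                                   expression_floor = 50))) {
      tight <- ga_induction_screen(m, config = cfg)
      expect_true(all(tight$locus_id %in% loose$locus_id))
    }
    scr90 <- correlation_screen(m, rownames(m)[1], LETTERS[1:6],
                                config = screen_config(
                                  correlation_threshold = 0.90))
    scr99 <- correlation_screen(m, rownames(m)[1], LETTERS[1:6],
                                config = screen_config(
                                  correlation_threshold = 0.99))
    expect_true(all(scr99$positive$locus_id %in% scr90$positive$locus_id))
    expect_true(all(scr99$negative$locus_id %in% scr90$negative$locus_id))
  }
})
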