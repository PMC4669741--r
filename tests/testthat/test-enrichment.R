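test_that("KS comparison handles identical, separated and small samples", {
  same <- ks_compare(1:20, 1:20)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  sep <- ks_compare(rnorm(50), rnorm(50) + 100)
  expect_equal(sep$D, 1)
  small <- ks_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(small$D, 1)
  expect_equal(small$p, oracle_ks_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")
  expect_error(ks_compare(c(NA, NA), 1:3), "non-empty")
})

test_that("exact KS p-values match exhaustive permutation enumeration", {
  set.seed(51)
  for (i in 1:8) {
    a <- rnorm(sample(3:5, 1))
    b <- rnorm(sample(3:5, 1))
    expect_equal(ks_compare(a, b)$p, oracle_ks_exact_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("KS p is invariant under common strictly monotone transforms", {
  set.seed(52)
  a <- rexp(30) + 0.1
  b <- rexp(40) * 1.8 + 0.1
  base <- ks_compare(a, b)
  for (f in list(log, sqrt, function(x) x^3, function(x) -1 / x)) {
    tr <- ks_compare(f(a), f(b))
    expect_equal(tr$D, base$D)
    expect_equal(tr$p, base$p)
  }
})

test_that("contingency reconstruction rounds halves away from zero", {
  t1 <- reconstruct_table(62, 156, 35, 49)
  expect_equal(unname(t1[1, ]), c(97L, 59L))
  expect_equal(unname(t1[2, ]), c(17L, 32L))
  t2 <- reconstruct_table(0, 10, 100, 10)
  expect_equal(unname(t2[, 1]), c(0L, 10L))
  t3 <- reconstruct_table(50, 3, 50, 3)
  expect_equal(unname(t3[, 1]), c(2L, 2L))  # round(1.5) -> 2, half away
  expect_error(reconstruct_table(120, 10, 10, 10), "0, 100")
})

test_that("Fisher's exact matches curated values and handles degeneracy", {
  expect_equal(fisher_exact(contingency_table(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact(contingency_table(5, 0, 0, 5)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(contingency_table(0, 10, 0, 8)), 1)
  expect_equal(fisher_exact(contingency_table(0, 0, 3, 4)), 1)
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher's exact is invariant to transposition and row/col swaps", {
  set.seed(53)
  for (i in 1:30) {
    x <- matrix(rpois(4, 8), 2)
    p <- fisher_exact(x)
    expect_equal(fisher_exact(t(x)), p, tolerance = 1e-10)
    expect_equal(fisher_exact(x[2:1, ]), p, tolerance = 1e-10)
    expect_equal(fisher_exact(x[2:1, 2:1]), p, tolerance = 1e-10)
  }
})

test_that("Fisher's exact agrees with hypergeometric enumeration (random tables)", {
  set.seed(54)
  for (i in 1:100) {
    x <- rpois(4, sample(c(2, 8, 20), 1))
    expect_equal(fisher_exact(contingency_table(x[1], x[2], x[3], x[4])),
                 oracle_fisher_two_sided(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-10)
  }
})

test_that("percentage rounding bounds the precision of reconstructed tables", {
  # counts consistent with printed '62% of 156 vs 35% of 49' span a
  # factor-of-2 bracket of Fisher p-values around 1e-3
  p_hi <- fisher_exact(contingency_table(96, 60, 17, 32))
  p_lo <- fisher_exact(contingency_table(97, 59, 17, 32))
  expect_equal(round(p_hi, 4), 0.0016)
  expect_equal(round(p_lo, 4), 0.0009)
  expect_lt(p_lo, p_hi)
  # the published G4 comparison (80 vs 36%) is not consistent with these
  # group sizes under any standard 2x2 test: reconstruction gives p << 1e-4
  p_g4 <- fisher_exact(reconstruct_table(80, 156, 36, 49))
  expect_lt(p_g4, 1e-6)
})

test_that("group percentages report counts and rounded shares", {
  flags <- c(rep(TRUE, 97), rep(FALSE, 59), rep(TRUE, 17), rep(FALSE, 32))
  groups <- c(rep("dep", 156), rep("indep", 49))
  gp <- group_percentages(flags, groups)
  expect_equal(gp$pct_rounded[gp$group == "dep"], 62)
  expect_equal(gp$pct_rounded[gp$group == "indep"], 35)
  expect_equal(group_percentages(rep(FALSE, 5), rep("g", 5))$pct, 0)
  expect_equal(group_percentages(rep(TRUE, 5), rep("g", 5))$pct, 100)
  empty <- group_percentages(logical(0), character(0))
  expect_equal(nrow(empty), 0)
})

test_that("the enrichment report compares classes on features and flags", {
  set.seed(55)
  dep <- simulate_utrs(utr_sim_spec(60, gc_target = 0.7, seed = 61,
                                    length_range = c(80, 160)))
  ind <- simulate_utrs(utr_sim_spec(40, gc_target = 0.35, seed = 62,
                                    length_range = c(80, 160)))
  seqs <- c(dep$sequences, ind$sequences)
  names(seqs) <- sprintf("u%03d", seq_along(seqs))
  ft <- utr_features(seqs)
  cls <- c(rep("dependent", 60), rep("independent", 40))
  rep_out <- enrichment_report(ft, cls, adjust = TRUE)
  gc_row <- rep_out$continuous[rep_out$continuous$feature == "gc", ]
  expect_gt(gc_row$median_a, gc_row$median_b)
  expect_lt(gc_row$p, 1e-6)
  expect_true(all(rep_out$motifs$p_adj >= rep_out$motifs$p))
  expect_error(enrichment_report(ft, rep("dependent", 100)), "non-empty")
})
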