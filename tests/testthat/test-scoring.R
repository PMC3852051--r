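test_that("pair_counts skips gap columns and counts mismatches", {
  fams <- toy_families()
  c_a <- pair_counts(fams$a, "a1", "a2")
  expect_equal(c_a$delta, 11L)
  expect_equal(c_a$ell, 12L)
  c_b <- pair_counts(fams$b, "b1", "b2")
  expect_equal(list(c_b$delta, c_b$ell), list(15L, 19L))
  expect_equal(pair_counts(fams$b, "b1", "b3")$delta, 3L)

  # identity: no mismatches, ell = non-gap width
  self <- pair_counts(fams$a, "a1", "a1")
  expect_equal(self$delta, 0L)
  expect_equal(self$ell, 13L)

  # complementary gaps: nothing comparable
  fam <- aligned_family("g", c("x_S", "y_S"), c("AC--", "--AC"), c("S", "S"))
  cc <- pair_counts(fam, "x_S", "y_S")
  expect_equal(list(cc$delta, cc$ell), list(0L, 0L))

  expect_error(pair_counts(fams$a, "a1", "nope"), class = "coevomap_lookup")
})

test_that("unit scores reproduce the worked two-species example", {
  s1 <- unit_log_score(list(delta = 11, ell = 12), list(delta = 15, ell = 19))
  expect_equal(exp(s1), 0.274, tolerance = 5e-4 / 0.274)
  s2 <- unit_log_score(list(delta = 11, ell = 12), list(delta = 3, ell = 19))
  expect_lt(abs(exp(s2) - 4.4e-5), 0.05e-5)
})

test_that("unit_log_score is symmetric, bounded and matches dhyper", {
  set.seed(11)
  for (rep in 1:50) {
    lA <- sample(0:60, 1); lB <- sample(0:60, 1)
    dA <- if (lA) sample(0:lA, 1) else 0L
    dB <- if (lB) sample(0:lB, 1) else 0L
    s <- unit_log_score(list(delta = dA, ell = lA), list(delta = dB, ell = lB))
    expect_identical(s, unit_log_score(list(delta = dB, ell = lB),
                                       list(delta = dA, ell = lA)))
    expect_true(is.finite(s))
    expect_lte(s, 0)
    # independent oracle: the hypergeometric density
    expect_equal(s, dhyper(dA, lA, lB, dA + dB, log = TRUE), tolerance = 1e-12)
  }
  # zero mismatches on both sides is certain under equal rates
  expect_identical(unit_log_score(list(delta = 0, ell = 9),
                                  list(delta = 0, ell = 4)), 0)
  expect_error(unit_log_score(list(delta = 5, ell = 3), list(delta = 0, ell = 1)),
               class = "coevomap_domain")
})

test_that("hypergeometric pmf normalizes to 1 over its support", {
  for (lA in c(1L, 7L, 50L, 200L)) for (lB in c(1L, 13L, 200L)) {
    for (Tt in unique(c(0L, 1L, lA, (lA + lB) %/% 2L, lA + lB))) {
      dA <- max(0L, Tt - lB):min(Tt, lA)
      tot <- sum(exp(coevomap:::hyper_log_pmf(dA, lA, Tt - dA, lB)))
      expect_equal(tot, 1, tolerance = 1e-9)
    }
  }
})

test_that("equal mismatch splits score best when lengths are equal", {
  for (L in c(10L, 20L)) for (Tt in c(4L, 10L, 2L * L)) {
    dA <- max(0L, Tt - L):min(Tt, L)
    sc <- coevomap:::hyper_log_pmf(dA, L, Tt - dA, L)
    expect_equal(dA[which.max(sc)], Tt %/% 2L)
  }
})

test_that("build_score_table enumerates exactly the admissible quadruples", {
  fams <- toy_families()
  g <- build_graph(fams$a, fams$b)
  tab <- build_score_table(fams$a, fams$b, g)
  # brute-force: pairs of distinct edges with distinct A and B endpoints
  E <- nrow(g$edges)
  expected <- 0L
  for (e1 in seq_len(E - 1L)) for (e2 in (e1 + 1L):E) {
    if (g$edges[e1, 1L] != g$edges[e2, 1L] && g$edges[e1, 2L] != g$edges[e2, 2L])
      expected <- expected + 1L
  }
  expect_equal(nrow(tab$quads), expected)
  expect_true(all(is.finite(tab$log_f)) && all(tab$log_f <= 0))
  expect_gt(tab$offset_K, 0)
  expect_true(all(tab$log_f + tab$offset_K > 0))
  expect_equal(tab$w, (tab$log_f + tab$offset_K) / 2)

  # single-edge graph: no quadruples, margin-only offset
  fa1 <- aligned_family("sA", "a_S1", "ACDE", "S1")
  fb1 <- aligned_family("sB", "b_S1", "ACDF", "S1")
  g1 <- build_graph(fa1, fb1)
  t1 <- build_score_table(fa1, fb1, g1)
  expect_equal(nrow(t1$quads), 0L)
  expect_equal(t1$offset_K, 1)

  # two species with one edge each: a single cross-species quadruple
  fa2 <- aligned_family("tA", c("a_S1", "a_S2"), c("ACDE", "ACDQ"), c("S1", "S2"))
  fb2 <- aligned_family("tB", c("b_S1", "b_S2"), c("ACDF", "ACWF"), c("S1", "S2"))
  g2 <- build_graph(fa2, fb2)
  expect_equal(nrow(build_score_table(fa2, fb2, g2)$quads), 1L)
})

test_that("coevolution degree is the mean unit score of a pair", {
  ri <- random_instance(21, n_species = 2L, paralogs = c(2L, 2L))
  tm <- truth_matching(ri$inst, ri$graph)
  n <- nrow(tm)
  expect_gte(n, 2L)
  pair <- tm[1L, ]
  deg <- coevolution_degree(pair, tm, ri$table)
  # direct recomputation from individual unit scores
  others <- tm[-1L, , drop = FALSE]
  direct <- mean(vapply(seq_len(n - 1L), function(r) {
    two <- coevomap:::new_matching(rbind(tm[1L, ], others[r, ]))
    log_likelihood(two, ri$table)
  }, numeric(1)))
  expect_equal(deg, direct, tolerance = 1e-12)

  # size-2 matching: the degree is the single unit's log score
  two <- coevomap:::new_matching(tm[1:2, ])
  expect_equal(coevolution_degree(two[1L, ], two, ri$table),
               log_likelihood(two, ri$table))
  one <- coevomap:::new_matching(tm[1L, , drop = FALSE])
  expect_error(coevolution_degree(one[1L, ], one, ri$table),
               class = "coevomap_domain")
})
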