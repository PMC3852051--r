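test_that("the assignment primitive is exact against brute force", {
  brute <- function(P) {
    nr <- nrow(P); nc <- ncol(P)
    best <- -Inf
    if (nr <= nc) {
      for (pp in coevomap:::injections(seq_len(nc), nr))
        best <- max(best, sum(P[cbind(seq_len(nr), pp)]))
    } else {
      for (pp in coevomap:::injections(seq_len(nr), nc))
        best <- max(best, sum(P[cbind(pp, seq_len(nc))]))
    }
    best
  }
  set.seed(2)
  for (rep in 1:100) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    P <- matrix(runif(nr * nc), nr, nc)
    expect_equal(coevomap:::assign_max(P)$value, brute(P), tolerance = 1e-12)
  }
})

test_that("local profits solve the partner matching exactly", {
  # single-edge graph: no partners
  fa1 <- aligned_family("sA", "a_S1", "ACDE", "S1")
  fb1 <- aligned_family("sB", "b_S1", "ACDF", "S1")
  g1 <- build_graph(fa1, fb1)
  t1 <- build_score_table(fa1, fb1, g1)
  expect_equal(local_profit(1L, 1L, numeric(0), t1), 0)
  expect_error(local_profit(2L, 1L, numeric(0), t1), class = "coevomap_domain")

  # one partner edge at lambda = 0: profit is its half-weight
  fa2 <- aligned_family("tA", c("a_S1", "a_S2"), c("ACDE", "ACDQ"), c("S1", "S2"))
  fb2 <- aligned_family("tB", c("b_S1", "b_S2"), c("ACDF", "ACWF"), c("S1", "S2"))
  g2 <- build_graph(fa2, fb2)
  t2 <- build_score_table(fa2, fb2, g2)
  expect_equal(local_profit(1L, 1L, numeric(1), t2), t2$w[1L])

  # 3x3 partner grid: exhaustive maximum over partner matchings
  ri <- random_instance(13, n_species = 2L, paralogs = c(2L, 2L))
  tab <- ri$table
  lambda <- numeric(nrow(tab$quads))
  e <- 1L
  i <- tab$edges[e, 1L]; k <- tab$edges[e, 2L]
  partners <- which(tab$qindex[e, ] > 0L)
  best <- 0
  for (size in seq_len(length(partners))) {
    for (sel in utils::combn(partners, size, simplify = FALSE)) {
      if (anyDuplicated(tab$edges[sel, 1L]) || anyDuplicated(tab$edges[sel, 2L]))
        next
      best <- max(best, sum(tab$w[tab$qindex[e, sel]]))
    }
  }
  expect_equal(local_profit(i, k, lambda, tab), best, tolerance = 1e-12)
})

test_that("the dual bound dominates the exact optimum at lambda = 0", {
  for (seed in c(3, 8, 14)) {
    ri <- random_instance(seed)
    if (count_max_matchings(ri$graph) > 2e4) next
    opt <- oracle_optimum(ri$graph, ri$table)
    db <- dual_bound(numeric(nrow(ri$table$quads)), ri$table)
    expect_gte(db$value, opt - 1e-9)
    expect_equal(nrow(db$x), ri$graph$n)
    # classical decomposition bound: sum of selected local profits
    eids <- coevomap:::edge_ids(db$x, ri$table)
    expect_equal(db$value,
                 sum(db$v[eids]) - choose(ri$graph$n, 2) * ri$table$offset_K,
                 tolerance = 1e-9)
    prim <- primal_from_dual(db$x, ri$table)
    expect_lte(prim$lower_bound, db$value + 1e-9)
  }
})

test_that("solver bounds are valid, monotone and deterministic", {
  ri <- random_instance(4)
  ctrl <- solver_control(max_iter = 120L, time_limit = 30)
  res1 <- solve_matching(ri$graph, ri$table, ctrl)
  res2 <- solve_matching(ri$graph, ri$table, ctrl)
  expect_identical(res1[c("matching", "lower_bound", "upper_bound",
                          "relative_gap", "iterations")],
                   res2[c("matching", "lower_bound", "upper_bound",
                          "relative_gap", "iterations")])
  tr <- res1$trace
  expect_true(all(tr$lower <= tr$upper + 1e-9))        # weak duality each iteration
  expect_false(is.unsorted(tr$best_lower))             # best bounds monotone
  expect_false(is.unsorted(rev(tr$best_upper)))
  expect_equal(res1$lower_bound, log_likelihood(res1$matching, ri$table))
})

test_that("a uniform score table is solved at the first iteration", {
  # identical sequences make every unit score log(1) = 0: all matchings tie
  ids_a <- c("a1_S1", "a2_S1", "a3_S2")
  ids_b <- c("b1_S1", "b2_S1", "b3_S2")
  fa <- aligned_family("uA", ids_a, rep("ACDEACDE", 3L), c("S1", "S1", "S2"))
  fb <- aligned_family("uB", ids_b, rep("ACDEACDW", 3L), c("S1", "S1", "S2"))
  g <- build_graph(fa, fb)
  tab <- build_score_table(fa, fb, g)
  res <- solve_matching(g, tab)
  expect_equal(res$iterations, 1L)
  expect_true(res$proved_optimal)
  expect_equal(res$relative_gap, 0)
  expect_equal(res$lower_bound, 0)

  # n = 1: single best edge, zero bounds
  fa1 <- aligned_family("oA", "a_S1", "ACDE", "S1")
  fb1 <- aligned_family("oB", c("b1_S1", "b2_S1"), c("ACDE", "WWWW"), c("S1", "S1"))
  g1 <- build_graph(fa1, fb1)
  t1 <- build_score_table(fa1, fb1, g1)
  r1 <- solve_matching(g1, t1)
  expect_equal(r1$lower_bound, 0)
  expect_equal(r1$upper_bound, 0)
  expect_equal(nrow(r1$matching), 1L)
})

test_that("small random instances are mostly solved to proven optimality", {
  proved <- 0L; total <- 0L
  for (seed in 101:110) {
    ri <- random_instance(seed)
    if (count_max_matchings(ri$graph) > 2e4) next
    total <- total + 1L
    opt <- oracle_optimum(ri$graph, ri$table)
    res <- solve_matching(ri$graph, ri$table,
                          solver_control(max_iter = 400L, time_limit = 30))
    expect_lte(res$lower_bound, opt + 1e-9)
    expect_gte(res$upper_bound, opt - 1e-9)
    if (res$proved_optimal) {
      proved <- proved + 1L
      expect_equal(res$lower_bound, opt, tolerance = 1e-6)
    }
  }
  expect_gte(proved / total, 0.9)
})
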