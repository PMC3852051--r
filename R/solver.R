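# Lagrangian relaxation of the offset-shifted quadratic matching program.
#
# Each unit of coevolution (two disjoint edges (i,k), (j,l), i < j) carries
# weight w = (log f + K)/2 in each of the two local problems that see it.
# The relaxation dualizes the symmetry constraint between the two copies with
# one multiplier per oriented quadruple: the local problem of edge (i,k)
# weighs partner (j,l) as w + lambda when i < j and w - lambda when j < i.
# For any lambda the master matching over local profits v_ik(lambda) is an
# upper bound; any feasible master matching scored by the true likelihood is
# a lower bound.

# per-edge partner structures reused every iteration
solver_prep <- function(table) {
  E <- nrow(table$edges)
  lapply(seq_len(E), function(e) {
    p <- which(table$qindex[e, ] > 0L)
    if (!length(p)) {
      return(list(p = integer(0)))
    }
    q <- table$qindex[e, p]
    sgn <- ifelse(table$edges[p, 1L] > table$edges[e, 1L], 1, -1)
    jv <- table$edges[p, 1L]; lv <- table$edges[p, 2L]
    urow <- sort(unique(jv)); ucol <- sort(unique(lv))
    row <- match(jv, urow); col <- match(lv, ucol)
    nr <- length(urow); nc <- length(ucol)
    cells <- (col - 1L) * nr + row
    cell2p <- integer(nr * nc)
    cell2p[cells] <- seq_along(p)
    list(p = p, q = q, sgn = sgn, nr = nr, nc = nc,
         cells = cells, cell2p = cell2p)
  })
}

local_solve <- function(st, lambda, table) {
  if (!length(st$p)) return(list(v = 0, chosen = integer(0)))
  wts <- table$w[st$q] + st$sgn * lambda[st$q]
  pos <- wts > 0
  if (!any(pos)) return(list(v = 0, chosen = integer(0)))
  M <- matrix(0, st$nr, st$nc)
  M[st$cells[pos]] <- wts[pos]
  res <- assign_max(M)
  acells <- (res$pairs[, 2L] - 1L) * st$nr + res$pairs[, 1L]
  pidx <- st$cell2p[acells]
  pidx <- pidx[pidx > 0L]
  pidx <- pidx[wts[pidx] > 0]
  list(v = res$value, chosen = pidx)
}

#' Local Lagrangian profit of one graph edge
#'
#' Solves the local subproblem of edge (i,k): a maximum-weight bipartite
#' matching over candidate partner edges (j,l) disjoint from (i,k), each
#' weighted by the shifted half-weight adjusted by its multiplier (added for
#' i < j, subtracted for j < i). Only strictly positive adjusted weights can
#' be selected, so the profit is non-negative.
#'
#' @param i,k node indices of a graph edge.
#' @param lambda multiplier vector, one entry per quadruple in
#'   \code{table$quads} (0 = unadjusted).
#' @param table a \code{\link{build_score_table}} result.
#' @return The local profit v_ik(lambda), a non-negative number.
#' @export
local_profit <- function(i, k, lambda, table) {
  e <- which(table$edges[, 1L] == i & table$edges[, 2L] == k)
  if (!length(e))
    stop_coevomap("domain", sprintf("(%d, %d) is not a graph edge", i, k))
  if (length(lambda) != nrow(table$quads))
    stop_coevomap("domain", "lambda must have one entry per quadruple")
  st <- solver_prep(table)[[e]]
  local_solve(st, lambda, table)$v
}

dual_bound_internal <- function(lambda, table, prep) {
  E <- nrow(table$edges)
  v <- numeric(E)
  chosen <- vector("list", E)
  for (e in seq_len(E)) {
    ls <- local_solve(prep[[e]], lambda, table)
    v[e] <- ls$v
    chosen[[e]] <- ls$chosen
  }
  # master: per species component, a maximum-weight assignment of the full
  # smaller side (cardinality forced structurally, zero-profit edges allowed)
  x <- matrix(integer(0), 0L, 2L)
  raw <- 0
  for (p in table$species_parts) {
    V <- matrix(0, length(p$a), length(p$b))
    key <- outer((p$a - 1) * table$n_b, p$b, "+")
    eid <- match(key, table$edge_key)
    V[] <- v[eid]
    res <- assign_max(V)
    raw <- raw + res$value
    x <- rbind(x, cbind(p$a[res$pairs[, 1L]], p$b[res$pairs[, 2L]]))
  }
  x <- new_matching(x)
  list(value = raw - choose(table$n, 2) * table$offset_K,
       x = x, v = v, chosen = chosen,
       x_edge_ids = edge_ids(x, table))
}

#' Lagrangian dual bound at a given multiplier vector
#'
#' Computes the master maximum-weight maximum-cardinality matching over the
#' local profits v_ik(lambda), one component per species. The returned value
#' (translated to the log-likelihood scale by subtracting
#' \code{choose(n,2) * K}) is an upper bound on the optimal log likelihood
#' for any lambda.
#'
#' @inheritParams local_profit
#' @return List with \code{value} (upper bound, log-likelihood scale),
#'   \code{x} (the master matching, a feasible matching of cardinality n) and
#'   \code{v} (local profits per edge).
#' @export
dual_bound <- function(lambda, table) {
  if (length(lambda) != nrow(table$quads))
    stop_coevomap("domain", "lambda must have one entry per quadruple")
  db <- dual_bound_internal(lambda, table, solver_prep(table))
  db[c("value", "x", "v")]
}

#' Feasible matching and lower bound from a master solution
#'
#' @param x a feasible matching of maximum cardinality (e.g. the master
#'   matching from \code{\link{dual_bound}}).
#' @param table a \code{\link{build_score_table}} result.
#' @return List with the matching and its log likelihood, a valid lower
#'   bound on the optimum.
#' @export
primal_from_dual <- function(x, table) {
  if (nrow(x) != table$n)
    stop_coevomap("validity",
                  sprintf("master matching has size %d, expected n = %d",
                          nrow(x), table$n))
  list(matching = x, lower_bound = log_likelihood(x, table))
}

# deterministic within-species 2-swap (and swap-with-unmatched) improvement;
# first-improvement strategy with a full rescan after every accepted move
improve_matching <- function(matching, ll, table) {
  step_once <- function(matching, ll) {
    for (p in table$species_parts) {
      rows <- which(matching[, 1L] %in% p$a)
      if (!length(rows)) next
      if (length(rows) >= 2L) {
        for (r1 in rows) for (r2 in rows[rows > r1]) {
          cand <- matching
          cand[c(r1, r2), 2L] <- cand[c(r2, r1), 2L]
          cll <- log_likelihood(cand, table)
          if (cll > ll + 1e-12) return(list(matching = cand, ll = cll))
        }
      }
      free_b <- setdiff(p$b, matching[rows, 2L])
      for (r in rows) for (b in free_b) {
        cand <- matching
        cand[r, 2L] <- b
        cll <- log_likelihood(cand, table)
        if (cll > ll + 1e-12) return(list(matching = cand, ll = cll))
      }
    }
    NULL
  }
  repeat {
    mv <- step_once(matching, ll)
    if (is.null(mv)) break
    matching <- mv$matching
    ll <- mv$ll
  }
  list(matching = new_matching(matching), ll = ll)
}

#' Solver control parameters
#'
#' @param max_iter iteration cap (default 300).
#' @param time_limit wall-clock limit in seconds (default 300, i.e. 5
#'   minutes: bound quality saturates beyond that on realistic instances).
#' @param gap_tol relative gap below which the solution is declared optimal
#'   (default 1e-6).
#' @param mu initial subgradient step scale (Polyak/Held-Karp style step
#'   \code{mu * (upper - lower) / ||g||^2}, default 2).
#' @param half_after halve \code{mu} after this many consecutive
#'   non-improving upper bounds (default 20).
#' @param dd_every attempt a dual-descent move every this many iterations
#'   (default 5); the move is kept only if it strictly decreases the dual
#'   bound, so the scheme never degrades the subgradient trajectory.
#' @param dd_shrink dual-descent shrink factor toward the multiplier value
#'   that equalizes the two oriented local profits of a violated unit
#'   (default 0.5).
#' @param local_search improve primal matchings by deterministic
#'   within-species 2-swaps (default TRUE).
#' @param seed echoed into results for provenance; the solver itself is
#'   deterministic.
#' @return List of class \code{solver_control}.
#' @export
solver_control <- function(max_iter = 300L, time_limit = 300, gap_tol = 1e-6,
                           mu = 2, half_after = 20L, dd_every = 5L,
                           dd_shrink = 0.5, local_search = TRUE, seed = 1L) {
  structure(list(max_iter = as.integer(max_iter), time_limit = time_limit,
                 gap_tol = gap_tol, mu = mu, half_after = as.integer(half_after),
                 dd_every = as.integer(dd_every), dd_shrink = dd_shrink,
                 local_search = isTRUE(local_search), seed = seed),
            class = "solver_control")
}

relative_gap <- function(upper, lower) {
  if (!is.finite(lower) || !is.finite(upper)) return(Inf)
  if (upper - lower <= 1e-9) return(0)
  if (lower != 0) (upper - lower) / abs(lower) else Inf
}

#' Solve the maximum-likelihood matching problem by Lagrangian relaxation
#'
#' Hybrid subgradient / dual-descent optimization of the Lagrangian dual.
#' Every iteration produces an upper bound (the dual bound) and a lower
#' bound (the likelihood of the feasible master matching, optionally
#' 2-swap-improved); the best of each is kept, so the reported bound
#' sandwich is monotone. Terminates on proven optimality (relative gap at
#' most \code{gap_tol}), the iteration cap, or the time limit.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param table the matching \code{\link{build_score_table}} result.
#' @param control a \code{\link{solver_control}} list.
#' @return A \code{solver_result}: list with \code{matching},
#'   \code{lower_bound}, \code{upper_bound} (log-likelihood scale),
#'   \code{relative_gap}, \code{proved_optimal}, \code{iterations} and a
#'   per-iteration \code{trace} data frame.
#' @export
solve_matching <- function(graph, table, control = solver_control()) {
  if (nrow(graph$edges) == 0L)
    stop_coevomap("empty_graph", "matching graph has no edges: nothing to solve")
  t0 <- proc.time()[["elapsed"]]
  prep <- solver_prep(table)
  m <- nrow(table$quads)
  lambda <- numeric(m)
  best_lower <- -Inf; best_upper <- Inf
  best_matching <- NULL
  mu <- control$mu
  non_improving <- 0L
  trace <- vector("list", control$max_iter)
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    db <- dual_bound_internal(lambda, table, prep)
    cand <- db$x
    ll <- log_likelihood(cand, table)
    if (control$local_search) {
      imp <- improve_matching(cand, ll, table)
      cand <- imp$matching; ll <- imp$ll
    }
    prev_upper <- best_upper
    if (ll > best_lower) { best_lower <- ll; best_matching <- cand }
    if (db$value < best_upper) best_upper <- db$value
    trace[[it]] <- data.frame(iteration = it, lower = ll, upper = db$value,
                              best_lower = best_lower, best_upper = best_upper)
    gap <- relative_gap(best_upper, best_lower)
    if (gap <= control$gap_tol) break
    if (proc.time()[["elapsed"]] - t0 > control$time_limit) break
    if (m == 0L) break
    # subgradient of the dual bound: +1 where the oriented first edge of a
    # unit is selected and chose the unit, -1 for the second edge
    g <- numeric(m)
    for (e in db$x_edge_ids) {
      st <- prep[[e]]; ch <- db$chosen[[e]]
      if (length(ch)) {
        qs <- st$q[ch]
        g[qs] <- g[qs] + st$sgn[ch]
      }
    }
    if (!any(g != 0)) break
    descended <- FALSE
    if (it %% control$dd_every == 0L) {
      # dual-descent trial: shrink the multipliers of violated units toward
      # the value equalizing their two oriented local profits; keep the move
      # only if it strictly improves the dual bound (monotone descent)
      trial <- lambda
      viol <- g != 0
      trial[viol] <- trial[viol] * (1 - control$dd_shrink)
      db_trial <- dual_bound_internal(trial, table, prep)
      if (db_trial$value < db$value - 1e-12) {
        lambda <- trial
        descended <- TRUE
      }
    }
    if (!descended) {
      step <- mu * max(best_upper - best_lower, 0) / sum(g * g)
      lambda <- lambda - step * g
    }
    if (db$value >= prev_upper - 1e-12) {
      non_improving <- non_improving + 1L
      if (non_improving >= control$half_after) {
        mu <- mu / 2
        non_improving <- 0L
      }
    } else non_improving <- 0L
  }
  trace <- do.call(rbind, trace[seq_len(it)])
  gap <- relative_gap(best_upper, best_lower)
  structure(list(matching = best_matching,
                 lower_bound = best_lower,
                 upper_bound = best_upper,
                 relative_gap = gap,
                 proved_optimal = gap <= control$gap_tol,
                 iterations = it,
                 trace = trace,
                 control = control),
            class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  cat(sprintf(paste0("solver_result: matching of size %d\n",
                     "  log likelihood (lower bound): %.6f\n",
                     "  upper bound:                  %.6f\n",
                     "  relative gap: %.3g%s  [%d iterations]\n"),
              nrow(x$matching), x$lower_bound, x$upper_bound,
              x$relative_gap,
              if (x$proved_optimal) " (proven optimal)" else "",
              x$iterations))
  invisible(x)
}
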