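#' Built-in self-test
#'
#' Runs fast end-to-end checks of the scoring and solver machinery: the
#' worked unit-score examples (0.274 and 4.4e-5), hypergeometric
#' normalization, the offset-shift identity between the quadratic objective
#' and the log likelihood on every enumerated maximum matching of a small
#' synthetic instance, and the weak-duality bound sandwich of the Lagrangian
#' solver against exact enumeration.
#'
#' @return List with \code{passed} (logical) and a \code{checks} data frame
#'   (name, ok, detail), invisibly if all pass.
#' @export
selftest <- function() {
  checks <- list()
  add <- function(name, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(name = name, ok = ok,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  }

  s1 <- exp(unit_log_score(list(delta = 11, ell = 12), list(delta = 15, ell = 19)))
  add("unit score example (0.274)", abs(s1 - 0.274) < 5e-4, sprintf("%.6f", s1))
  s2 <- exp(unit_log_score(list(delta = 11, ell = 12), list(delta = 3, ell = 19)))
  add("unit score example (4.4e-5)", abs(s2 - 4.4e-5) < 0.05e-5, sprintf("%.3e", s2))

  norm_ok <- TRUE
  for (lA in c(5L, 20L)) for (lB in c(7L, 30L)) for (Tt in c(0L, 3L, lA, lA + lB)) {
    dA <- max(0L, Tt - lB):min(Tt, lA)
    tot <- sum(exp(hyper_log_pmf(dA, lA, Tt - dA, lB)))
    if (abs(tot - 1) > 1e-9) norm_ok <- FALSE
  }
  add("hypergeometric normalization", norm_ok)

  inst <- generate_families(synth_config(n_species = 2L, paralogs_a = c(2L, 2L),
                                         paralogs_b = c(2L, 2L), seq_length = 60L,
                                         seed = 7L))
  graph <- build_graph(inst$family_a, inst$family_b)
  tab <- build_score_table(inst$family_a, inst$family_b, graph)
  all_m <- enumerate_max_matchings(graph)
  dev <- max(vapply(all_m, function(m)
    abs(bqp2_objective(m, tab) - log_likelihood(m, tab)), numeric(1)))
  add("offset-shift objective identity", dev < 1e-9, sprintf("max dev %.2e", dev))
  if (tab$offset_K <= 0 || any(tab$w <= 0))
    add("score table offset positivity", FALSE)
  else
    add("score table offset positivity", TRUE)

  opt <- max(vapply(all_m, log_likelihood, numeric(1), table = tab))
  res <- solve_matching(graph, tab, solver_control(max_iter = 150L, time_limit = 30))
  add("weak duality sandwich",
      res$lower_bound <= opt + 1e-9 && res$upper_bound >= opt - 1e-9,
      sprintf("lower %.4f opt %.4f upper %.4f", res$lower_bound, opt, res$upper_bound))
  add("best bounds monotone",
      !is.unsorted(res$trace$best_lower) &&
        !is.unsorted(rev(res$trace$best_upper)))

  checks <- do.call(rbind, checks)
  passed <- all(checks$ok)
  out <- list(passed = passed, checks = checks)
  if (!passed) {
    print(checks[!checks$ok, ])
    return(out)
  }
  invisible(out)
}
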