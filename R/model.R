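#' Build the species-constrained matching graph
#'
#' Nodes are the members of the two families; an edge joins every same-species
#' pair, so the graph is a disjoint union of complete bipartite components,
#' one per shared species. All maximal matchings have the same cardinality
#' \eqn{n = \sum_t \min(|A_t|, |B_t|)}; the search space is the set of
#' matchings of that cardinality.
#'
#' @param family_a,family_b the two \code{\link{aligned_family}} objects.
#' @return A \code{matching_graph}: list with \code{ids_a}, \code{ids_b},
#'   \code{species_a}, \code{species_b}, \code{edges} (two-column integer
#'   matrix of node indices, sorted by A index then B index),
#'   \code{species_parts} (per shared species, the A and B node indices),
#'   \code{species_table} and \code{n}.
#' @export
build_graph <- function(family_a, family_b) {
  shared <- intersect(unique(family_a$species), unique(family_b$species))
  if (!length(shared))
    stop_coevomap("empty_graph",
                  sprintf("families '%s' and '%s' share no species: nothing to map",
                          family_a$name, family_b$name))
  hits <- which(outer(family_a$species, family_b$species, "=="), arr.ind = TRUE)
  edges <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "k"))
  parts <- lapply(shared, function(t)
    list(a = which(family_a$species == t), b = which(family_b$species == t)))
  names(parts) <- shared
  all_sp <- union(unique(family_a$species), unique(family_b$species))
  tab <- data.frame(species = all_sp,
                    n_a = as.integer(table(factor(family_a$species, all_sp))),
                    n_b = as.integer(table(factor(family_b$species, all_sp))),
                    stringsAsFactors = FALSE)
  n <- sum(pmin(tab$n_a, tab$n_b))
  structure(list(ids_a = family_a$ids, ids_b = family_b$ids,
                 species_a = family_a$species, species_b = family_b$species,
                 edges = edges, species_parts = parts,
                 species_table = tab, n = n),
            class = "matching_graph")
}

#' @export
print.matching_graph <- function(x, ...) {
  cat(sprintf("matching_graph: %d x %d proteins, %d shared species, %d edges, n = %d\n",
              length(x$ids_a), length(x$ids_b), length(x$species_parts),
              nrow(x$edges), x$n))
  invisible(x)
}

new_matching <- function(m) {
  m <- matrix(as.integer(m), ncol = 2L, dimnames = list(NULL, c("i", "k")))
  m <- m[order(m[, 1L]), , drop = FALSE]
  structure(m, class = c("matching", "matrix"))
}

#' Validate a matching against its graph
#'
#' @param matching a two-column matrix of (A index, B index) pairs.
#' @param graph a \code{\link{build_graph}} result.
#' @return The matching, invisibly; errors if any node is matched twice or
#'   any pair is not a graph edge.
#' @export
validate_matching <- function(matching, graph) {
  if (nrow(matching)) {
    if (anyDuplicated(matching[, 1L]) || anyDuplicated(matching[, 2L]))
      stop_coevomap("validity", "a node is incident to two matching edges")
    key <- (matching[, 1L] - 1) * length(graph$ids_b) + matching[, 2L]
    gkey <- (graph$edges[, 1L] - 1) * length(graph$ids_b) + graph$edges[, 2L]
    if (!all(key %in% gkey))
      stop_coevomap("validity", "matching contains a pair that is not a graph edge")
  }
  invisible(matching)
}

#' Log likelihood of a matching
#'
#' Sums the unit log scores over all unordered pairs of distinct matching
#' edges; 0 for a matching of size 1 (no units, empty product).
#'
#' @param matching a matching over the graph the table was built from.
#' @param table a \code{\link{build_score_table}} result.
#' @return The log likelihood, a non-positive number.
#' @export
log_likelihood <- function(matching, table) {
  if (nrow(matching) < 1L)
    stop_coevomap("domain", "log likelihood requires a non-empty matching")
  e <- edge_ids(matching, table)
  if (length(e) < 2L) return(0)
  pr <- combn(e, 2L)
  q <- table$qindex[cbind(pr[1L, ], pr[2L, ])]
  if (any(q == 0L))
    stop_coevomap("validity", "matching induces an invalid quadruple")
  sum(table$log_f[q])
}

#' Offset-shifted quadratic objective of a maximum-cardinality matching
#'
#' Evaluates the shifted quadratic objective: the sum of (log f + K) over the
#' induced units minus \code{choose(n, 2) * K}. For every maximum-cardinality
#' matching this equals \code{\link{log_likelihood}} exactly, which is what
#' licenses solving the shifted program instead of the raw one.
#'
#' @inheritParams log_likelihood
#' @return The objective value.
#' @export
bqp2_objective <- function(matching, table) {
  if (nrow(matching) != table$n)
    stop_coevomap("domain",
                  sprintf("matching has size %d but maximum cardinality is %d",
                          nrow(matching), table$n))
  e <- edge_ids(matching, table)
  if (length(e) < 2L) return(0)
  pr <- combn(e, 2L)
  q <- table$qindex[cbind(pr[1L, ], pr[2L, ])]
  sum(table$log_f[q] + table$offset_K) - choose(table$n, 2) * table$offset_K
}

# all ordered k-tuples of distinct elements of v (injections of 1..k into v)
injections <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  out <- vector("list", 0L)
  for (idx in seq_along(v)) {
    for (rest in injections(v[-idx], k - 1L))
      out[[length(out) + 1L]] <- c(v[idx], rest)
  }
  out
}

#' Number of maximum-cardinality matchings
#'
#' @param graph a \code{\link{build_graph}} result.
#' @return Product over shared species of the number of injections from the
#'   smaller side into the larger.
#' @export
count_max_matchings <- function(graph) {
  prod(vapply(graph$species_parts, function(p) {
    lo <- min(length(p$a), length(p$b)); hi <- max(length(p$a), length(p$b))
    exp(lfactorial(hi) - lfactorial(hi - lo))
  }, numeric(1)))
}

#' Enumerate all maximum-cardinality matchings
#'
#' Exact search-space oracle for small instances: the cross product, over
#' species components, of all injections from the smaller side into the
#' larger. Refuses instances above \code{cap} matchings.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param cap refuse enumeration beyond this many matchings (default 1e6).
#' @return List of matchings, each of cardinality \code{graph$n}.
#' @export
enumerate_max_matchings <- function(graph, cap = 1e6) {
  total <- count_max_matchings(graph)
  if (total > cap)
    stop_coevomap("too_large",
                  sprintf("%.3g maximum matchings exceed the cap of %.3g; use solve_matching()",
                          total, cap))
  per_species <- lapply(graph$species_parts, function(p) {
    a <- p$a; b <- p$b
    if (length(a) <= length(b)) {
      lapply(injections(b, length(a)), function(bb) cbind(a, bb))
    } else {
      lapply(injections(a, length(b)), function(aa) cbind(aa, b))
    }
  })
  combos <- list(matrix(integer(0), 0L, 2L))
  for (lst in per_species) {
    combos <- unlist(lapply(combos, function(m)
      lapply(lst, function(mt) rbind(m, mt))), recursive = FALSE)
  }
  lapply(combos, new_matching)
}
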