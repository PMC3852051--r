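#' Mismatch and comparable-column counts for a sequence pair
#'
#' Counts, over alignment columns where neither row has a gap, the number of
#' mismatching columns (\code{delta}) and the number of comparable columns,
#' i.e. matches plus mismatches (\code{ell}). Gap columns never count.
#'
#' @param family an \code{\link{aligned_family}}.
#' @param id1,id2 sequence ids within \code{family}.
#' @return A \code{pair_counts} object: list with integers \code{delta},
#'   \code{ell}, \code{0 <= delta <= ell}.
#' @export
pair_counts <- function(family, id1, id2) {
  i <- match(c(id1, id2), family$ids)
  if (anyNA(i))
    stop_coevomap("lookup", sprintf("unknown sequence id(s): %s",
                                    paste(c(id1, id2)[is.na(i)], collapse = ", ")))
  r1 <- strsplit(family$seqs[i[1L]], "", fixed = TRUE)[[1L]]
  r2 <- strsplit(family$seqs[i[2L]], "", fixed = TRUE)[[1L]]
  comp <- r1 != "-" & r2 != "-"
  new_pair_counts(sum(comp & r1 != r2), sum(comp))
}

new_pair_counts <- function(delta, ell) {
  delta <- as.integer(delta); ell <- as.integer(ell)
  if (is.na(delta) || is.na(ell) || delta < 0L || ell < 0L || delta > ell)
    stop_coevomap("domain", "invalid pair counts: need 0 <= delta <= ell")
  structure(list(delta = delta, ell = ell), class = "pair_counts")
}

#' All pairwise mismatch/length counts of a family
#'
#' @param family an \code{\link{aligned_family}}.
#' @return List of two symmetric integer matrices \code{delta} and
#'   \code{ell}, with sequence ids as dimnames.
#' @export
pair_count_matrices <- function(family) {
  chars <- do.call(rbind, strsplit(family$seqs, "", fixed = TRUE))
  gap <- chars == "-"
  n <- nrow(chars)
  delta <- ell <- matrix(0L, n, n, dimnames = list(family$ids, family$ids))
  for (i in seq_len(n)) {
    ngi <- !gap[i, ]
    for (j in seq_len(i)) {
      comp <- ngi & !gap[j, ]
      ell[i, j] <- ell[j, i] <- sum(comp)
      delta[i, j] <- delta[j, i] <- sum(comp & chars[i, ] != chars[j, ])
    }
  }
  list(delta = delta, ell = ell)
}

# log hypergeometric probability of the (dA, dB) mismatch split given
# comparable-column counts lA, lB and total dA + dB; vectorized, log-gamma
# arithmetic via lchoose. Always finite on the support (dA <= lA, dB <= lB).
hyper_log_pmf <- function(dA, lA, dB, lB) {
  lchoose(lA, dA) + lchoose(lB, dB) - lchoose(lA + lB, dA + dB)
}

#' Log score of a unit of coevolution
#'
#' The value of a unit ((a,b),(a',b')) is the hypergeometric probability of
#' observing mismatch counts \code{Delta_A} and \code{Delta_B} given the
#' comparable-column counts and the total number of mismatches, under the
#' hypothesis that both pairs diverged at equal rates:
#' \deqn{f = \frac{\binom{\ell_A}{\Delta_A}\binom{\ell_B}{\Delta_B}}
#'               {\binom{\ell_A+\ell_B}{\Delta_A+\Delta_B}}.}
#' Returned in log space; always finite and \eqn{\le 0}, and symmetric in
#' its two arguments.
#'
#' @param counts_a,counts_b \code{pair_counts} for the family-A and family-B
#'   sequence pair (or bare lists with \code{delta} and \code{ell}).
#' @return log f, a finite non-positive number.
#' @export
unit_log_score <- function(counts_a, counts_b) {
  ca <- new_pair_counts(counts_a$delta, counts_a$ell)
  cb <- new_pair_counts(counts_b$delta, counts_b$ell)
  hyper_log_pmf(ca$delta, ca$ell, cb$delta, cb$ell)
}

#' Build the unit-of-coevolution score table for a matching graph
#'
#' Scores every quadruple of two disjoint graph edges (i,k), (j,l) with
#' i < j (family-A order) and k != l, including quadruples spanning two
#' species. Also derives the positive offset K = -min(log f) +
#' \code{offset_margin} and the shifted half-weights w = (log f + K)/2 used
#' by the Lagrangian solver; the offset does not change which matching is
#' optimal.
#'
#' @param family_a,family_b the two \code{\link{aligned_family}} objects.
#' @param graph the \code{\link{build_graph}} result for the two families.
#' @param offset_margin positive margin added beyond strict positivity
#'   (default 1).
#' @return A \code{unit_score_table}: list with \code{edges}, \code{quads}
#'   (two-column matrix of edge indices, first edge has the smaller A index),
#'   \code{log_f}, \code{offset_K}, \code{w}, plus lookup structures.
#' @export
build_score_table <- function(family_a, family_b, graph, offset_margin = 1) {
  stopifnot(offset_margin > 0)
  if (!identical(graph$ids_a, family_a$ids) || !identical(graph$ids_b, family_b$ids))
    stop_coevomap("domain", "graph was not built from these families")
  cm_a <- pair_count_matrices(family_a)
  cm_b <- pair_count_matrices(family_b)
  edges <- graph$edges
  E <- nrow(edges)
  qindex <- matrix(0L, E, E)
  if (E >= 2L) {
    pr <- which(upper.tri(qindex), arr.ind = TRUE)   # e1 < e2 in edge order
    i1 <- edges[pr[, 1L], 1L]; k1 <- edges[pr[, 1L], 2L]
    i2 <- edges[pr[, 2L], 1L]; k2 <- edges[pr[, 2L], 2L]
    keep <- i1 < i2 & k1 != k2          # edges sorted by A index: i1 <= i2
    pr <- pr[keep, , drop = FALSE]
    log_f <- hyper_log_pmf(cm_a$delta[cbind(i1, i2)][keep],
                           cm_a$ell[cbind(i1, i2)][keep],
                           cm_b$delta[cbind(k1, k2)][keep],
                           cm_b$ell[cbind(k1, k2)][keep])
  } else {
    pr <- matrix(integer(0), 0L, 2L)
    log_f <- numeric(0)
  }
  if (nrow(pr)) {
    qindex[pr] <- seq_len(nrow(pr))
    qindex[pr[, c(2L, 1L), drop = FALSE]] <- seq_len(nrow(pr))
  }
  offset_K <- if (length(log_f)) -min(log_f) + offset_margin else offset_margin
  structure(list(edges = edges,
                 quads = pr,
                 log_f = log_f,
                 offset_K = offset_K,
                 w = (log_f + offset_K) / 2,
                 qindex = qindex,
                 n = graph$n,
                 n_b = length(graph$ids_b),
                 edge_key = (edges[, 1L] - 1) * length(graph$ids_b) + edges[, 2L],
                 species_parts = graph$species_parts),
            class = "unit_score_table")
}

# edge indices of a matching's edges within a score table; errors if any
# matched pair is not a graph edge
edge_ids <- function(matching, table) {
  key <- (matching[, 1L] - 1) * table$n_b + matching[, 2L]
  e <- match(key, table$edge_key)
  if (anyNA(e))
    stop_coevomap("validity", "matching contains a pair that is not a graph edge")
  sort(e)
}

#' Coevolution degree of one mapped pair within a matching
#'
#' The mean of log f over the n - 1 units of coevolution that contain the
#' pair: the log of the geometric-mean unit value C(a,b; theta), a per-pair
#' measure of coevolution.
#'
#' @param pair integer vector \code{c(i, k)} of graph node indices, or a
#'   one-row matching; must be an edge of \code{matching}.
#' @param matching a matching with at least 2 edges containing \code{pair}.
#' @param table a \code{\link{build_score_table}} result.
#' @return The mean unit log score, a non-positive number.
#' @export
coevolution_degree <- function(pair, matching, table) {
  pair <- as.integer(pair)
  s <- nrow(matching)
  if (s < 2L)
    stop_coevomap("domain", "coevolution degree is undefined for matchings of size < 2")
  row <- which(matching[, 1L] == pair[1L] & matching[, 2L] == pair[2L])
  if (!length(row))
    stop_coevomap("lookup", "pair is not part of the matching")
  e <- edge_ids(matching, table)
  e_pair <- edge_ids(matching[row, , drop = FALSE], table)
  q <- table$qindex[cbind(e_pair, setdiff(e, e_pair))]
  mean(table$log_f[q])
}
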