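#' Recall and precision of a predicted matching
#'
#' Recall is the percentage of correctly predicted pairings relative to the
#' reference cardinality; precision is the number of correct pairings
#' divided by the predicted cardinality (in percent).
#'
#' @param predicted,reference matchings over the same graph.
#' @return An \code{eval_report}: list with \code{recall}, \code{precision}
#'   (percentages), \code{correct}, \code{predicted_size},
#'   \code{reference_size}.
#' @export
recall_precision <- function(predicted, reference) {
  if (nrow(reference) == 0L)
    stop_coevomap("domain", "recall is undefined for an empty reference matching")
  if (nrow(predicted) == 0L)
    stop_coevomap("domain", "precision is undefined for an empty predicted matching")
  pk <- paste(predicted[, 1L], predicted[, 2L])
  rk <- paste(reference[, 1L], reference[, 2L])
  correct <- length(intersect(pk, rk))
  structure(list(recall = 100 * correct / nrow(reference),
                 precision = 100 * correct / nrow(predicted),
                 correct = correct,
                 predicted_size = nrow(predicted),
                 reference_size = nrow(reference)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: recall %.1f%%, precision %.1f%% (%d/%d reference, %d predicted)\n",
              x$recall, x$precision, x$correct, x$reference_size,
              x$predicted_size))
  invisible(x)
}

#' Average log likelihood per unit of coevolution
#'
#' Normalizes the log likelihood of a matching by its number of units,
#' \code{choose(size, 2)}, making matchings of different cardinality
#' comparable.
#'
#' @param matching a matching of size at least 2.
#' @param table a \code{\link{build_score_table}} result.
#' @return The mean unit log score.
#' @export
avg_unit_loglik <- function(matching, table) {
  s <- nrow(matching)
  if (s < 2L)
    stop_coevomap("domain",
                  "average unit log likelihood is undefined for matchings of size < 2")
  log_likelihood(matching, table) / choose(s, 2)
}
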