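# synthetic paired families with planted coevolution

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic coevolving-family generator
#'
#' The generator realizes the model the scoring assumes: mismatches between
#' two sequences arise from independent Bernoulli substitution trials, and
#' coevolving partners share their substitution rate exactly. Each family
#' descends from its own random ancestor by a star phylogeny; sequence v
#' substitutes each column independently with its own rate q_v, and the
#' planted partner of v in the other family is given the same q_v, so every
#' planted unit satisfies the equal-rates hypothesis.
#'
#' @param n_species number of species (default 4).
#' @param paralogs_a,paralogs_b \code{c(min, max)} paralogs per species and
#'   family (default \code{c(3, 3)}).
#' @param seq_length ungapped alignment width (default 200 columns).
#' @param shared_rate_range interval from which per-sequence substitution
#'   rates are drawn (default \code{c(0.05, 0.75)}).
#' @param decoy_rate_jitter minimum rate separation enforced between the
#'   paralogs of one species (default 0.3); 0 draws rates independently, so
#'   decoy pairings can be nearly indistinguishable from planted ones.
#' @param indel_rate per-sequence, per-column gap probability (default 0.02).
#' @param seed RNG seed; generation is byte-identical given the config.
#' @return List of class \code{synth_config}.
#' @export
synth_config <- function(n_species = 4L, paralogs_a = c(3L, 3L),
                         paralogs_b = c(3L, 3L), seq_length = 200L,
                         shared_rate_range = c(0.05, 0.75),
                         decoy_rate_jitter = 0.3, indel_rate = 0.02,
                         seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              paralogs_a = as.integer(rep(paralogs_a, length.out = 2L)),
              paralogs_b = as.integer(rep(paralogs_b, length.out = 2L)),
              seq_length = as.integer(seq_length),
              shared_rate_range = as.numeric(shared_rate_range),
              decoy_rate_jitter = as.numeric(decoy_rate_jitter),
              indel_rate = as.numeric(indel_rate),
              seed = as.integer(seed))
  if (cfg$n_species < 1L || cfg$seq_length < 1L ||
      any(cfg$paralogs_a < 1L) || any(cfg$paralogs_b < 1L) ||
      any(cfg$shared_rate_range < 0) || any(cfg$shared_rate_range > 1) ||
      cfg$indel_rate < 0 || cfg$indel_rate > 1 || cfg$decoy_rate_jitter < 0)
    stop_coevomap("config", "invalid synthetic generator configuration")
  structure(cfg, class = "synth_config")
}

# star-phylogeny sequence: mutate ancestor columns i.i.d. with rate q,
# always to one of the 19 other residues
mutate_sequence <- function(anc_idx, q) {
  L <- length(anc_idx)
  mut <- runif(L) < q
  idx <- anc_idx
  nm <- sum(mut)
  if (nm) {
    off <- sample.int(19L, nm, replace = TRUE)
    idx[mut] <- ((anc_idx[mut] - 1L + off) %% 20L) + 1L
  }
  idx
}

#' Generate a pair of synthetic coevolving families with planted truth
#'
#' For each species, paralog "slots" get substitution rates from
#' \code{shared_rate_range}; when \code{decoy_rate_jitter > 0}, consecutive
#' slot rates are separated by at least the jitter, making paralogs
#' distinguishable. The planted pair of slot p in families A and B shares
#' its rate exactly (the equal-rates hypothesis); all other pairings mix
#' different rates. Gap columns are inserted per sequence i.i.d. at
#' \code{indel_rate}; family-B sequence order is shuffled so the truth is
#' not positional.
#'
#' @param config a \code{\link{synth_config}}.
#' @return List with \code{family_a}, \code{family_b}
#'   (\code{\link{aligned_family}}), \code{truth} (data frame of planted
#'   \code{id_a}, \code{id_b}, \code{species}) and \code{config}.
#' @export
generate_families <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(config$seed)
  L <- config$seq_length
  rmin <- config$shared_rate_range[1L]; rmax <- config$shared_rate_range[2L]
  jit <- config$decoy_rate_jitter
  anc_a <- sample.int(20L, L, replace = TRUE)
  anc_b <- sample.int(20L, L, replace = TRUE)
  ids_a <- ids_b <- sp_a <- sp_b <- character(0)
  seq_a <- seq_b <- character(0)
  truth <- list()
  for (t in seq_len(config$n_species)) {
    sp <- sprintf("SP%02d", t)
    na_t <- config$paralogs_a[1L] +
      sample.int(config$paralogs_a[2L] - config$paralogs_a[1L] + 1L, 1L) - 1L
    nb_t <- config$paralogs_b[1L] +
      sample.int(config$paralogs_b[2L] - config$paralogs_b[1L] + 1L, 1L) - 1L
    P <- max(na_t, nb_t)
    if (jit > 0) {
      span <- (P - 1L) * jit
      lo <- runif(1L, rmin, max(rmin, rmax - span))
      q <- pmin(lo + (seq_len(P) - 1L) * jit, rmax)
    } else {
      q <- runif(P, rmin, rmax)
    }
    for (p in seq_len(P)) {
      if (p <= na_t) {
        id <- sprintf("a%02dp%02d_%s", t, p, sp)
        row <- AA_ALPHABET[mutate_sequence(anc_a, q[p])]
        row[runif(L) < config$indel_rate] <- "-"
        ids_a <- c(ids_a, id); sp_a <- c(sp_a, sp)
        seq_a <- c(seq_a, paste(row, collapse = ""))
      }
      if (p <= nb_t) {
        id <- sprintf("b%02dp%02d_%s", t, p, sp)
        row <- AA_ALPHABET[mutate_sequence(anc_b, q[p])]
        row[runif(L) < config$indel_rate] <- "-"
        ids_b <- c(ids_b, id); sp_b <- c(sp_b, sp)
        seq_b <- c(seq_b, paste(row, collapse = ""))
      }
      if (p <= min(na_t, nb_t)) {
        truth[[length(truth) + 1L]] <-
          data.frame(id_a = sprintf("a%02dp%02d_%s", t, p, sp),
                     id_b = sprintf("b%02dp%02d_%s", t, p, sp),
                     species = sp, stringsAsFactors = FALSE)
      }
    }
  }
  perm <- sample.int(length(ids_b))
  list(family_a = aligned_family("synthA", ids_a, seq_a, sp_a),
       family_b = aligned_family("synthB", ids_b[perm], seq_b[perm], sp_b[perm]),
       truth = do.call(rbind, truth),
       config = config)
}

#' Planted truth as a matching over the instance's graph
#'
#' @param instance a \code{\link{generate_families}} result.
#' @param graph optional pre-built graph of the instance's families.
#' @return The planted matching.
#' @export
truth_matching <- function(instance, graph = build_graph(instance$family_a,
                                                         instance$family_b)) {
  matching_from_ids(graph, instance$truth$id_a, instance$truth$id_b)
}
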