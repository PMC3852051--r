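#' Construct an aligned protein family
#'
#' An \code{aligned_family} bundles a multiple sequence alignment with a
#' species label for every sequence. Rows must all have the same width;
#' residues are uppercased and \code{'.'} gaps are normalized to \code{'-'}.
#'
#' @param name family identifier.
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned rows (same length as \code{ids}).
#' @param species character vector of species labels, either parallel to
#'   \code{ids} or named by sequence id.
#' @return An object of class \code{aligned_family} with elements
#'   \code{name}, \code{ids}, \code{seqs}, \code{species}.
#' @export
aligned_family <- function(name, ids, seqs, species) {
  ids <- as.character(ids)
  seqs <- chartr(".", "-", toupper(as.character(seqs)))
  if (length(ids) != length(seqs))
    stop_coevomap("format", "ids and seqs must have the same length")
  if (length(ids) == 0L)
    stop_coevomap("format", sprintf("family '%s' has no sequences", name))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_coevomap("duplicate_id",
                  sprintf("duplicate sequence id(s) in family '%s': %s",
                          name, paste(dup, collapse = ", ")))
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    ref <- as.integer(names(which.max(table(w))))
    bad <- ids[w != ref][1L]
    stop_coevomap("ragged_alignment",
                  sprintf("alignment '%s' is ragged: sequence '%s' has width %d, expected %d",
                          name, bad, w[ids == bad][1L], ref))
  }
  if (!is.null(names(species))) {
    missing <- setdiff(ids, names(species))
    if (length(missing))
      stop_coevomap("missing_species",
                    sprintf("no species label for sequence(s): %s",
                            paste(missing, collapse = ", ")))
    species <- unname(species[ids])
  } else {
    if (length(species) != length(ids))
      stop_coevomap("missing_species",
                    "unnamed species vector must be parallel to ids")
  }
  species <- as.character(species)
  if (anyNA(species) || any(!nzchar(species)))
    stop_coevomap("missing_species",
                  sprintf("empty species label for sequence(s): %s",
                          paste(ids[is.na(species) | !nzchar(species)], collapse = ", ")))
  structure(list(name = name, ids = ids, seqs = seqs, species = species),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("aligned_family '%s': %d sequences, width %d, %d species\n",
              x$name, length(x$ids), nchar(x$seqs[1L]),
              length(unique(x$species))))
  invisible(x)
}

#' Read an aligned family from FASTA with species labels
#'
#' Reads an aligned FASTA file and attaches a species label to every
#' sequence. Labels come either from a two-column tab-separated file
#' (sequence id, species; no header) or, when no mapping is supplied, from a
#' SwissProt-style header suffix \code{NAME_SPECIES}. An explicit mapping
#' wins over header parsing.
#'
#' @param alignment path to an aligned FASTA file.
#' @param species optional: path to a two-column TSV mapping file, or a
#'   character vector of species labels named by sequence id.
#' @param name family identifier; defaults to the file name.
#' @return An \code{\link{aligned_family}}.
#' @export
read_family <- function(alignment, species = NULL, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(alignment))
  set <- tryCatch(Biostrings::readBStringSet(alignment),
                  error = function(e) stop_coevomap("format",
                    sprintf("cannot read FASTA '%s': %s", alignment, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (is.null(species)) {
    has_suffix <- grepl("_[^_]+$", ids)
    if (!all(has_suffix))
      stop_coevomap("missing_species",
                    sprintf("cannot parse species from header(s): %s",
                            paste(ids[!has_suffix], collapse = ", ")))
    sp <- sub("^.*_", "", ids)
  } else if (is.character(species) && length(species) == 1L && file.exists(species)) {
    map <- read.delim(species, header = FALSE, sep = "\t",
                      colClasses = "character")
    if (ncol(map) < 2L)
      stop_coevomap("format", sprintf("species map '%s' is not two-column TSV", species))
    sp <- stats::setNames(map[[2L]], map[[1L]])
  } else {
    sp <- species
  }
  aligned_family(name, ids, seqs, sp)
}

#' Write an aligned family to FASTA (plus optional species TSV)
#'
#' @param family an \code{\link{aligned_family}}.
#' @param path output FASTA path.
#' @param species_path optional path for a two-column species TSV.
#' @return \code{path}, invisibly.
#' @export
write_family <- function(family, path, species_path = NULL) {
  set <- Biostrings::BStringSet(stats::setNames(family$seqs, family$ids))
  Biostrings::writeXStringSet(set, path)
  if (!is.null(species_path)) {
    write.table(data.frame(id = family$ids, species = family$species),
                species_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a matching as TSV
#'
#' Emits columns \code{family_A_id}, \code{family_B_id}, \code{species},
#' sorted by species then by family-A id, so output is deterministic.
#'
#' @param matching a matching (two-column integer matrix of graph node
#'   indices, as returned by the solver or enumerator).
#' @param graph the \code{\link{build_graph}} result the matching refers to.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_matching <- function(matching, graph, path) {
  validate_matching(matching, graph)
  df <- as.data.frame(matching, graph)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_coevomap("io",
                    sprintf("cannot write '%s': %s", path, conditionMessage(e))))
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.matching <- function(x, graph, ...) {
  df <- data.frame(family_A_id = graph$ids_a[x[, 1L]],
                   family_B_id = graph$ids_b[x[, 2L]],
                   species = graph$species_a[x[, 1L]],
                   stringsAsFactors = FALSE)
  df[order(df$species, df$family_A_id), , drop = FALSE]
}

#' Read a matching TSV written by \code{write_matching}
#'
#' @inheritParams write_matching
#' @param path path to the matching TSV.
#' @return A matching (class \code{matching}).
#' @export
read_matching <- function(path, graph) {
  df <- read.delim(path, sep = "\t", colClasses = "character")
  if (!all(c("family_A_id", "family_B_id") %in% names(df)))
    stop_coevomap("format", sprintf("'%s' lacks family_A_id/family_B_id columns", path))
  matching_from_ids(graph, df$family_A_id, df$family_B_id)
}

#' Build a matching from sequence id pairs
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param ids_a,ids_b parallel character vectors of paired sequence ids.
#' @return A matching.
#' @export
matching_from_ids <- function(graph, ids_a, ids_b) {
  i <- match(ids_a, graph$ids_a)
  k <- match(ids_b, graph$ids_b)
  if (anyNA(i) || anyNA(k))
    stop_coevomap("lookup",
                  sprintf("unknown sequence id(s): %s",
                          paste(c(ids_a[is.na(i)], ids_b[is.na(k)]), collapse = ", ")))
  m <- new_matching(cbind(i, k))
  validate_matching(m, graph)
  m
}

#' Write a JSON run report
#'
#' @param result a \code{\link{solve_matching}} result.
#' @param path output path.
#' @param seed,config optional provenance echoed into the report.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(result, path, seed = NULL, config = NULL) {
  rep <- list(lower_bound = result$lower_bound,
              upper_bound = result$upper_bound,
              relative_gap = result$relative_gap,
              proved_optimal = result$proved_optimal,
              iterations = result$iterations,
              trace = result$trace,
              seed = seed, config = config)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
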