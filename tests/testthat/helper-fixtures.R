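# fixtures are built in code; nothing is stored on disk

# two-species toy pair of families with hand-checkable counts:
# family A pair (a1, a2): 11 mismatches over 12 comparable columns,
# two further columns gapped in one of the rows.
fig_rows_a <- function() c(
  a1 = paste0(strrep("A", 11), "C", "-", "D"),
  a2 = paste0(strrep("C", 11), "C", "E", "-")
)

# family B triple: (b1, b2) has 15 mismatches over 19 comparable columns,
# (b1, b3) has 3 mismatches over the same 19.
fig_rows_b <- function() c(
  b1 = paste0(strrep("A", 15), strrep("G", 4)),
  b2 = paste0(strrep("C", 15), strrep("G", 4)),
  b3 = paste0(strrep("C", 3), strrep("A", 12), strrep("G", 4))
)

toy_families <- function() {
  ra <- fig_rows_a(); rb <- fig_rows_b()
  list(
    a = aligned_family("toyA", names(ra), unname(ra), c("YEAST", "HUMAN")),
    b = aligned_family("toyB", names(rb), unname(rb), c("YEAST", "HUMAN", "HUMAN"))
  )
}

# a small random instance wrapper used by oracle tests
random_instance <- function(seed, n_species = 2L + (seed %% 3L),
                            paralogs = c(1L, 4L), seq_length = 40L,
                            jitter = 0, indel = 0.05) {
  inst <- generate_families(synth_config(
    n_species = n_species, paralogs_a = paralogs, paralogs_b = paralogs,
    seq_length = seq_length, decoy_rate_jitter = jitter,
    indel_rate = indel, seed = seed))
  g <- build_graph(inst$family_a, inst$family_b)
  tab <- build_score_table(inst$family_a, inst$family_b, g)
  list(inst = inst, graph = g, table = tab)
}

# exact optimum by full enumeration
oracle_optimum <- function(graph, table) {
  max(vapply(enumerate_max_matchings(graph), log_likelihood, numeric(1),
             table = table))
}
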