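# Shared fixture builders (everything is generated in code at test time).

write_tmp_obo <- function(lines) {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), f)
  f
}

mini_obo_path <- function() {
  system.file("extdata", "mini_go.obo", package = "gofusion")
}

# hand-built 2-term BP ontology
two_term_obo <- function() {
  write_tmp_obo(c(
    "[Term]", "id: GO:0000010", "name: a", "namespace: biological_process",
    'def: "a" []', "",
    "[Term]", "id: GO:0000011", "name: b", "namespace: biological_process",
    'def: "b" []', "is_a: GO:0000010", ""
  ))
}

# small single-aspect graph from explicit edges (child -> parent)
toy_graph <- function(ids, edges_df, aspect = "BP") {
  go_graph(
    tibble::tibble(id = ids, name = ids, definition = ids,
                   aspect = aspect, obsolete = FALSE),
    edges_df
  )
}

toy_edges <- function(child, parent, relation = "is_a") {
  tibble::tibble(child = child, parent = parent,
                 relation = rep_len(relation, length(child)))
}

# minimal in-memory cohort around explicit embedding entries
toy_cohort <- function(seq_entries, annotations, graph,
                       text_entries = list(), taxonomy = NULL) {
  ids <- names(seq_entries)
  if (is.null(taxonomy)) taxonomy <- setNames(rep(1L, length(ids)), ids)
  d <- nrow(seq_entries[[1]])
  dp <- if (length(text_entries)) nrow(text_entries[[1]]) else 0L
  cohort(
    protein_ids = ids,
    seq_archive = list(entries = seq_entries, dim = d, metadata = list()),
    text_archive = list(entries = text_entries, dim = dp,
                        metadata = list()),
    taxonomy = taxonomy,
    annotations = annotations,
    ontology = list(terms = graph$terms, edges = graph$edges)
  )
}

# default small simulated cohort reused across tests (cheap: one aspect)
small_sim <- function(n = 80, gamma = 10, d = 16, d_prime = 12, seed = 7,
                      ...) {
  generate_cohort(sim_config(n_proteins = n, gamma_per_aspect = gamma,
                             d = d, d_prime = d_prime, aspects = "BP",
                             seed = seed, ...))
}
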