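#' Simulation configuration
#'
#' Defaults describe the desk-scale reference cohort used throughout the
#' test-suite: 500 proteins, 30 terms per aspect, planted linear signal of
#' strength 5 against unit Gaussian noise, term texts tied to the same
#' mixing matrix and a species effect on a fifth of the terms.
#'
#' @param n_proteins Number of proteins.
#' @param gamma_per_aspect Terms per aspect DAG.
#' @param d,d_prime Sequence / text embedding widths.
#' @param len_range Inclusive residue-length range (uniform).
#' @param text_len_range Inclusive text token-length range (uniform).
#' @param signal_strength Scale of the label-driven mean shift of the
#'   sequence embedding.
#' @param noise_sd Gaussian noise sd on every embedding position.
#' @param text_relevance In `[0, 1]`; how strongly a term's text embedding
#'   follows its own mixing-matrix column.
#' @param taxonomy_effect Fraction of leaf terms whose prevalence depends
#'   on the species.
#' @param n_species Number of species (code 0 stays reserved for unknown).
#' @param aspects Which aspect DAGs to generate.
#' @param seed Master seed; the cohort is a pure function of the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 500, gamma_per_aspect = 30, d = 64,
                       d_prime = 48, len_range = c(20, 60),
                       text_len_range = c(5, 15), signal_strength = 5,
                       noise_sd = 1, text_relevance = 0.8,
                       taxonomy_effect = 0.2, n_species = 6,
                       aspects = c("BP", "MF", "CC"), seed = 0) {
  stopifnot(n_proteins >= 1, gamma_per_aspect >= 1, d >= 1, d_prime >= 1,
            noise_sd > 0, text_relevance >= 0, text_relevance <= 1,
            taxonomy_effect >= 0, taxonomy_effect <= 1, n_species >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a random rooted GO-like DAG
#'
#' Term 1 is the root; every later term draws 1-2 parents from earlier
#' terms, so the graph is acyclic by construction. Ids are zero-padded so
#' construction order coincides with the lexicographic label-space order.
#'
#' @param gamma Number of terms.
#' @param seed Seed.
#' @param aspect Aspect tag attached to every term (also sets the id block:
#'   BP ids start at GO:1000001, MF at GO:2000001, CC at GO:3000001).
#' @return A [go_graph()].
#' @export
generate_dag <- function(gamma, seed = 0, aspect = "BP") {
  stopifnot(gamma >= 1)
  offset <- switch(aspect, BP = 1e6, MF = 2e6, CC = 3e6)
  ids <- sprintf("GO:%07d", offset + seq_len(gamma))
  withr::with_seed(seed, {
    edges <- list()
    for (i in seq_len(gamma)[-1]) {
      k <- sample(1:2, 1)
      parents <- sample(i - 1L, min(k, i - 1L))
      rel <- sample(c("is_a", "part_of"), length(parents), replace = TRUE,
                    prob = c(0.8, 0.2))
      edges[[i]] <- tibble::tibble(child = ids[i], parent = ids[parents],
                                   relation = rel)
    }
    terms <- tibble::tibble(
      id = ids,
      name = paste("synthetic term", ids),
      definition = paste("Synthetic description of process", seq_len(gamma),
                         "in aspect", aspect),
      aspect = aspect,
      obsolete = FALSE
    )
    go_graph(terms, dplyr::bind_rows(edges))
  })
}

#' Generate a synthetic cohort with planted signal
#'
#' Emulates the structure a frozen protein language model and text encoder
#' would produce: per-residue sequence embeddings whose per-protein mean is
#' a linear image `signal_strength * G y` of the true (propagated) label
#' vector plus isotropic noise; per-term text embeddings tilted toward the
#' same mixing column through a fixed down-projection; and species codes
#' that modulate a subset of leaf terms. All randomness derives from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [cohort()] with extra fields `graphs` (per-aspect
#'   [go_graph()]s), `labels` (per-aspect binary matrices) and a
#'   `sim_truth` attribute holding the mixing matrix.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  graphs <- lapply(seq_along(cf$aspects), function(a) {
    generate_dag(cf$gamma_per_aspect, seed = cf$seed + a, aspect = cf$aspects[a])
  })
  names(graphs) <- cf$aspects

  all_terms <- unlist(lapply(graphs, function(g) g$terms$id), use.names = FALSE)
  gamma_total <- length(all_terms)

  withr::with_seed(cf$seed, {
    G <- matrix(rnorm(cf$d * gamma_total, sd = 1 / sqrt(cf$d)),
                cf$d, gamma_total, dimnames = list(NULL, all_terms))
    Q <- matrix(rnorm(cf$d_prime * cf$d, sd = 1 / sqrt(cf$d)),
                cf$d_prime, cf$d)

    # per-aspect leaf sets and species-modulated terms
    leaves <- lapply(graphs, function(g) {
      setdiff(g$terms$id, unique(g$edges$parent))
    })
    anc <- lapply(graphs, graph_ancestors)
    modulated <- lapply(leaves, function(lv) {
      m <- round(cf$taxonomy_effect * length(lv))
      if (m == 0L) return(setNames(integer(), character()))
      picked <- sample(lv, m)
      setNames(sample.int(cf$n_species, m, replace = TRUE), picked)
    })

    ids <- sprintf("P%05d", seq_len(cf$n_proteins))
    species <- sample.int(cf$n_species, cf$n_proteins, replace = TRUE)

    labels <- lapply(graphs, function(g) {
      matrix(0L, cf$n_proteins, nrow(g$terms),
             dimnames = list(ids, g$terms$id))
    })
    for (i in seq_len(cf$n_proteins)) {
      for (a in cf$aspects) {
        lv <- leaves[[a]]
        w <- rep(1, length(lv))
        mod <- modulated[[a]]
        hit <- names(mod)[mod == species[i]]
        w[lv %in% hit] <- 4
        k <- min(length(lv), 1L + rpois(1, 1))
        pos <- sample(lv, k, prob = w)
        pos <- unique(c(pos, unlist(anc[[a]][pos], use.names = FALSE)))
        labels[[a]][i, pos] <- 1L
      }
    }

    y_all <- do.call(cbind, lapply(cf$aspects, function(a) labels[[a]]))
    y_all <- y_all[, all_terms, drop = FALSE]

    lens <- sample(seq(cf$len_range[1], cf$len_range[2]),
                   cf$n_proteins, replace = TRUE)
    seq_entries <- vector("list", cf$n_proteins)
    names(seq_entries) <- ids
    for (i in seq_len(cf$n_proteins)) {
      mu <- cf$signal_strength * as.vector(G %*% y_all[i, ])
      seq_entries[[i]] <- mu + matrix(rnorm(cf$d * lens[i], sd = cf$noise_sd),
                                      cf$d, lens[i])
    }

    tlens <- sample(seq(cf$text_len_range[1], cf$text_len_range[2]),
                    gamma_total, replace = TRUE)
    text_entries <- vector("list", gamma_total)
    names(text_entries) <- all_terms
    for (j in seq_len(gamma_total)) {
      base <- cf$text_relevance * as.vector(Q %*% G[, j])
      text_entries[[j]] <- base +
        matrix(rnorm(cf$d_prime * tlens[j], sd = cf$noise_sd),
               cf$d_prime, tlens[j])
    }

    annotations <- dplyr::bind_rows(lapply(cf$aspects, function(a) {
      idx <- which(labels[[a]] == 1L, arr.ind = TRUE)
      tibble::tibble(
        protein_id = rownames(labels[[a]])[idx[, 1]],
        go_id = colnames(labels[[a]])[idx[, 2]],
        aspect = a
      )
    }))
    annotations <- dplyr::arrange(annotations, .data$protein_id, .data$go_id)

    onto_terms <- dplyr::bind_rows(lapply(graphs, function(g) g$terms))
    onto_edges <- dplyr::bind_rows(lapply(graphs, function(g) g$edges))

    ch <- cohort(
      protein_ids = ids,
      seq_archive = list(entries = seq_entries, dim = cf$d,
                         metadata = list(source = "gofusion-sim",
                                         seed = cf$seed)),
      text_archive = list(entries = text_entries, dim = cf$d_prime,
                          metadata = list(source = "gofusion-sim",
                                          seed = cf$seed)),
      taxonomy = setNames(as.integer(species), ids),
      annotations = annotations,
      ontology = list(terms = onto_terms, edges = onto_edges)
    )
    ch$graphs <- graphs
    ch$labels <- labels
    ch$config <- cf
    attr(ch, "sim_truth") <- list(G = G, Q = Q, modulated = modulated)
    ch
  })
}

#' Write a cohort to disk
#'
#' Emits the on-disk form every pipeline stage consumes: an OBO ontology
#' file, annotation and taxonomy TSVs and the two embedding archives.
#'
#' @param ch A [cohort()] (typically from [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(ch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(ch$ontology$terms, ch$ontology$edges,
            file.path(dir, "ontology.obo"))
  write.table(ch$annotations, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(protein_id = names(ch$taxonomy),
               species_id = unname(ch$taxonomy)),
    file.path(dir, "taxonomy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_archive(ch$seq_archive$entries, file.path(dir, "seq_embeddings.bin"),
                metadata = ch$seq_archive$metadata)
  write_archive(ch$text_archive$entries,
                file.path(dir, "text_embeddings.bin"),
                metadata = ch$text_archive$metadata)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `ontology.obo`, `annotations.tsv`,
#'   `taxonomy.tsv` and the two embedding archives.
#' @return A [cohort()].
#' @export
read_cohort <- function(dir) {
  onto <- read_obo(file.path(dir, "ontology.obo"))
  seq_arc <- read_archive(file.path(dir, "seq_embeddings.bin"))
  text_arc <- read_archive(file.path(dir, "text_embeddings.bin"))
  cohort(
    protein_ids = names(seq_arc$entries),
    seq_archive = seq_arc,
    text_archive = text_arc,
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
    annotations = read_annotations(file.path(dir, "annotations.tsv")),
    ontology = onto
  )
}

write_obo <- function(terms, edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  ns <- c(BP = "biological_process", MF = "molecular_function",
          CC = "cellular_component")
  by_child <- split(seq_len(nrow(edges)), edges$child)
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", terms$name[i]),
             paste0("namespace: ", ns[[terms$aspect[i]]]),
             paste0("def: \"", terms$definition[i], "\" []"))
    for (j in by_child[[id]]) {
      out <- c(out, if (edges$relation[j] == "is_a") {
        paste0("is_a: ", edges$parent[j])
      } else {
        paste0("relationship: part_of ", edges$parent[j])
      })
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
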