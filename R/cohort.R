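#' Read a protein -> species taxonomy table
#'
#' @param path TSV file with header `protein_id<TAB>species_id`.
#' @return Named integer vector mapping protein id to species code; unknown
#'   or empty species map to the reserved code `0`.
#' @export
read_taxonomy <- function(path) {
  tab <- tibble::as_tibble(read.delim(path, sep = "\t",
                                      colClasses = "character"))
  if (!all(c("protein_id", "species_id") %in% names(tab))) {
    abort("taxonomy table needs columns protein_id and species_id",
          class = "gofusion_io_error")
  }
  sp <- suppressWarnings(as.integer(tab$species_id))
  sp[is.na(sp)] <- 0L
  dup <- tab$protein_id[duplicated(tab$protein_id)]
  for (id in unique(dup)) {
    if (length(unique(sp[tab$protein_id == id])) > 1L) {
      abort(paste0("conflicting species for protein ", id),
            class = "gofusion_io_error")
    }
  }
  keep <- !duplicated(tab$protein_id)
  setNames(sp[keep], tab$protein_id[keep])
}

#' Read a protein -> GO annotation table
#'
#' @param path TSV file with header `protein_id<TAB>go_id<TAB>aspect`.
#' @return Tibble with those three columns.
#' @export
read_annotations <- function(path) {
  tab <- tibble::as_tibble(read.delim(path, sep = "\t",
                                      colClasses = "character"))
  need <- c("protein_id", "go_id", "aspect")
  if (!all(need %in% names(tab))) {
    abort("annotation table needs columns protein_id, go_id, aspect",
          class = "gofusion_io_error")
  }
  tab[need]
}

#' Assemble a cohort
#'
#' A cohort bundles everything one aspect model consumes: the ordered
#' protein ids, the per-residue sequence archive, the GO-term text archive,
#' the taxonomy map and the annotation table (label matrices are built
#' per aspect from a pruned label space).
#'
#' @param protein_ids Ordered character vector.
#' @param seq_archive,text_archive Archives as returned by
#'   [read_archive()] (lists with `entries`, `dim`, `metadata`).
#' @param taxonomy Named integer vector (see [read_taxonomy()]).
#' @param annotations Tibble (see [read_annotations()]).
#' @param ontology List with `terms`/`edges` (see [read_obo()]).
#' @return A `gofusion_cohort` object.
#' @export
cohort <- function(protein_ids, seq_archive, text_archive, taxonomy,
                   annotations, ontology) {
  missing_seq <- setdiff(protein_ids, names(seq_archive$entries))
  if (length(missing_seq)) {
    abort(paste0("proteins missing from sequence archive: ",
                 paste(head(missing_seq, 3), collapse = ", ")),
          class = "gofusion_cohort_error")
  }
  tax <- setNames(rep(0L, length(protein_ids)), protein_ids)
  known <- intersect(protein_ids, names(taxonomy))
  tax[known] <- taxonomy[known]
  structure(
    list(
      protein_ids = protein_ids,
      seq_archive = seq_archive,
      text_archive = text_archive,
      taxonomy = tax,
      annotations = annotations,
      ontology = ontology
    ),
    class = "gofusion_cohort"
  )
}

#' @export
print.gofusion_cohort <- function(x, ...) {
  cat("<gofusion_cohort> n=", length(x$protein_ids),
      ", seq dim=", x$seq_archive$dim,
      ", text dim=", x$text_archive$dim,
      ", species=", length(unique(x$taxonomy)),
      ", annotations=", nrow(x$annotations), "\n", sep = "")
  invisible(x)
}

subset_cohort <- function(ch, ids) {
  cohort(
    protein_ids = ids,
    seq_archive = list(entries = ch$seq_archive$entries[ids],
                       dim = ch$seq_archive$dim,
                       metadata = ch$seq_archive$metadata),
    text_archive = ch$text_archive,
    taxonomy = ch$taxonomy[ids],
    annotations = dplyr::filter(ch$annotations, .data$protein_id %in% ids),
    ontology = ch$ontology
  )
}

#' Train/test split with label coverage guarantee
#'
#' Splits a cohort at random under the constraint that every term of the
#' supplied label space keeps at least one positive example in the train
#' split ("all GO terms must be present for training"). After the random
#' split, each uncovered term has its lowest-indexed carrier protein moved
#' back into train.
#'
#' @param ch A [cohort()].
#' @param test_fraction In `(0, 1)`; default 0.1 (the CAFA5 convention,
#'   14,225 of 142,246).
#' @param seed Integer seed; the split is a deterministic function of
#'   `(cohort, test_fraction, seed)`.
#' @param label_space Optional [prune_by_frequency()] result; when given,
#'   train coverage is enforced for its retained terms.
#' @return List with `train` and `test` cohorts.
#' @export
split_cohort <- function(ch, test_fraction = 0.1, seed = 0,
                         label_space = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- length(ch$protein_ids)
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) {
    abort("test fraction leaves no training proteins",
          class = "gofusion_split_error")
  }
  test_idx <- withr::with_seed(seed,
    sort(sample.int(n, n_test)))
  in_test <- logical(n)
  in_test[test_idx] <- TRUE

  if (!is.null(label_space)) {
    ids <- ch$protein_ids
    retained <- label_space$graph$terms$id
    ann <- dplyr::filter(ch$annotations, .data$go_id %in% retained)
    carriers <- split(match(ann$protein_id, ids), ann$go_id)
    moved <- 0L
    for (term in names(carriers)) {
      idx <- sort(unique(carriers[[term]]))
      idx <- idx[!is.na(idx)]
      if (!length(idx)) next
      if (all(in_test[idx])) {
        in_test[idx[1]] <- FALSE # lowest-indexed carrier joins train
        moved <- moved + 1L
      }
    }
    uncovered <- vapply(carriers, function(idx) {
      idx <- idx[!is.na(idx)]
      length(idx) > 0L && all(in_test[idx])
    }, logical(1))
    if (any(uncovered)) {
      abort(paste0("cannot cover terms in train: ",
                   paste(names(carriers)[uncovered], collapse = ", ")),
            class = "gofusion_split_error")
    }
  }
  list(
    train = subset_cohort(ch, ch$protein_ids[!in_test]),
    test = subset_cohort(ch, ch$protein_ids[in_test])
  )
}
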