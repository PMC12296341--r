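#' Prune low-frequency GO terms from a label space
#'
#' Long-tail GO terms annotated fewer than `threshold` times are removed
#' from the label space. Pruned nodes are contracted, not merely deleted:
#' the parents of every pruned node are connected directly to its children,
#' so ancestor reachability between retained terms is preserved and the
#' graph convolution still sees the hierarchy. The default threshold of 21
#' corresponds to roughly 0.015% of the CAFA5 cohort (142,246 proteins).
#'
#' @param graph A single-aspect [go_graph()].
#' @param annotations Tibble with columns `protein_id`, `go_id` (an
#'   `aspect` column, if present, is ignored here; pass the aspect's own
#'   annotations).
#' @param threshold Minimum annotation count for a term to be retained.
#' @return A `go_label_space`: list with `graph` (pruned [go_graph()]),
#'   `gamma`, `adjacency_hat` (see [normalized_adjacency()]),
#'   `frequencies` (named counts over *all* original terms) and
#'   `threshold`.
#' @export
prune_by_frequency <- function(graph, annotations, threshold = 21) {
  stopifnot(threshold >= 0)
  counts <- table(annotations$go_id[annotations$go_id %in% graph$terms$id])
  freq <- setNames(integer(nrow(graph$terms)), graph$terms$id)
  freq[names(counts)] <- as.integer(counts)

  keep <- names(freq)[freq >= threshold]
  if (length(keep) == 0L) {
    abort(paste0("threshold ", threshold, " empties the label space"),
          class = "gofusion_prune_error")
  }
  pruned_graph <- contract_pruned(graph, keep)
  structure(
    list(
      graph = pruned_graph,
      gamma = nrow(pruned_graph$terms),
      adjacency_hat = normalized_adjacency(pruned_graph),
      frequencies = freq,
      threshold = threshold
    ),
    class = "go_label_space"
  )
}

#' @export
print.go_label_space <- function(x, ...) {
  cat("<go_label_space> gamma=", x$gamma, " (of ", length(x$frequencies),
      " terms), threshold=", x$threshold, "\n", sep = "")
  invisible(x)
}

# remove terms not in `keep`, reconnecting parents of each removed node to
# its children; removal in reverse topological order keeps chains of pruned
# nodes transitively connected
contract_pruned <- function(graph, keep) {
  drop <- setdiff(graph$terms$id, keep)
  if (length(drop) == 0L) return(graph)
  parents <- split(graph$edges$parent, graph$edges$child)
  children <- split(graph$edges$child, graph$edges$parent)
  relmap <- as.list(setNames(graph$edges$relation,
                             paste(graph$edges$child, graph$edges$parent)))
  # adjacency as environment-free lists we mutate
  for (v in drop) {
    ps <- setdiff(parents[[v]] %||% character(), v)
    cs <- setdiff(children[[v]] %||% character(), v)
    for (ch in cs) {
      # child inherits the pruned node's parents; keep the child-edge relation
      rel <- relmap[[paste(ch, v)]] %||% "is_a"
      parents[[ch]] <- unique(c(setdiff(parents[[ch]], v), ps))
      for (p in ps) {
        k <- paste(ch, p)
        if (is.null(relmap[[k]])) relmap[[k]] <- rel
        children[[p]] <- unique(c(children[[p]], ch))
      }
    }
    for (p in ps) children[[p]] <- setdiff(children[[p]], v)
    parents[[v]] <- NULL
    children[[v]] <- NULL
  }
  kept_parents <- parents[intersect(names(parents), keep)]
  edges <- tibble::tibble(
    child = rep(names(kept_parents), lengths(kept_parents)),
    parent = unlist(kept_parents, use.names = FALSE)
  )
  edges <- dplyr::filter(edges, .data$parent %in% keep)
  edges$relation <- vapply(paste(edges$child, edges$parent),
                           function(k) relmap[[k]] %||% "is_a", character(1))
  go_graph(dplyr::filter(graph$terms, .data$id %in% keep), edges)
}

#' Automatic pruning threshold from cohort size
#'
#' Recomputes the "0.015% of samples" rule for an arbitrary cohort size.
#'
#' @param n_proteins Number of proteins in the cohort.
#' @param rate Fraction of samples (default 0.015%, i.e. `1.5e-4`).
#' @return Integer threshold (at least 1).
#' @export
auto_threshold <- function(n_proteins, rate = 1.5e-4) {
  max(1L, as.integer(round(n_proteins * rate)))
}

#' Binary label matrix for a protein cohort
#'
#' @param label_space A [prune_by_frequency()] result.
#' @param annotations Tibble with `protein_id`, `go_id`.
#' @param protein_order Character vector fixing the row order.
#' @param propagate If `TRUE`, each positive term also sets all of its
#'   retained `is_a`/`part_of` ancestors (true-path rule). Off by default:
#'   curated CAFA-style label files are conventionally pre-propagated.
#' @return Binary `n x gamma` matrix with protein / term dimnames.
#' @export
build_label_matrix <- function(label_space, annotations, protein_order,
                               propagate = FALSE) {
  ids <- label_space$graph$terms$id
  Y <- matrix(0L, length(protein_order), length(ids),
              dimnames = list(protein_order, ids))
  ann <- dplyr::filter(annotations, .data$go_id %in% ids,
                       .data$protein_id %in% protein_order)
  if (nrow(ann) > 0L) {
    Y[cbind(match(ann$protein_id, protein_order), match(ann$go_id, ids))] <- 1L
    if (propagate) {
      anc <- graph_ancestors(label_space$graph)
      for (j in seq_along(ids)) {
        pos <- which(Y[, j] == 1L)
        if (!length(pos)) next
        up <- anc[[ids[j]]]
        if (length(up)) Y[pos, match(up, ids)] <- 1L
      }
    }
  }
  empty <- rownames(Y)[rowSums(Y) == 0L]
  if (length(empty)) {
    warn(paste0(length(empty), " protein(s) have no retained annotations ",
                "(kept with all-zero rows), e.g. ", empty[1]))
  }
  Y
}

#' Write / read a label-space manifest
#'
#' The manifest records the retained term order, per-term frequencies and
#' the pruning threshold as JSON, together with a digest of the term order
#' used to guard checkpoint/label-space compatibility.
#'
#' @param label_space A `go_label_space`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_label_manifest <- function(label_space, path) {
  obj <- list(
    term_order = label_space$graph$terms$id,
    term_digest = digest_string(paste(label_space$graph$terms$id,
                                      collapse = ",")),
    frequencies = as.list(label_space$frequencies),
    threshold = label_space$threshold,
    gamma = label_space$gamma
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

label_space_digest <- function(label_space) {
  digest_string(paste(label_space$graph$terms$id, collapse = ","))
}
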