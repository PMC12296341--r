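#' Build a single-aspect GO graph
#'
#' A `go_graph` holds the terms of one GO aspect in deterministic
#' (lexicographic) order together with the child-to-parent `is_a`/`part_of`
#' edges between them. The term order defines the label-space column indices
#' used by every downstream matrix.
#'
#' @param terms Tibble with columns `id`, `name`, `definition`, `aspect`.
#' @param edges Tibble with columns `child`, `parent`, `relation`; endpoints
#'   must be in `terms$id`.
#' @return A `go_graph` object (list with `terms`, `edges`, `index`).
#' @export
go_graph <- function(terms, edges) {
  terms <- dplyr::arrange(terms, .data$id)
  if (anyDuplicated(terms$id)) {
    abort("duplicate term ids in graph", class = "gofusion_graph_error")
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble::tibble(child = character(), parent = character(),
                            relation = character())
  } else {
    edges <- dplyr::arrange(dplyr::distinct(edges),
                            .data$child, .data$parent, .data$relation)
  }
  bad <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(bad)) {
    abort(paste0("edge endpoints not in term set: ",
                 paste(head(bad, 3), collapse = ", ")),
          class = "gofusion_graph_error")
  }
  g <- structure(
    list(
      terms = terms,
      edges = edges,
      index = setNames(seq_len(nrow(terms)), terms$id)
    ),
    class = "go_graph"
  )
  if (nrow(edges) > 0L && !igraph::is_dag(as_igraph(g))) {
    abort("graph is not acyclic", class = "gofusion_graph_error")
  }
  g
}

#' @export
print.go_graph <- function(x, ...) {
  cat("<go_graph> ", nrow(x$terms), " terms (",
      paste(unique(x$terms$aspect), collapse = "/"), "), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("child", "parent")],
    directed = TRUE,
    vertices = graph$terms$id
  )
}

#' Restrict an ontology to one aspect
#'
#' Induces the subgraph on the terms of a single GO aspect. Cross-aspect
#' edges are discarded; the three subontologies are modeled independently.
#'
#' @param terms,edges Output of [read_obo()] (or compatible tibbles).
#' @param aspect `"BP"`, `"MF"` or `"CC"`.
#' @return A [go_graph()].
#' @export
split_subontology <- function(terms, edges, aspect) {
  aspect <- match.arg(aspect, c("BP", "MF", "CC"))
  keep <- dplyr::filter(terms, .data$aspect == !!aspect)
  if (nrow(keep) == 0L) {
    abort(paste0("no terms for aspect ", aspect),
          class = "gofusion_graph_error")
  }
  e <- dplyr::filter(edges, .data$child %in% keep$id,
                     .data$parent %in% keep$id)
  go_graph(keep, e)
}

#' Symmetric normalized adjacency of a GO graph
#'
#' Computes \eqn{\hat A = D^{-1/2} (A + I) D^{-1/2}} where `A` is the
#' symmetrized 0/1 adjacency over the union of `is_a` and `part_of` edges
#' and `D` is the degree matrix of `A + I`. This is the standard
#' self-looped graph-convolution normalization; \eqn{\hat A} is symmetric
#' with eigenvalues in `[-1, 1]`.
#'
#' @param graph A [go_graph()].
#' @return A dense `gamma x gamma` matrix with term ids as dimnames.
#' @export
normalized_adjacency <- function(graph) {
  n <- nrow(graph$terms)
  A <- matrix(0, n, n, dimnames = list(graph$terms$id, graph$terms$id))
  if (nrow(graph$edges) > 0L) {
    ci <- graph$index[graph$edges$child]
    pi <- graph$index[graph$edges$parent]
    A[cbind(ci, pi)] <- 1
    A[cbind(pi, ci)] <- 1
  }
  AI <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(AI))
  dinv * AI * rep(dinv, each = n)
}

# retained-ancestor closure: named list id -> character vector of ancestors
# (transitive, excluding the term itself)
graph_ancestors <- function(graph) {
  g <- as_igraph(graph)
  ord <- igraph::topo_sort(g, mode = "out")$name
  anc <- setNames(rep(list(character()), nrow(graph$terms)), graph$terms$id)
  parents <- split(graph$edges$parent, graph$edges$child)
  # edges run child -> parent, so topo order lists children first; fill
  # ancestor sets from the parent end down
  for (id in rev(ord)) {
    p <- parents[[id]]
    if (is.null(p)) next
    anc[[id]] <- unique(c(p, unlist(anc[p], use.names = FALSE)))
  }
  anc
}
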