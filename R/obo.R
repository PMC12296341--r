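#' Read a Gene Ontology OBO file
#'
#' Parses an OBO 1.2/1.4 ontology file into a term table and an edge table.
#' Only the fields used downstream are retained: accession, name, definition,
#' namespace (mapped to the three GO aspects) and the `is_a` / `part_of`
#' relations. All other relationship types (`regulates`, `occurs_in`, ...)
#' are dropped, and obsolete terms are excluded together with any edge that
#' touches them.
#'
#' @param path Path to an OBO file.
#' @return A list with two tibbles:
#'   * `terms`: columns `id`, `name`, `definition`, `aspect` (one of
#'     `"BP"`, `"MF"`, `"CC"`) and `obsolete` (always `FALSE` here).
#'   * `edges`: columns `child`, `parent`, `relation` (`"is_a"` or
#'     `"part_of"`), restricted to edges between retained terms.
#' @examples
#' obo <- system.file("extdata", "mini_go.obo", package = "gofusion")
#' onto <- read_obo(obo)
#' onto$terms
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("OBO file not found: ", path), class = "gofusion_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) {
    abort("no stanzas found; not an OBO file?", class = "gofusion_parse_error")
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  kinds <- lines[starts]

  terms <- list()
  edges <- list()
  for (s in seq_along(starts)) {
    if (kinds[s] != "[Term]") next
    body <- lines[starts[s]:ends[s]]
    term <- parse_term_stanza(body)
    if (is.null(term)) next # obsolete
    terms[[length(terms) + 1L]] <- term$row
    if (nrow(term$edges) > 0L) edges[[length(edges) + 1L]] <- term$edges
  }
  terms <- dplyr::bind_rows(terms)
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(child = character(), parent = character(),
                   relation = character())
  # drop edges whose parent is obsolete / absent from the retained set
  edges <- dplyr::filter(edges, .data$parent %in% terms$id,
                         .data$child %in% terms$id)
  list(terms = terms, edges = edges)
}

obo_field <- function(body, key) {
  hits <- grep(paste0("^", key, ":"), body, value = TRUE)
  trimws(sub(paste0("^", key, ":\\s*"), "", hits))
}

parse_term_stanza <- function(body) {
  id <- obo_field(body, "id")[1]
  if (is.na(id) || !length(id)) {
    abort("term stanza without id", class = "gofusion_parse_error")
  }
  obs <- obo_field(body, "is_obsolete")
  if (length(obs) && tolower(obs[1]) == "true") return(NULL)

  ns <- obo_field(body, "namespace")
  if (!length(ns)) {
    abort(paste0("term stanza ", id, " has no namespace"),
          class = "gofusion_parse_error")
  }
  aspect <- switch(ns[1],
    biological_process = "BP",
    molecular_function = "MF",
    cellular_component = "CC",
    abort(paste0("term stanza ", id, " has unknown namespace '", ns[1], "'"),
          class = "gofusion_parse_error")
  )
  name <- obo_field(body, "name")
  def <- obo_field(body, "def")
  def <- if (length(def)) strip_def(def[1]) else ""

  # is_a: GO:xxxxxxx ! comment
  isa <- obo_field(body, "is_a")
  isa <- sub("\\s*!.*$", "", isa)
  rel <- obo_field(body, "relationship")
  po <- grep("^part_of\\s", rel, value = TRUE)
  po <- sub("^part_of\\s+", "", po)
  po <- sub("\\s*!.*$", "", po)

  edges <- tibble::tibble(
    child = rep(id, length(isa) + length(po)),
    parent = c(isa, po),
    relation = c(rep("is_a", length(isa)), rep("part_of", length(po)))
  )
  row <- tibble::tibble(
    id = id,
    name = if (length(name)) name[1] else "",
    definition = def,
    aspect = aspect,
    obsolete = FALSE
  )
  list(row = row, edges = edges)
}

# def: "quoted text" [citation, citation] -> quoted text
strip_def <- function(x) {
  x <- sub("\\s*\\[[^]]*\\]\\s*$", "", x)
  x <- sub('^"', "", x)
  sub('"$', "", x)
}
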