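#' Embedding archives
#'
#' An embedding archive maps entity ids (protein accessions or GO term ids)
#' to dense `dim x length` matrices of per-position embeddings. On disk an
#' archive is a flat little-endian IEEE double container plus a JSON sidecar
#' (`<path>.json`) recording the entry order, the shared embedding width,
#' per-entry lengths and free-form metadata; the write -> read round trip is
#' bit-exact.
#'
#' @param entries Named list of numeric matrices, all with the same number
#'   of rows (the embedding width).
#' @param path Output path for the binary container (sidecar goes to
#'   `paste0(path, ".json")`).
#' @param metadata Optional list (e.g. source tag, creation seed).
#' @return `write_archive()` returns `path` invisibly; `read_archive()`
#'   returns a list with `entries`, `dim`, `metadata`.
#' @examples
#' a <- list(p1 = matrix(rnorm(8), 2), p2 = matrix(rnorm(6), 2))
#' f <- tempfile()
#' write_archive(a, f)
#' arc <- read_archive(f)
#' identical(arc$entries, a)
#' @export
write_archive <- function(entries, path, metadata = list()) {
  if (length(entries)) {
    dims <- vapply(entries, nrow, integer(1))
    if (length(unique(dims)) != 1L) {
      abort(paste0("inconsistent embedding widths: ",
                   paste(unique(dims), collapse = ", ")),
            class = "gofusion_archive_error")
    }
    lens <- vapply(entries, ncol, integer(1))
    if (any(lens < 1L)) {
      abort("every entry needs length >= 1", class = "gofusion_archive_error")
    }
    d <- unname(dims[1])
  } else {
    lens <- integer()
    d <- 0L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  for (m in entries) writeBin(as.vector(m), con, size = 8L,
                              endian = "little")
  sidecar <- list(
    format = "gofusion-archive-v1",
    dim = d,
    ids = as.list(names(entries)),
    lengths = as.list(unname(lens)),
    metadata = metadata
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    abort(paste0("archive or sidecar missing for ", path),
          class = "gofusion_io_error")
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!identical(side$format, "gofusion-archive-v1")) {
    abort("unrecognized archive container", class = "gofusion_archive_error")
  }
  d <- as.integer(side$dim)
  lens <- as.integer(side$lengths)
  ids <- as.character(side$ids)
  expected <- sum(as.double(lens) * d) * 8
  if (length(ids) && file.info(path)$size != expected) {
    abort("archive container is corrupted (size mismatch)",
          class = "gofusion_archive_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  entries <- vector("list", length(ids))
  names(entries) <- ids
  for (i in seq_along(ids)) {
    v <- readBin(con, "double", n = d * lens[i], size = 8L,
                 endian = "little")
    entries[[i]] <- matrix(v, nrow = d)
  }
  meta <- side$metadata
  if (length(meta) == 0L) meta <- list()
  list(entries = entries, dim = d, metadata = meta)
}
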