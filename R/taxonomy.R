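#' Taxonomy label-encoding table
#'
#' A learnable `(n_species + 1) x d` embedding table; row 1 (species code
#' 0) is the reserved unknown-species row. Equivalent to one-hot encoding
#' followed by a linear layer.
#'
#' @param n_species Number of known species codes (1..n_species).
#' @param d Embedding width.
#' @param w_tax Fixed mixing weight (default 0.1; setting it to 0 is the
#'   taxonomy-off ablation).
#' @param init_sd Gaussian initialization sd (default 0.02).
#' @param seed Seed.
#' @return A `taxonomy_encoder` list with `table` and `w_tax`.
#' @export
taxonomy_encoder <- function(n_species, d, w_tax = 0.1, init_sd = 0.02,
                             seed = 0) {
  stopifnot(n_species >= 0, w_tax >= 0)
  withr::with_seed(seed, {
    structure(list(
      table = matrix(rnorm((n_species + 1L) * d, sd = init_sd),
                     n_species + 1L, d),
      w_tax = w_tax,
      n_species = as.integer(n_species)
    ), class = "taxonomy_encoder")
  })
}

#' Pool fused residue-level features to protein level
#'
#' Arithmetic mean over all positions (sequence and selected-text columns
#' jointly).
#'
#' @param fused A `d x L` matrix (or a [fuse_features()] result).
#' @return A length-`d` vector.
#' @export
pool_protein <- function(fused) {
  if (is.list(fused)) fused <- fused$features
  if (!is.matrix(fused) || ncol(fused) < 1) {
    abort("pooling needs at least one position",
          class = "gofusion_shape_error")
  }
  rowMeans(fused)
}

#' Mix the species encoding into a pooled protein feature
#'
#' `x_mix = table[species] * w_tax + x_pro`. Species codes outside the
#' table (and the reserved code 0) use the unknown row; this is a defined
#' path, not an error.
#'
#' @param x_pro Length-`d` pooled feature.
#' @param species Non-negative integer species code.
#' @param encoder A [taxonomy_encoder()].
#' @return Length-`d` mixed feature vector.
#' @export
mix_features <- function(x_pro, species, encoder) {
  row <- species_row(encoder, species)
  encoder$table[row, ] * encoder$w_tax + x_pro
}

species_row <- function(encoder, species) {
  species <- as.integer(species)
  if (is.na(species) || species < 0L || species > encoder$n_species) 1L
  else species + 1L
}
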