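#' Text-alignment parameters
#'
#' Learnable state of the text-alignment stage: the linear projection that
#' maps text embeddings (width `d_prime`) into the sequence embedding space
#' (width `d`) and the position-wise feed-forward network applied after
#' attention. The attention itself is parameter-free dot-product attention
#' (the input serves as query, key and value); heads are contiguous
#' `d / n_heads` row slices, each scaled by `sqrt(d / n_heads)`.
#'
#' @param d Sequence embedding width (must be divisible by `n_heads`).
#' @param d_prime Text embedding width.
#' @param n_heads Number of attention heads (default 8).
#' @param fragment_length Maximum positions per attention fragment
#'   (default 512); longer concatenations are split into consecutive
#'   fragments.
#' @param top_k_texts Cap on selected texts per protein (default 5).
#' @param dropout Dropout rate on the attention output during training.
#' @param seed Seed for parameter initialization.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(d, d_prime, n_heads = 8, fragment_length = 512,
                             top_k_texts = 5, dropout = 0.3, seed = 0) {
  if (d %% n_heads != 0) {
    abort("d must be divisible by n_heads", class = "gofusion_shape_error")
  }
  stopifnot(fragment_length >= 1, top_k_texts >= 0)
  withr::with_seed(seed, {
    h <- 2L * d
    structure(list(
      P = matrix(rnorm(d * d_prime, sd = sqrt(2 / d_prime)), d, d_prime),
      W1f = matrix(rnorm(h * d, sd = sqrt(2 / d)), h, d),
      b1f = numeric(h),
      W2f = matrix(rnorm(d * h, sd = sqrt(2 / h)), d, h),
      b2f = numeric(d),
      n_heads = as.integer(n_heads),
      fragment_length = as.integer(fragment_length),
      top_k_texts = as.integer(top_k_texts),
      dropout = dropout
    ), class = "alignment_params")
  })
}

# cached sinusoid table, grown on demand (keyed by embedding width)
pe_table <- function(d, L) {
  key <- as.character(d)
  tab <- the[[paste0("pe_", key)]]
  if (is.null(tab) || ncol(tab) < L) {
    Lmax <- max(L, 64L)
    pos <- matrix(rep(seq_len(Lmax) - 1, each = d), d, Lmax)
    i2 <- 2 * ((seq_len(d) - 1) %/% 2) # 2i for rows (2i, 2i+1)
    ang <- pos / (10000^(i2 / d))
    tab <- ang
    odd <- seq_len(d) %% 2 == 1 # rows 1,3,... hold dims 0,2,... -> sin
    tab[odd, ] <- sin(ang[odd, , drop = FALSE])
    tab[!odd, ] <- cos(ang[!odd, , drop = FALSE])
    the[[paste0("pe_", key)]] <- tab
  }
  tab[, seq_len(L), drop = FALSE]
}

#' Sinusoidal positional encoding
#'
#' Adds the transformer sinusoid table to a `d x L` embedding:
#' `PE(pos, 2i) = sin(pos / 10000^(2i/d))` and
#' `PE(pos, 2i+1) = cos(pos / 10000^(2i/d))`, positions counted from 0.
#'
#' @param m A `d x L` numeric matrix.
#' @return `m` plus the positional table (same shape).
#' @export
positional_encode <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 1)
  m + pe_table(nrow(m), ncol(m))
}

#' Project a text embedding into sequence space
#'
#' @param params [alignment_params()].
#' @param text A `d_prime x l'` matrix.
#' @return A `d x l'` matrix (`P %*% text`).
#' @export
project_text <- function(params, text) {
  params$P %*% text
}

#' Select relevant GO-term texts for a protein
#'
#' Scores each candidate text by the mean per-position cosine similarity
#' between the projected text columns and the aligned sequence columns
#' (positions `1..min(l, l')`), keeps texts with positive relevance, sorts
#' by descending relevance (ties broken by GO id) and truncates to
#' `top_k_texts`. Zero-norm columns contribute cosine 0.
#'
#' @param seq A `d x l` sequence embedding.
#' @param texts Named list of `d_prime x l'` text embeddings.
#' @param params [alignment_params()].
#' @return Tibble with columns `id`, `relevance`, ordered as selected;
#'   zero rows when nothing passes the filter.
#' @export
relevance_select <- function(seq, texts, params) {
  proj <- lapply(texts, function(tx) params$P %*% tx)
  sel <- select_projected(seq, proj, params$top_k_texts)
  tibble::tibble(id = sel$ids, relevance = sel$relevance)
}

# relevance scoring/selection on already-projected texts (hot path)
select_projected <- function(seq, proj, top_k) {
  if (length(proj) == 0L || top_k == 0L) {
    return(list(ids = character(), relevance = numeric()))
  }
  l <- ncol(seq)
  seq_norm <- sqrt(.colSums(seq * seq, nrow(seq), l))
  rel <- vapply(proj, function(tp) {
    K <- min(l, ncol(tp))
    a <- tp[, seq_len(K), drop = FALSE]
    b <- seq[, seq_len(K), drop = FALSE]
    na <- sqrt(.colSums(a * a, nrow(a), K))
    cosv <- .colSums(a * b, nrow(a), K) / (na * seq_norm[seq_len(K)])
    bad <- !is.finite(cosv)
    if (any(bad)) {
      log_once("zero_norm_cosine",
               "zero-norm column(s) in relevance scoring; cosine taken as 0")
      cosv[bad] <- 0
    }
    sum(cosv) / K
  }, numeric(1))
  keep <- which(rel > 0)
  if (!length(keep)) return(list(ids = character(), relevance = numeric()))
  ids <- names(proj)[keep]
  ord <- order(-rel[keep], ids)
  take <- seq_len(min(top_k, length(keep)))
  list(ids = ids[ord][take], relevance = unname(rel[keep][ord][take]))
}

# pack position blocks into fragments of <= fragment_length columns.
# blocks: integer vector of block sizes (first = sequence, rest = texts).
# the sequence block may be chopped at fragment boundaries; a text block
# never straddles a fragment boundary (it opens a new fragment instead,
# and is chopped only if longer than a whole fragment).
plan_fragments <- function(blocks, fragment_length) {
  runs <- list() # list of (start, len) in concatenated coordinates
  frag_of <- integer()
  frag <- 1L
  used <- 0L
  offset <- 0L
  for (b in seq_along(blocks)) {
    size <- blocks[b]
    if (b == 1L) {
      pos <- 0L
      while (pos < size) {
        take <- min(size - pos, fragment_length - used)
        if (take == 0L) {
          frag <- frag + 1L
          used <- 0L
          next
        }
        runs[[length(runs) + 1L]] <- c(offset + pos + 1L, take)
        frag_of <- c(frag_of, frag)
        used <- used + take
        pos <- pos + take
      }
    } else {
      if (size > fragment_length - used) {
        frag <- frag + 1L
        used <- 0L
      }
      pos <- 0L
      while (pos < size) {
        take <- min(size - pos, fragment_length)
        runs[[length(runs) + 1L]] <- c(offset + pos + 1L, take)
        frag_of <- c(frag_of, frag)
        pos <- pos + take
        used <- used + take
        if (pos < size) {
          frag <- frag + 1L
          used <- 0L
        }
      }
    }
    offset <- offset + size
  }
  split(runs, frag_of)
}

# multi-head parameter-free attention over one fragment.
# X: d x L. Returns list(out, heads = list of softmax weight matrices).
attention_fragment <- function(X, n_heads) {
  d <- nrow(X)
  L <- ncol(X)
  dh <- d %/% n_heads
  s <- sqrt(dh)
  out <- matrix(0, d, L)
  Ws <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    rows <- ((h - 1L) * dh + 1L):(h * dh)
    Xh <- X[rows, , drop = FALSE]
    S <- crossprod(Xh) / s # L x L
    if (L > 1L) {
      rmax <- S[cbind(seq_len(L), max.col(S, ties.method = "first"))]
      W <- exp(S - rmax) # vector recycles down rows: row-wise shift
    } else {
      W <- exp(S - S)
    }
    W <- W / .rowSums(W, L, L)
    out[rows, ] <- tcrossprod(Xh, W)
    Ws[[h]] <- W
  }
  list(out = out, weights = Ws)
}

#' Fuse a sequence embedding with selected text embeddings
#'
#' Concatenates the positional-encoded sequence with the positional-encoded
#' projected texts, runs parameter-free multi-head dot-product attention
#' within fragments of at most `fragment_length` positions, then applies
#' the position-wise feed-forward network with a residual connection. With
#' no selected text the same operator runs on the sequence alone.
#'
#' @param seq A `d x l` sequence embedding.
#' @param texts Named list of `d_prime x l'` text embeddings to fuse
#'   (already restricted to the [relevance_select()] choice).
#' @param params [alignment_params()].
#' @param positional Apply positional encoding (default `TRUE`; turning it
#'   off restores permutation equivariance within a fragment).
#' @param training Apply dropout to the attention output (uses the current
#'   RNG stream).
#' @param keep_cache Retain intermediates for backpropagation (internal).
#' @return List with `features` (`d x (l + sum l')`), `mask` (character
#'   vector: `"seq"` or the text id per position) and, if requested,
#'   `cache`.
#' @export
fuse_features <- function(seq, texts = list(), params,
                          positional = TRUE, training = FALSE,
                          keep_cache = FALSE) {
  if (!all(is.finite(seq)) ||
      (length(texts) && !all(vapply(texts, function(m) all(is.finite(m)),
                                    logical(1))))) {
    abort("non-finite values in fusion input", class = "gofusion_value_error")
  }
  projected <- lapply(texts, function(tx) params$P %*% tx)
  fuse_core(seq, projected, texts, params, positional, training, keep_cache)
}

# hot path: texts already projected through P
fuse_core <- function(seq, projected, texts, params, positional = TRUE,
                      training = FALSE, keep_cache = FALSE) {
  enc <- function(m) if (positional) positional_encode(m) else m
  blocks <- c(list(enc(seq)), lapply(projected, enc))
  sizes <- vapply(blocks, ncol, integer(1))
  X0 <- do.call(cbind, blocks)
  mask <- c(rep("seq", ncol(seq)),
            rep(names(texts) %||% character(), vapply(texts, ncol,
                                                      integer(1))))

  frags <- plan_fragments(sizes, params$fragment_length)
  A <- matrix(0, nrow(X0), ncol(X0))
  frag_cache <- vector("list", length(frags))
  for (f in seq_along(frags)) {
    cols <- unlist(lapply(frags[[f]], function(r) seq(r[1],
                                                      length.out = r[2])))
    att <- attention_fragment(X0[, cols, drop = FALSE], params$n_heads)
    A[, cols] <- att$out
    if (keep_cache) frag_cache[[f]] <- list(cols = cols,
                                            weights = att$weights)
  }

  drop_mask <- NULL
  A_d <- A
  if (training && params$dropout > 0) {
    drop_mask <- matrix(runif(length(A)) >= params$dropout, nrow(A))
    A_d <- A * drop_mask / (1 - params$dropout)
  }

  Z1 <- params$W1f %*% A_d + params$b1f
  R1 <- pmax(Z1, 0)
  Y <- params$W2f %*% R1 + params$b2f + A_d

  out <- list(features = Y, mask = mask)
  if (keep_cache) {
    out$cache <- list(X0 = X0, frags = frag_cache, A = A, A_d = A_d,
                      drop_mask = drop_mask, Z1 = Z1, R1 = R1,
                      sizes = sizes, projected = projected,
                      texts = texts, positional = positional)
  }
  out
}
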