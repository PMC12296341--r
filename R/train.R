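#' Train a multi-modal GO prediction model for one aspect
#'
#' Jointly optimizes the text projection, the post-attention feed-forward
#' network, the taxonomy embedding table and the prediction head with Adam
#' on element-wise binary cross-entropy, following the linear-probing
#' recipe (frozen upstream embeddings; only the fusion and head parameters
#' learn). Gradients are computed by exact backpropagation through the
#' fusion stack; the hard text selection of [relevance_select()] is treated
#' as non-differentiable.
#'
#' @param ch Training [cohort()].
#' @param aspect `"BP"`, `"MF"` or `"CC"`.
#' @param label_space Optional [prune_by_frequency()] result; built from
#'   the cohort's ontology and annotations when `NULL`.
#' @param modules Character subset of `c("text", "taxonomy", "relation")`;
#'   dropping an entry is the corresponding ablation (text off: pooled raw
#'   sequence embedding; taxonomy off: `w_tax = 0`; relation off: identity
#'   adjacency).
#' @param config [train_config()].
#' @param threshold Pruning threshold used when `label_space` is `NULL`
#'   (default [auto_threshold()] of the cohort size).
#' @param w_tax Taxonomy mixing weight (ignored when the taxonomy module
#'   is off).
#' @param propagate Propagate annotations to ancestors when building the
#'   label matrix.
#' @return A `gofusion_model` with the learned parameters, the per-epoch
#'   `loss_trace` and everything needed to predict on new cohorts.
#' @export
train_model <- function(ch, aspect = "BP", label_space = NULL,
                        modules = c("text", "taxonomy", "relation"),
                        config = train_config(), threshold = NULL,
                        w_tax = 0.1, propagate = FALSE) {
  modules <- validate_modules(modules)
  ann <- dplyr::filter(ch$annotations, .data$aspect == !!aspect)
  if (is.null(label_space)) {
    graph <- split_subontology(ch$ontology$terms, ch$ontology$edges, aspect)
    label_space <- prune_by_frequency(
      graph, ann, threshold %||% auto_threshold(length(ch$protein_ids)))
  }
  Y <- build_label_matrix(label_space, ann, ch$protein_ids,
                          propagate = propagate)
  gamma <- label_space$gamma
  d <- ch$seq_archive$dim
  Ahat <- if ("relation" %in% modules) label_space$adjacency_hat else
    diag(gamma)

  texts <- ch$text_archive$entries[
    intersect(label_space$graph$terms$id, names(ch$text_archive$entries))]
  use_text <- "text" %in% modules && length(texts) > 0L
  n_species <- max(0L, ch$taxonomy)

  align <- if (use_text) {
    alignment_params(d, ch$text_archive$dim, seed = config$seed + 1L)
  }
  tax <- taxonomy_encoder(n_species, d,
                          w_tax = if ("taxonomy" %in% modules) w_tax else 0,
                          seed = config$seed + 2L)
  headp <- head_params(d, gamma, seed = config$seed + 3L)

  params <- collect_params(align, tax, headp, use_text,
                           "taxonomy" %in% modules)
  opt <- adam_init(params, config)

  n <- length(ch$protein_ids)
  species_rows <- vapply(ch$taxonomy, function(s) species_row(tax, s),
                         integer(1))
  loss_trace <- numeric(config$epochs)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, epoch)
      order <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- order[start:min(start + config$batch_size - 1L, n)]
        step <- train_batch(ch, idx, Y, align, tax, headp, Ahat,
                            use_text, texts, species_rows, params)
        total <- total + step$loss * length(idx)
        params <- adam_step(params, step$grads, opt, lr)
        assigned <- assign_params(params, align, tax, headp, use_text)
        align <- assigned$align
        tax <- assigned$tax
        headp <- assigned$headp
        if (!all(vapply(params, function(p) all(is.finite(p)), logical(1)))) {
          abort(paste0("non-finite parameters at epoch ", epoch),
                class = "gofusion_train_error")
        }
      }
      loss_trace[epoch] <- total / n
    }
  })

  structure(list(
    aspect = aspect,
    label_space = label_space,
    modules = modules,
    align = align,
    tax = tax,
    head = headp,
    adjacency = Ahat,
    config = config,
    loss_trace = loss_trace,
    d = d,
    term_digest = label_space_digest(label_space),
    n_train = n
  ), class = "gofusion_model")
}

validate_modules <- function(modules) {
  bad <- setdiff(modules, c("text", "taxonomy", "relation"))
  if (length(bad)) {
    abort(paste0("unknown module switch: ", paste(bad, collapse = ", ")),
          class = "gofusion_config_error")
  }
  modules
}

#' @export
print.gofusion_model <- function(x, ...) {
  cat("<gofusion_model> aspect=", x$aspect, ", gamma=",
      x$label_space$gamma, ", modules={",
      paste(x$modules, collapse = ","), "}, final loss=",
      signif(utils::tail(x$loss_trace, 1), 4), "\n", sep = "")
  invisible(x)
}

# ---- parameter plumbing ----------------------------------------------------

collect_params <- function(align, tax, headp, use_text, use_tax) {
  p <- list(W1 = headp$W1, b1 = headp$b1, W2 = headp$W2, b2 = headp$b2,
            W_A = headp$W_A)
  if (use_text) {
    p <- c(p, list(P = align$P, W1f = align$W1f, b1f = align$b1f,
                   W2f = align$W2f, b2f = align$b2f))
  }
  if (use_tax) p <- c(p, list(tax_table = tax$table))
  p
}

assign_params <- function(params, align, tax, headp, use_text) {
  headp$W1 <- params$W1
  headp$b1 <- params$b1
  headp$W2 <- params$W2
  headp$b2 <- params$b2
  headp$W_A <- params$W_A
  if (use_text) {
    align$P <- params$P
    align$W1f <- params$W1f
    align$b1f <- params$b1f
    align$W2f <- params$W2f
    align$b2f <- params$b2f
  }
  if (!is.null(params$tax_table)) tax$table <- params$tax_table
  list(align = align, tax = tax, headp = headp)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

adam_init <- function(params, config) {
  e <- new.env(parent = emptyenv())
  e$m <- zero_like(params)
  e$v <- zero_like(params)
  e$t <- 0L
  e$beta1 <- config$beta1
  e$beta2 <- config$beta2
  e$eps <- config$eps
  e
}

adam_step <- function(params, grads, opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1
  b2 <- opt$beta2
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    opt$m[[k]] <- b1 * opt$m[[k]] + (1 - b1) * g
    opt$v[[k]] <- b2 * opt$v[[k]] + (1 - b2) * g^2
    params[[k]] <- params[[k]] -
      lr * (opt$m[[k]] / c1) / (sqrt(opt$v[[k]] / c2) + opt$eps)
  }
  params
}

# ---- forward / backward ----------------------------------------------------

# forward for one protein up to the pooled feature; returns cache when
# training so the batch backward can run
forward_protein <- function(seq, texts, align, use_text, training,
                            proj = NULL) {
  if (!use_text) {
    return(list(x_pro = rowMeans(seq), cache = NULL))
  }
  if (is.null(proj)) proj <- lapply(texts, function(tx) align$P %*% tx)
  sel <- select_projected(seq, proj, align$top_k_texts)
  fz <- fuse_core(seq, proj[sel$ids], texts[sel$ids], align,
                  training = training, keep_cache = training)
  list(x_pro = rowMeans(fz$features), cache = fz$cache)
}

# exact gradients for one minibatch; returns list(loss, grads)
train_batch <- function(ch, idx, Y, align, tax, headp, Ahat, use_text,
                        texts, species_rows, params) {
  b <- length(idx)
  gamma <- ncol(headp$W2)

  proj <- if (use_text) lapply(texts, function(tx) align$P %*% tx)
  fw <- lapply(idx, function(i) {
    forward_protein(ch$seq_archive$entries[[i]], texts, align, use_text,
                    training = TRUE, proj = proj)
  })
  Xpro <- do.call(rbind, lapply(fw, function(f) f$x_pro))
  rows <- species_rows[idx]
  Xb <- Xpro + tax$w_tax * tax$table[rows, , drop = FALSE]
  Yb <- Y[idx, , drop = FALSE]
  dimnames(Xb) <- NULL
  dimnames(Yb) <- NULL

  # head forward with intermediates
  Hpre <- Xb %*% headp$W1 + rep(headp$b1, each = b)
  H1 <- pmax(Hpre, 0)
  H <- H1 %*% headp$W2 + rep(headp$b2, each = b)
  Zg <- H %*% Ahat
  logits <- Zg %*% headp$W_A
  scores <- sigmoid(logits)
  loss <- bce_loss(scores, Yb)
  if (!is.finite(loss)) {
    abort("non-finite loss", class = "gofusion_train_error")
  }

  grads <- list()
  dlogits <- (scores - Yb) / (b * gamma)
  grads$W_A <- crossprod(Zg, dlogits)
  dZg <- dlogits %*% t(headp$W_A)
  dH <- dZg %*% t(Ahat)
  grads$b2 <- colSums(dH)
  grads$W2 <- crossprod(H1, dH)
  dH1 <- dH %*% t(headp$W2)
  dHpre <- dH1 * (Hpre > 0)
  grads$b1 <- colSums(dHpre)
  grads$W1 <- crossprod(Xb, dHpre)
  dXb <- dHpre %*% t(headp$W1)

  if (!is.null(params$tax_table)) {
    gt <- tax$table * 0
    for (r in seq_len(b)) {
      gt[rows[r], ] <- gt[rows[r], ] + tax$w_tax * dXb[r, ]
    }
    grads$tax_table <- gt
  }

  if (use_text) {
    ga <- list(P = align$P * 0, W1f = align$W1f * 0,
               b1f = align$b1f * 0, W2f = align$W2f * 0,
               b2f = align$b2f * 0)
    for (r in seq_len(b)) {
      if (is.null(fw[[r]]$cache)) next
      ga <- backward_fusion(fw[[r]]$cache, dXb[r, ], align, ga)
    }
    grads <- c(grads, ga)
  }
  list(loss = loss, grads = lapply(grads, unname))
}

# backprop through pooling, FFN(+residual), dropout, attention and the
# text projection for one protein; accumulates into `ga`
backward_fusion <- function(cache, dx_pro, align, ga) {
  L <- ncol(cache$A)
  dY <- matrix(dx_pro / L, length(dx_pro), L)

  # FFN with residual: Y = W2f %*% relu(W1f %*% A_d + b1f) + b2f + A_d
  dA_d <- dY
  dR1 <- crossprod(align$W2f, dY)
  ga$W2f <- ga$W2f + dY %*% t(cache$R1)
  ga$b2f <- ga$b2f + rowSums(dY)
  dZ1 <- dR1 * (cache$Z1 > 0)
  ga$W1f <- ga$W1f + dZ1 %*% t(cache$A_d)
  ga$b1f <- ga$b1f + rowSums(dZ1)
  dA_d <- dA_d + crossprod(align$W1f, dZ1)

  dA <- if (is.null(cache$drop_mask)) dA_d else
    dA_d * cache$drop_mask / (1 - align$dropout)

  # attention backward per fragment / head
  dX0 <- matrix(0, nrow(cache$X0), ncol(cache$X0))
  dh <- nrow(cache$X0) %/% align$n_heads
  s <- sqrt(dh)
  for (fr in cache$frags) {
    cols <- fr$cols
    X <- cache$X0[, cols, drop = FALSE]
    for (h in seq_along(fr$weights)) {
      rowsh <- ((h - 1L) * dh + 1L):(h * dh)
      Xh <- X[rowsh, , drop = FALSE]
      W <- fr$weights[[h]]
      dA_h <- dA[rowsh, cols, drop = FALSE]
      dXh <- dA_h %*% W
      dW <- crossprod(dA_h, Xh)
      dS <- (dW - rowSums(dW * W)) * W
      dXh <- dXh + Xh %*% (dS + t(dS)) / s
      dX0[rowsh, cols] <- dX0[rowsh, cols] + dXh
    }
  }

  # positional encoding is additive; text blocks feed the projection
  sizes <- cache$sizes
  offset <- sizes[1]
  txts <- cache$texts
  for (j in seq_along(txts)) {
    lj <- ncol(txts[[j]])
    colsj <- (offset + 1L):(offset + lj)
    ga$P <- ga$P + dX0[, colsj, drop = FALSE] %*% t(txts[[j]])
    offset <- offset + lj
  }
  ga
}

#' Predict GO-term scores for a cohort
#'
#' Runs the frozen fusion stack and head without dropout.
#'
#' @param object A [train_model()] fit.
#' @param ch A [cohort()] whose sequence archive matches the model's
#'   embedding width.
#' @param ... Unused.
#' @return An `n x gamma` score matrix in `(0, 1)` with protein / term
#'   dimnames.
#' @export
predict.gofusion_model <- function(object, ch, ...) {
  if (ch$seq_archive$dim != object$d) {
    abort("embedding width mismatch between model and cohort",
          class = "gofusion_shape_error")
  }
  use_text <- "text" %in% object$modules && !is.null(object$align)
  texts <- ch$text_archive$entries[
    intersect(object$label_space$graph$terms$id,
              names(ch$text_archive$entries))]
  n <- length(ch$protein_ids)
  proj <- if (use_text) lapply(texts, function(tx) object$align$P %*% tx)
  Xpro <- matrix(0, n, object$d)
  for (i in seq_len(n)) {
    Xpro[i, ] <- forward_protein(ch$seq_archive$entries[[i]], texts,
                                 object$align, use_text,
                                 training = FALSE, proj = proj)$x_pro
  }
  rows <- vapply(ch$taxonomy, function(s) species_row(object$tax, s),
                 integer(1))
  Xb <- Xpro + object$tax$w_tax * object$tax$table[rows, , drop = FALSE]
  scores <- head_forward(Xb, object$head, object$adjacency)
  dimnames(scores) <- list(ch$protein_ids, object$label_space$graph$terms$id)
  scores
}

#' Label matrix of a cohort under a fitted model's label space
#'
#' @param model A [train_model()] fit.
#' @param ch A [cohort()].
#' @param propagate See [build_label_matrix()].
#' @return Binary matrix aligned with [predict.gofusion_model()] output.
#' @export
model_labels <- function(model, ch, propagate = FALSE) {
  ann <- dplyr::filter(ch$annotations, .data$aspect == model$aspect)
  suppressWarnings(
    build_label_matrix(model$label_space, ann, ch$protein_ids,
                       propagate = propagate))
}
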