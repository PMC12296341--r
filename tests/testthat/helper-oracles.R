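# Independent straight-line oracles used to cross-check the vectorized
# implementations. These are deliberately written with explicit loops and
# no shared code with the package internals.

# parameter-free multi-head attention + position-wise FFN with residual,
# literal transcription: per head h over row slice, per output position i,
# softmax over j of (x_i . x_j)/sqrt(dh), then FFN(col) + col.
oracle_attention_ffn <- function(X, params) {
  d <- nrow(X)
  L <- ncol(X)
  nh <- params$n_heads
  dh <- d / nh
  A <- matrix(0, d, L)
  for (h in seq_len(nh)) {
    rows <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(L)) {
      e <- numeric(L)
      for (j in seq_len(L)) {
        e[j] <- sum(X[rows, i] * X[rows, j]) / sqrt(dh)
      }
      w <- exp(e - max(e))
      w <- w / sum(w)
      acc <- numeric(dh)
      for (j in seq_len(L)) acc <- acc + w[j] * X[rows, j]
      A[rows, i] <- acc
    }
  }
  Y <- matrix(0, d, L)
  for (i in seq_len(L)) {
    hcol <- params$W1f %*% A[, i] + params$b1f
    hcol[hcol < 0] <- 0
    Y[, i] <- params$W2f %*% hcol + params$b2f + A[, i]
  }
  Y
}

# literal per-element head forward: scores = sigmoid((relu(xW1+b1)W2+b2) A W_A)
oracle_head_forward <- function(X, params, Ahat) {
  b <- nrow(X)
  gamma <- ncol(params$W2)
  out <- matrix(0, b, gamma)
  for (r in seq_len(b)) {
    h1 <- as.vector(X[r, ] %*% params$W1) + params$b1
    h1[h1 < 0] <- 0
    h <- as.vector(h1 %*% params$W2) + params$b2
    z <- numeric(gamma)
    for (j in seq_len(gamma)) z[j] <- sum(h * Ahat[, j])
    lg <- numeric(gamma)
    for (j in seq_len(gamma)) lg[j] <- sum(z * params$W_A[, j])
    out[r, ] <- 1 / (1 + exp(-lg))
  }
  out
}

# exhaustive Fmax with explicit per-protein loops over the CAFA grid
oracle_fmax <- function(scores, labels) {
  taus <- seq(0.01, 1, by = 0.01)
  best <- 0
  best_tau <- taus[1]
  for (tau in taus) {
    precs <- c()
    recs <- c()
    for (i in seq_len(nrow(scores))) {
      pred <- which(scores[i, ] >= tau)
      truth <- which(labels[i, ] == 1)
      if (length(pred) > 0) {
        precs <- c(precs, length(intersect(pred, truth)) / length(pred))
      }
      if (length(truth) > 0) {
        recs <- c(recs, length(intersect(pred, truth)) / length(truth))
      }
    }
    pr <- if (length(precs)) mean(precs) else 0
    rc <- if (length(recs)) mean(recs) else 0
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    if (f > best + 1e-15) {
      best <- f
      best_tau <- tau
    }
  }
  list(fmax = best, tau = best_tau)
}

# per-position cosine relevance, literal transcription
oracle_relevance <- function(seq, text_projected) {
  K <- min(ncol(seq), ncol(text_projected))
  acc <- 0
  for (k in seq_len(K)) {
    a <- text_projected[, k]
    b <- seq[, k]
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    acc <- acc + if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  acc / K
}

# brute-force transitive closure over child->parent edges
oracle_reachable <- function(edges, ids) {
  reach <- matrix(FALSE, length(ids), length(ids),
                  dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    reach[edges$child[i], edges$parent[i]] <- TRUE
  }
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}
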