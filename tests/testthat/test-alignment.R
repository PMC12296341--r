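id_params <- function(d, d_prime = d, n_heads = 2, top_k = 5,
                      zero_ffn = TRUE) {
  p <- alignment_params(d, d_prime, n_heads = n_heads, top_k_texts = top_k,
                        dropout = 0, seed = 1)
  if (d == d_prime) p$P <- diag(d)
  if (zero_ffn) {
    p$W1f <- p$W1f * 0
    p$W2f <- p$W2f * 0
    p$b1f <- p$b1f * 0
    p$b2f <- p$b2f * 0
  }
  p
}

test_that("positional encoding matches the closed-form sinusoid table", {
  z <- matrix(0, 4, 2)
  pe <- positional_encode(z)
  # position 0: sin(0)=0 on even dims, cos(0)=1 on odd dims
  expect_equal(pe[, 1], c(0, 1, 0, 1))
  # position 1: angle is 1 for dims (0,1) and 1/100 for dims (2,3)
  expect_equal(pe[, 2], c(sin(1), cos(1), sin(0.01), cos(0.01)))

  # additivity: PE(x) - x is independent of x
  x <- matrix(rnorm(12), 4, 3)
  y <- matrix(rnorm(12), 4, 3)
  expect_equal(positional_encode(x) - x, positional_encode(y) - y)
})

test_that("relevance selection keeps positively aligned texts in order", {
  set.seed(1)
  p <- id_params(4)
  s <- matrix(rnorm(4 * 6), 4, 6)
  texts <- list(
    "GO:0000001" = s[, 1:3], # identical prefix: relevance exactly 1
    "GO:0000002" = -s[, 1:3], # antipodal: relevance exactly -1
    "GO:0000003" = matrix(rnorm(12), 4, 3)
  )
  sel <- relevance_select(s, texts, p)
  expect_true("GO:0000001" %in% sel$id)
  expect_false("GO:0000002" %in% sel$id)
  expect_equal(sel$relevance[sel$id == "GO:0000001"], 1)

  # against the literal per-position cosine oracle, including ordering
  rel_oracle <- vapply(texts, function(tx) oracle_relevance(s, p$P %*% tx),
                       numeric(1))
  keep <- rel_oracle[rel_oracle > 0]
  expect_equal(sel$id, names(sort(-keep)))
  expect_equal(sel$relevance, unname(sort(keep, decreasing = TRUE)))
})

test_that("hand-built 2x2 candidates reproduce oracle relevances", {
  p <- id_params(2)
  s <- matrix(c(1, 0, 0, 1), 2, 2)
  texts <- list(a = matrix(c(1, 1, 0, 1), 2, 2),
                b = matrix(c(0, 1, 1, 0), 2, 2),
                c = matrix(c(-1, 0, 0, -1), 2, 2))
  sel <- relevance_select(s, texts, p)
  # a: (cos45 + cos0)/2; b: (cos90 + cos90)/2 = 0 (excluded); c: -1
  expect_equal(sel$id, "a")
  expect_equal(sel$relevance, (cos(pi / 4) + 1) / 2)
})

test_that("zero-norm columns contribute cosine 0 instead of NaN", {
  p <- id_params(2)
  s <- cbind(c(0, 0), c(1, 0))
  texts <- list(a = cbind(c(1, 0), c(1, 0)))
  sel <- relevance_select(s, texts, p)
  expect_equal(sel$relevance, 0.5) # (0 + 1)/2
})

test_that("single- and two-position attention match closed forms", {
  p <- id_params(4, zero_ffn = FALSE)
  x <- matrix(rnorm(4), 4, 1)
  out <- fuse_features(x, list(), p, positional = FALSE, keep_cache = TRUE)
  # softmax over one item is 1: attention output is the input
  expect_equal(out$cache$frags[[1]]$weights[[1]], matrix(1, 1, 1))
  ffn <- p$W2f %*% pmax(p$W1f %*% x + p$b1f, 0) + p$b2f + x
  expect_equal(out$features, ffn)

  # two identical positions: every attention row is (1/2, 1/2)
  x2 <- cbind(x[, 1], x[, 1])
  out2 <- fuse_features(x2, list(), p, positional = FALSE,
                        keep_cache = TRUE)
  for (W in out2$cache$frags[[1]]$weights) {
    expect_equal(W, matrix(0.5, 2, 2))
  }
})

test_that("fusion matches the straight-line attention+FFN oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- alignment_params(8, 6, n_heads = 2, dropout = 0, seed = seed)
    x <- matrix(rnorm(48), 8, 6)
    got <- fuse_features(x, list(), p, positional = TRUE)
    want <- oracle_attention_ffn(positional_encode(x), p)
    expect_equal(got$features, want, tolerance = 1e-6)
  }
})

test_that("fusion with selected texts concatenates and masks positions", {
  set.seed(2)
  p <- alignment_params(8, 6, n_heads = 2, dropout = 0, seed = 2)
  x <- matrix(rnorm(32), 8, 4)
  texts <- list("GO:0000007" = matrix(rnorm(18), 6, 3))
  got <- fuse_features(x, texts, p)
  expect_equal(dim(got$features), c(8, 7))
  expect_equal(got$mask, c(rep("seq", 4), rep("GO:0000007", 3)))
  # the whole concatenation must equal the oracle on PE(seq) + PE(P text)
  X <- cbind(positional_encode(x), positional_encode(p$P %*% texts[[1]]))
  expect_equal(got$features, oracle_attention_ffn(X, p), tolerance = 1e-6)
})

test_that("attention rows sum to one across heads and fragments", {
  set.seed(3)
  p <- alignment_params(8, 6, n_heads = 4, fragment_length = 5,
                        dropout = 0, seed = 3)
  x <- matrix(rnorm(8 * 13), 8, 13)
  out <- fuse_features(x, list(), p, keep_cache = TRUE)
  expect_gt(length(out$cache$frags), 1) # really fragmented
  for (fr in out$cache$frags) {
    for (W in fr$weights) {
      expect_equal(unname(rowSums(W)), rep(1, nrow(W)), tolerance = 1e-6)
    }
  }
})

test_that("positional encoding breaks permutation equivariance; disabling restores it", {
  set.seed(4)
  p <- alignment_params(8, 6, n_heads = 2, dropout = 0, seed = 4)
  x <- matrix(rnorm(8 * 5), 8, 5)
  perm <- c(3, 1, 5, 2, 4)
  no_pe <- fuse_features(x, list(), p, positional = FALSE)$features
  no_pe_perm <- fuse_features(x[, perm], list(), p,
                              positional = FALSE)$features
  expect_equal(no_pe_perm, no_pe[, perm], tolerance = 1e-10)

  with_pe <- fuse_features(x, list(), p)$features
  with_pe_perm <- fuse_features(x[, perm], list(), p)$features
  expect_gt(max(abs(with_pe_perm - with_pe[, perm])), 1e-4)
})

test_that("a short sequence is unchanged by the fragment-size setting", {
  set.seed(5)
  x <- matrix(rnorm(8 * 40), 8, 40)
  p1 <- alignment_params(8, 6, n_heads = 2, fragment_length = 512,
                         dropout = 0, seed = 5)
  p2 <- p1
  p2$fragment_length <- 40L
  expect_identical(fuse_features(x, list(), p1)$features,
                   fuse_features(x, list(), p2)$features)
})

test_that("empty selections and bad inputs are handled", {
  p <- alignment_params(4, 4, n_heads = 2, dropout = 0, seed = 6)
  x <- matrix(rnorm(8), 4, 2)
  out <- fuse_features(x, list(), p)
  expect_equal(dim(out$features), dim(x))
  x[1, 1] <- NaN
  expect_error(fuse_features(x, list(), p),
               class = "gofusion_value_error")
  expect_error(alignment_params(6, 4, n_heads = 4),
               class = "gofusion_shape_error")
})
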