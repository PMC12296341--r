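test_that("all-zero parameters score 0.5 everywhere", {
  hp <- head_params(3, 4, seed = 1)
  for (k in names(hp)) hp[[k]] <- hp[[k]] * 0
  s <- head_forward(matrix(rnorm(6), 2, 3), hp, diag(4))
  expect_equal(unname(s), matrix(0.5, 2, 4))
})

test_that("scalar head matches the hand-computed sigmoid chain", {
  hp <- structure(list(W1 = matrix(0.5, 1, 2), b1 = c(0.1, -0.2),
                       W2 = matrix(c(1, -1), 2, 1), b2 = 0.3,
                       W_A = matrix(2, 1, 1)), class = "head_params")
  x <- 0.8
  h1 <- pmax(c(0.8 * 0.5 + 0.1, 0.8 * 0.5 - 0.2), 0) # (0.5, 0.2)
  h <- h1[1] * 1 + h1[2] * (-1) + 0.3 # 0.6
  expect_equal(as.vector(head_forward(x, hp, matrix(1, 1, 1))),
               1 / (1 + exp(-h * 2)))
})

test_that("batched forward matches the straight-line oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    hp <- head_params(4, 5, seed = seed)
    A <- normalized_adjacency(generate_dag(5, seed = seed))
    X <- matrix(rnorm(12), 3, 4)
    expect_equal(unname(head_forward(X, hp, unname(A))),
                 oracle_head_forward(X, hp, unname(A)), tolerance = 1e-6)
  }
})

test_that("identity adjacency and identity mixer reduce to the MLP", {
  hp <- head_params(4, 3, seed = 2)
  hp$W_A <- diag(3)
  X <- matrix(rnorm(8), 2, 4)
  H <- pmax(X %*% hp$W1 + rep(hp$b1, each = 2), 0) %*% hp$W2 +
    rep(hp$b2, each = 2)
  expect_equal(head_forward(X, hp, diag(3)), 1 / (1 + exp(-H)))
})

test_that("shape mismatches name the offending tensor", {
  hp <- head_params(4, 3, seed = 3)
  expect_error(head_forward(matrix(0, 2, 5), hp, diag(3)),
               regexp = "W1", class = "gofusion_shape_error")
  expect_error(head_forward(matrix(0, 2, 4), hp, diag(4)),
               class = "gofusion_shape_error")
})

test_that("the learning-rate schedule is the exact closed form", {
  cfg <- train_config()
  for (e in 1:30) {
    expect_equal(lr_at_epoch(cfg, e), 2e-4 * 0.6^((e - 1) %/% 5))
  }
  small <- train_config(variant = "small")
  expect_equal(lr_at_epoch(small, 1), 4e-5)
  expect_equal(lr_at_epoch(small, 6), 2e-5)
})

test_that("zero learning rate leaves parameters and loss untouched", {
  ch <- small_sim(n = 12, gamma = 4, seed = 13)
  ls <- prune_by_frequency(ch$graphs$BP, ch$annotations, 1)
  m <- train_model(ch, "BP", label_space = ls,
                   modules = c("taxonomy", "relation"),
                   config = train_config(lr = 0, epochs = 3, seed = 1))
  expect_equal(m$loss_trace, rep(m$loss_trace[1], 3), tolerance = 1e-12)
  fresh <- head_params(ch$seq_archive$dim, ls$gamma, seed = 1 + 3L)
  expect_equal(m$head$W1, fresh$W1)
  expect_equal(m$head$W_A, fresh$W_A)
})

test_that("a single protein-term pair can be memorized", {
  g <- toy_graph("GO:0000001", toy_edges(character(), character()))
  ann <- tibble::tibble(protein_id = "p1", go_id = "GO:0000001",
                        aspect = "BP")
  ch <- toy_cohort(list(p1 = matrix(rnorm(12), 4, 3)), ann, g)
  ls <- prune_by_frequency(g, ann, 1)
  m <- train_model(ch, "BP", label_space = ls, modules = character(),
                   config = train_config(lr = 0.05, epochs = 200,
                                         decay = 1, seed = 2))
  expect_gt(predict(m, ch)[1, 1], 0.9)
})

test_that("training is deterministic under a fixed seed", {
  ch <- small_sim(n = 20, gamma = 5, seed = 17)
  ls <- prune_by_frequency(ch$graphs$BP, ch$annotations, 1)
  cfg <- train_config(epochs = 3, seed = 5)
  m1 <- train_model(ch, "BP", label_space = ls, config = cfg)
  m2 <- train_model(ch, "BP", label_space = ls, config = cfg)
  expect_equal(m1$loss_trace, m2$loss_trace, tolerance = 1e-6)
  expect_equal(predict(m1, ch), predict(m2, ch), tolerance = 1e-6)
  m3 <- train_model(ch, "BP", label_space = ls,
                    config = train_config(epochs = 3, seed = 6))
  expect_false(isTRUE(all.equal(m1$loss_trace, m3$loss_trace)))
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(31)
  d <- 4
  gamma <- 3
  ids <- paste0("p", 1:3)
  g <- generate_dag(gamma, seed = 31)
  seqs <- setNames(lapply(1:3, function(i) matrix(rnorm(d * 5), d, 5)),
                   ids)
  # texts copied from sequence prefixes so selection is stably positive
  texts <- setNames(lapply(1:gamma, function(j) {
    seqs[[(j %% 3) + 1]][1:3, 1:4] + 0.05
  }), g$terms$id)
  ann <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
                        go_id = g$terms$id, aspect = "BP")
  ch <- toy_cohort(seqs, ann, g, text_entries = texts,
                   taxonomy = setNames(c(1L, 2L, 1L), ids))
  ls <- prune_by_frequency(g, ann, 0)
  Y <- build_label_matrix(ls, ann, ids)

  align <- alignment_params(d, 3, n_heads = 2, dropout = 0, seed = 1)
  tax <- taxonomy_encoder(2, d, w_tax = 0.1, seed = 2)
  headp <- head_params(d, gamma, seed = 3)
  Ahat <- ls$adjacency_hat
  rows <- c(2L, 3L, 2L)

  loss_of <- function(params) {
    a2 <- gofusion:::assign_params(params, align, tax, headp, TRUE)
    gofusion:::train_batch(ch, 1:3, Y, a2$align, a2$tax, a2$headp, Ahat,
                           TRUE, texts, rows,
                           params)$loss
  }
  params <- gofusion:::collect_params(align, tax, headp, TRUE, TRUE)
  grads <- gofusion:::train_batch(ch, 1:3, Y, align, tax, headp, Ahat,
                                  TRUE, texts, rows, params)$grads

  h <- 1e-5
  for (k in names(params)) {
    picks <- withr::with_seed(nchar(k),
      sample(length(params[[k]]), min(4, length(params[[k]]))))
    for (ix in picks) {
      pp <- params
      pp[[k]][ix] <- pp[[k]][ix] + h
      up <- loss_of(pp)
      pp[[k]][ix] <- pp[[k]][ix] - 2 * h
      dn <- loss_of(pp)
      num <- (up - dn) / (2 * h)
      expect_equal(grads[[k]][ix], num, tolerance = 1e-4,
                   label = paste("grad", k, ix))
    }
  }
})
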