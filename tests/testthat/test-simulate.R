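test_that("generated DAGs are rooted, acyclic and seed-deterministic", {
  g1 <- generate_dag(1, seed = 0)
  expect_equal(nrow(g1$terms), 1)
  expect_equal(nrow(g1$edges), 0)

  g <- generate_dag(10, seed = 42)
  g2 <- generate_dag(10, seed = 42)
  expect_identical(g, g2)
  expect_false(identical(g, generate_dag(10, seed = 43)))

  # every non-root has 1-2 parents drawn from earlier ids: topological by id
  expect_true(all(g$edges$parent < g$edges$child))
  npar <- table(g$edges$child)
  expect_true(all(npar >= 1 & npar <= 2))
})

test_that("generated labels respect the true-path rule", {
  ch <- small_sim(n = 25, gamma = 15, seed = 2)
  g <- ch$graphs$BP
  Y <- ch$labels$BP
  reach <- oracle_reachable(g$edges, g$terms$id)
  for (i in seq_len(nrow(Y))) {
    pos <- colnames(Y)[Y[i, ] == 1]
    for (term in pos) {
      expect_true(all(Y[i, colnames(Y) %in%
                           colnames(Y)[reach[term, ]]] == 1))
    }
  }
})

test_that("cohorts are bit-identical under a fixed seed and differ across seeds", {
  c1 <- small_sim(n = 15, gamma = 5, seed = 3)
  c2 <- small_sim(n = 15, gamma = 5, seed = 3)
  expect_identical(c1$seq_archive$entries, c2$seq_archive$entries)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$annotations, c2$annotations)
  c3 <- small_sim(n = 15, gamma = 5, seed = 4)
  expect_false(identical(c1$seq_archive$entries, c3$seq_archive$entries))
})

test_that("zero signal strength decouples mean embeddings from labels", {
  ch <- generate_cohort(sim_config(n_proteins = 300, gamma_per_aspect = 8,
                                   d = 8, d_prime = 6, aspects = "BP",
                                   signal_strength = 0, seed = 9))
  M <- t(vapply(ch$seq_archive$entries, rowMeans, numeric(8)))
  Y <- ch$labels$BP
  keep <- colSums(Y) > 0 & colSums(Y) < nrow(Y)
  expect_gt(sum(keep), 0)
  cors <- abs(stats::cor(M, Y[, keep, drop = FALSE]))
  expect_lt(max(cors), 0.25) # Monte-Carlo bound, ~3.5 sd at n = 300
})

test_that("a linear probe recovers strong planted signal (regression bound)", {
  ch <- generate_cohort(sim_config(n_proteins = 400, gamma_per_aspect = 20,
                                   d = 32, d_prime = 24, aspects = "BP",
                                   signal_strength = 5, noise_sd = 1,
                                   seed = 0))
  ls <- prune_by_frequency(ch$graphs$BP, ch$annotations, 1)
  sp <- split_cohort(ch, 0.15, 0, label_space = ls)
  probe <- train_model(sp$train, "BP", label_space = ls,
                       modules = character(),
                       config = train_config(seed = 0))
  ev <- evaluate_model(probe, sp$test)
  expect_gt(ev$aupr, 0.9)
})

test_that("written cohorts read back equivalently", {
  ch <- small_sim(n = 10, gamma = 4, seed = 6)
  dir <- tempfile()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_identical(back$seq_archive$entries, ch$seq_archive$entries)
  expect_identical(back$text_archive$entries, ch$text_archive$entries)
  expect_equal(back$taxonomy, ch$taxonomy)
  expect_equal(back$annotations, ch$annotations)
  expect_equal(back$ontology$terms$id, ch$ontology$terms$id)
  expect_equal(nrow(back$ontology$edges), nrow(ch$ontology$edges))
})
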