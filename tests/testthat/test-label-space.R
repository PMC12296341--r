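ann_tbl <- function(counts) {
  # counts: named vector term -> annotation count; proteins synthetic
  tibble::tibble(
    protein_id = unlist(lapply(seq_along(counts), function(i) {
      sprintf("P%s_%d", names(counts)[i], seq_len(counts[i]))
    })),
    go_id = rep(names(counts), counts),
    aspect = "BP"
  )
}

test_that("threshold 0 retains everything unchanged", {
  g <- generate_dag(8, seed = 3)
  ann <- ann_tbl(setNames(c(3, 1, 0, 2, 5, 1, 1, 4), g$terms$id))
  ls <- prune_by_frequency(g, ann, 0)
  expect_equal(ls$gamma, 8)
  expect_equal(ls$graph$edges, g$edges)
  expect_equal(unname(ls$frequencies[g$terms$id]), c(3, 1, 0, 2, 5, 1, 1, 4))
})

test_that("counting prunes exactly the below-threshold terms", {
  g <- toy_graph(c("GO:0000001", "GO:0000002", "GO:0000003"),
                 toy_edges(c("GO:0000002", "GO:0000003"),
                           c("GO:0000001", "GO:0000002")))
  ann <- ann_tbl(c("GO:0000001" = 5, "GO:0000002" = 2, "GO:0000003" = 1))
  ls <- prune_by_frequency(g, ann, 2)
  expect_equal(ls$graph$terms$id, c("GO:0000001", "GO:0000002"))
  expect_error(prune_by_frequency(g, ann, 100),
               class = "gofusion_prune_error")
})

test_that("contracting a pruned middle node reconnects parent to child", {
  # chain c -> b -> a; prune b: c must attach to a
  g <- toy_graph(c("GO:0000001", "GO:0000002", "GO:0000003"),
                 toy_edges(c("GO:0000003", "GO:0000002"),
                           c("GO:0000002", "GO:0000001")))
  ann <- ann_tbl(c("GO:0000001" = 5, "GO:0000002" = 1, "GO:0000003" = 5))
  ls <- prune_by_frequency(g, ann, 2)
  expect_equal(ls$graph$terms$id, c("GO:0000001", "GO:0000003"))
  expect_equal(nrow(ls$graph$edges), 1)
  expect_equal(ls$graph$edges$child, "GO:0000003")
  expect_equal(ls$graph$edges$parent, "GO:0000001")
})

test_that("pruning is monotone and reconnection preserves reachability", {
  for (seed in 1:8) {
    gamma <- 5 + (seed * 3) %% 26 # up to 30 nodes
    g <- generate_dag(gamma, seed = 100 + seed)
    counts <- withr::with_seed(seed, rpois(gamma, 3))
    ann <- ann_tbl(setNames(counts, g$terms$id))
    full_reach <- oracle_reachable(g$edges, g$terms$id)

    prev_gamma <- Inf
    for (th in 0:4) {
      ls <- tryCatch(prune_by_frequency(g, ann, th),
                     gofusion_prune_error = function(e) NULL)
      if (is.null(ls)) break
      expect_lte(ls$gamma, prev_gamma)
      prev_gamma <- ls$gamma
      expect_true(all(
        ls$frequencies[ls$graph$terms$id] >= th))

      pruned_reach <- oracle_reachable(ls$graph$edges, ls$graph$terms$id)
      kept <- ls$graph$terms$id
      expect_identical(pruned_reach[kept, kept],
                       full_reach[kept, kept])
    }
  }
})

test_that("label matrix transcribes, propagates, and matches frequencies", {
  g <- toy_graph(c("GO:0000001", "GO:0000002", "GO:0000003"),
                 toy_edges(c("GO:0000002", "GO:0000003"),
                           c("GO:0000001", "GO:0000002")))
  ann <- tibble::tibble(
    protein_id = c("p1", "p1", "p2"),
    go_id = c("GO:0000001", "GO:0000003", "GO:0000002"),
    aspect = "BP")
  ls <- prune_by_frequency(g, ann, 0)

  Y <- build_label_matrix(ls, ann, c("p1", "p2"))
  expect_equal(unname(Y), rbind(c(1L, 0L, 1L), c(0L, 1L, 0L)))

  # propagation: leaf positive implies all ancestors positive
  Yp <- build_label_matrix(ls, ann, c("p1", "p2"), propagate = TRUE)
  expect_equal(unname(Yp), rbind(c(1L, 1L, 1L), c(1L, 1L, 0L)))

  # empty table: all-zero matrix plus a warning about uncovered proteins
  expect_warning(
    Y0 <- build_label_matrix(ls, ann[0, ], c("p1", "p2")),
    "no retained annotations")
  expect_true(all(Y0 == 0L))

  # column sums equal post-pruning frequencies when propagation is off
  expect_equal(unname(colSums(Y)),
               unname(ls$frequencies[ls$graph$terms$id]))
})

test_that("propagated labels match a reachability oracle on a random DAG", {
  g <- generate_dag(12, seed = 5)
  ids <- g$terms$id
  ann <- tibble::tibble(protein_id = "p1", go_id = ids[12], aspect = "BP")
  ls <- prune_by_frequency(g, ann, 0)
  Y <- build_label_matrix(ls, ann, "p1", propagate = TRUE)
  reach <- oracle_reachable(g$edges, ids)
  expected <- as.integer(ids %in% c(ids[12], ids[reach[ids[12], ]]))
  expect_equal(unname(Y[1, ]), expected)
})

test_that("auto threshold reproduces the cohort-scale rule", {
  expect_equal(auto_threshold(142246), 21L)
  expect_equal(auto_threshold(100), 1L)
})
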