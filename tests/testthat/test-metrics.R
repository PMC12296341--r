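rand_instance <- function(seed, n = 6, gamma = 5, p = 0.3) {
  withr::with_seed(seed, list(
    scores = matrix(runif(n * gamma), n, gamma),
    labels = matrix(rbinom(n * gamma, 1, p), n, gamma)
  ))
}

test_that("perfect and degenerate predictors hit the metric extremes", {
  Y <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3)
  perfect <- fmax(Y, Y)
  expect_equal(perfect$fmax, 1)
  expect_equal(example_f1(Y, Y), 1)
  expect_equal(micro_aupr(Y, Y), 1)
  expect_equal(micro_mcc(Y, Y), 1)
  # every swept threshold achieves F = 1 for the perfect predictor
  expect_true(all(perfect$curve$f == 1))

  zeros <- matrix(0, 2, 3)
  expect_equal(fmax(zeros, Y)$fmax, 0)

  expect_error(fmax(Y, zeros), class = "gofusion_value_error")
  expect_error(micro_aupr(Y, zeros), class = "gofusion_value_error")
})

test_that("a balanced uninformative 2x2 case has zero MCC", {
  labels <- rbind(c(1, 0), c(1, 0))
  scores <- rbind(c(0.9, 0.9), c(0.1, 0.1)) # flips balance out
  expect_equal(micro_mcc(scores, labels), 0)
})

test_that("Fmax equals the exhaustive grid oracle on random instances", {
  for (seed in 1:25) {
    inst <- rand_instance(seed)
    if (all(rowSums(inst$labels) == 0)) next
    got <- fmax(inst$scores, inst$labels)
    want <- oracle_fmax(inst$scores, inst$labels)
    expect_equal(got$fmax, want$fmax, tolerance = 1e-12)
    expect_equal(got$tau, want$tau)
  }
})

test_that("scalar metrics match independently arranged formulas", {
  for (seed in 1:10) {
    inst <- rand_instance(seed, n = 5, gamma = 6)
    if (all(inst$labels == 0)) next
    s <- inst$scores
    y <- inst$labels

    # example F1 via per-protein precision/recall harmonic mean
    f1s <- vapply(seq_len(nrow(s)), function(i) {
      pred <- which(s[i, ] >= 0.5)
      truth <- which(y[i, ] == 1)
      if (!length(pred) && !length(truth)) return(1)
      tp <- length(intersect(pred, truth))
      pr <- if (length(pred)) tp / length(pred) else 0
      rc <- if (length(truth)) tp / length(truth) else 0
      if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    }, numeric(1))
    expect_equal(example_f1(s, y), mean(f1s))

    # micro AUPR via mean precision-at-rank over positives
    # (equivalent for continuous, tie-free scores)
    sv <- as.vector(s)
    yv <- as.vector(y)
    ord <- order(sv, decreasing = TRUE)
    yo <- yv[ord]
    ap <- mean((cumsum(yo) / seq_along(yo))[yo == 1])
    expect_equal(micro_aupr(s, y), ap, tolerance = 1e-12)

    # micro MCC as the Pearson phi of the binarized vectors
    pv <- as.numeric(sv >= 0.5)
    phi <- suppressWarnings(stats::cor(pv, yv))
    if (!is.na(phi)) expect_equal(micro_mcc(s, y), phi, tolerance = 1e-12)
  }
})

test_that("a random scorer's micro AUPR approaches the positive rate", {
  inst <- rand_instance(99, n = 120, gamma = 12, p = 0.25)
  expect_equal(micro_aupr(inst$scores, inst$labels),
               mean(inst$labels), tolerance = 0.05)
})

test_that("Fmax is invariant to grid-preserving transforms and row order", {
  inst <- rand_instance(3, n = 8, gamma = 6)
  s <- round(inst$scores, 1) # scores sit on grid points
  y <- inst$labels
  base <- fmax(s, y)$fmax
  expect_equal(fmax(s + 0.004, y)$fmax, base) # same induced binarizations
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  expect_equal(fmax(s[perm, ], y[perm, ])$fmax, base)
})

test_that("reports aggregate all metrics with tidy accessors", {
  inst <- rand_instance(12, n = 10, gamma = 5)
  ev <- evaluate_scores(inst$scores, inst$labels)
  expect_s3_class(ev, "gofusion_eval")
  expect_true(ev$fmax >= max(0, ev$curve$f[50]))
  expect_equal(nrow(tidy(ev)), 100)
  gl <- glance(ev)
  expect_equal(gl$fmax, ev$fmax)
  expect_equal(gl$n, 10)

  f <- tempfile()
  write_eval_report(ev, f)
  back <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(back$aupr, ev$aupr)
  expect_s3_class(autoplot(ev), "ggplot")
})
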