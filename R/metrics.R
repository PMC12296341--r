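tau_grid <- function() seq(0.01, 1, by = 0.01)

check_scores_labels <- function(scores, labels) {
  if (!all(dim(scores) == dim(labels))) {
    abort("scores and labels have different shapes",
          class = "gofusion_shape_error")
  }
  if (!all(labels %in% c(0, 1))) {
    abort("labels must be binary", class = "gofusion_value_error")
  }
}

#' Protein-centric Fmax
#'
#' Sweeps the decision threshold over `0.01, 0.02, ..., 1.00` (CAFA
#' convention). At each threshold, precision is averaged over proteins with
#' at least one predicted positive and recall over all proteins with at
#' least one true positive; Fmax is the maximum harmonic mean, taken as 0
#' where precision and recall are both 0, with threshold ties broken toward
#' the smaller threshold.
#'
#' @param scores `n x gamma` score matrix.
#' @param labels Binary matrix of the same shape.
#' @return List with `fmax`, `tau` (the argmax threshold) and the
#'   per-threshold `curve` tibble.
#' @export
fmax <- function(scores, labels) {
  check_scores_labels(scores, labels)
  truecnt <- rowSums(labels)
  if (all(truecnt == 0)) {
    abort("no protein has a true label; recall undefined",
          class = "gofusion_value_error")
  }
  has_truth <- truecnt > 0
  taus <- tau_grid()
  prec <- numeric(length(taus))
  rec <- numeric(length(taus))
  f <- numeric(length(taus))
  for (t in seq_along(taus)) {
    P <- scores >= taus[t]
    tp <- rowSums(P & (labels == 1))
    predcnt <- rowSums(P)
    predicting <- predcnt > 0
    pr <- if (any(predicting)) {
      mean(tp[predicting] / predcnt[predicting])
    } else 0
    rc <- mean(tp[has_truth] / truecnt[has_truth])
    prec[t] <- pr
    rec[t] <- rc
    f[t] <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  }
  best <- which.max(f) # first max -> smallest tau
  list(fmax = f[best], tau = taus[best],
       curve = tibble::tibble(tau = taus, precision = prec, recall = rec,
                              f = f))
}

#' Example-based F1
#'
#' Mean over proteins of the per-protein F1 at threshold `tau`. A protein
#' with an empty prediction *and* empty truth contributes F1 = 1
#' (configurable via `empty_value`).
#'
#' @param scores,labels As in [fmax()].
#' @param tau Operating threshold (default 0.5).
#' @param empty_value F1 assigned to empty-vs-empty proteins.
#' @return Scalar in `[0, 1]`.
#' @export
example_f1 <- function(scores, labels, tau = 0.5, empty_value = 1) {
  check_scores_labels(scores, labels)
  P <- scores >= tau
  tp <- rowSums(P & (labels == 1))
  fp <- rowSums(P & (labels == 0))
  fn <- rowSums(!P & (labels == 1))
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom > 0, 2 * tp / denom, empty_value)
  mean(f1)
}

#' Micro-averaged area under the precision-recall curve
#'
#' Pools all protein-term pairs, sorts by score and integrates the
#' step-wise precision over recall increments (no trapezoid interpolation),
#' grouping tied scores.
#'
#' @param scores,labels As in [fmax()].
#' @return Scalar in `[0, 1]`.
#' @export
micro_aupr <- function(scores, labels) {
  check_scores_labels(scores, labels)
  s <- as.vector(scores)
  y <- as.vector(labels)
  npos <- sum(y)
  if (npos == 0) {
    abort("no positive labels; AUPR undefined",
          class = "gofusion_value_error")
  }
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]
  s <- s[ord]
  cum_tp <- cumsum(y)
  k <- seq_along(y)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  prec <- (cum_tp / k)[last_of_group]
  rec <- (cum_tp / npos)[last_of_group]
  sum(diff(c(0, rec)) * prec)
}

#' Micro-averaged Matthews correlation coefficient
#'
#' Computed over the flattened binary confusion matrix at threshold `tau`;
#' 0 when any confusion marginal is zero.
#'
#' @param scores,labels As in [fmax()].
#' @param tau Operating threshold (default 0.5).
#' @return Scalar in `[-1, 1]`.
#' @export
micro_mcc <- function(scores, labels, tau = 0.5) {
  check_scores_labels(scores, labels)
  p <- as.vector(scores) >= tau
  y <- as.vector(labels) == 1
  tp <- sum(p & y)
  fp <- sum(p & !y)
  fn <- sum(!p & y)
  tn <- sum(!p & !y)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Full evaluation report
#'
#' Bundles the threshold sweep with the scalar metrics: Fmax with its
#' argmax threshold, example-based F1 and micro MCC at 0.5, and micro
#' AUPR.
#'
#' @param scores,labels As in [fmax()].
#' @return A `gofusion_eval` object; see also [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @export
evaluate_scores <- function(scores, labels) {
  fm <- fmax(scores, labels)
  structure(list(
    curve = fm$curve,
    fmax = fm$fmax,
    tau = fm$tau,
    f1 = example_f1(scores, labels),
    aupr = micro_aupr(scores, labels),
    mcc = micro_mcc(scores, labels),
    n = nrow(scores),
    gamma = ncol(scores)
  ), class = "gofusion_eval")
}

#' @export
print.gofusion_eval <- function(x, ...) {
  cat("<gofusion_eval> n=", x$n, ", gamma=", x$gamma,
      " | Fmax=", signif(x$fmax, 4), " (tau=", x$tau, ")",
      ", F1@0.5=", signif(x$f1, 4),
      ", AUPR=", signif(x$aupr, 4),
      ", MCC@0.5=", signif(x$mcc, 4), "\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted model on a cohort
#'
#' @param model A [train_model()] fit.
#' @param ch A [cohort()].
#' @param propagate Propagate test annotations to ancestors.
#' @return A [evaluate_scores()] report.
#' @export
evaluate_model <- function(model, ch, propagate = FALSE) {
  scores <- predict(model, ch)
  labels <- model_labels(model, ch, propagate = propagate)
  evaluate_scores(scores, labels)
}

#' Serialize an evaluation report
#'
#' Writes the scalar metrics as JSON and the threshold sweep as TSV.
#'
#' @param report A `gofusion_eval`.
#' @param path Basename; writes `<path>.json` and `<path>.tsv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(fmax = report$fmax, tau = report$tau, f1 = report$f1,
         aupr = report$aupr, mcc = report$mcc, n = report$n,
         gamma = report$gamma),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write.table(report$curve, paste0(path, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
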