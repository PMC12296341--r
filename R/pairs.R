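#' Pair-similarity selection and interaction matching rate
#'
#' Cross-checks GO predictions against an external protein-protein
#' interaction confidence table: proteins predicted with high per-protein
#' precision are paired when their positive predicted term sets are
#' similar, and each pair is looked up in the confidence table (a local
#' copy of STRING-style scores in `[0, 99.9]`, where a score of 70 or more
#' indicates an interaction).
#'
#' @param scores,labels As in [fmax()].
#' @param confidence Tibble with columns `protein_a`, `protein_b`, `score`
#'   (unordered pairs).
#' @param precision_floor Keep proteins whose per-protein precision at
#'   `tau` is at least this value (default 0.75).
#' @param similarity_floor Jaccard similarity floor on positive predicted
#'   term sets (default 0.70).
#' @param match_cutoff Confidence score at or above which a pair counts as
#'   matched (default 70).
#' @param tau Operating threshold for predictions (default 0.5).
#' @return List with `n_selected`, `n_matched`, `rate` (`NA` when no pair
#'   is selected) and the `pairs` tibble.
#' @export
pair_matching_rate <- function(scores, labels, confidence,
                               precision_floor = 0.75,
                               similarity_floor = 0.70,
                               match_cutoff = 70, tau = 0.5) {
  check_scores_labels(scores, labels)
  P <- scores >= tau
  tp <- rowSums(P & (labels == 1))
  predcnt <- rowSums(P)
  prec <- ifelse(predcnt > 0, tp / predcnt, 0)
  keep <- which(prec >= precision_floor & predcnt > 0)

  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  conf <- setNames(confidence$score,
                   key(confidence$protein_a, confidence$protein_b))

  pairs <- list()
  ids <- rownames(scores) %||% as.character(seq_len(nrow(scores)))
  if (length(keep) >= 2) {
    sets <- lapply(keep, function(i) which(P[i, ]))
    for (a in seq_along(keep)[-length(keep)]) {
      for (b in (a + 1):length(keep)) {
        inter <- length(intersect(sets[[a]], sets[[b]]))
        uni <- length(union(sets[[a]], sets[[b]]))
        sim <- if (uni > 0) inter / uni else 0
        if (sim >= similarity_floor) {
          ia <- ids[keep[a]]
          ib <- ids[keep[b]]
          sc <- conf[key(ia, ib)]
          pairs[[length(pairs) + 1L]] <- tibble::tibble(
            protein_a = ia, protein_b = ib, similarity = sim,
            confidence = if (is.na(sc)) NA_real_ else unname(sc))
        }
      }
    }
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(protein_a = character(), protein_b = character(),
                   similarity = numeric(), confidence = numeric())
  n_sel <- nrow(pairs)
  n_match <- sum(!is.na(pairs$confidence) &
                   pairs$confidence >= match_cutoff)
  list(n_selected = n_sel, n_matched = n_match,
       rate = if (n_sel > 0) n_match / n_sel else NA_real_,
       pairs = pairs)
}

#' Aggregate per-aspect pair-matching counts
#'
#' Combines per-aspect selected/matched pair counts into the overall
#' matching rate, e.g. for published per-aspect tallies.
#'
#' @param counts Tibble with columns `aspect`, `pairs_selected`,
#'   `pairs_matched`.
#' @return One-row tibble with `pairs_selected`, `pairs_matched` and
#'   `rate_pct`.
#' @export
pair_match_summary <- function(counts) {
  stopifnot(all(c("pairs_selected", "pairs_matched") %in% names(counts)))
  sel <- sum(counts$pairs_selected)
  mat <- sum(counts$pairs_matched)
  tibble::tibble(
    pairs_selected = sel,
    pairs_matched = mat,
    rate_pct = 100 * mat / sel
  )
}
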