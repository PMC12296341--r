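#' Pruning-frequency sweep
#'
#' For each threshold: rebuild the label space, retrain the head on the
#' train split and report Fmax on the test split. The retained-term column
#' is exact and deterministic; thresholds that empty the label space are
#' recorded as invalid rows and the sweep continues.
#'
#' @param ch A [cohort()].
#' @param thresholds Ascending integer thresholds.
#' @param aspect Aspect to sweep.
#' @param config [train_config()].
#' @param modules Module switches passed to [train_model()].
#' @param test_fraction,seed Split parameters (see [split_cohort()]).
#' @return Tibble with one row per threshold: `threshold`,
#'   `gamma_retained`, `fmax`, `valid`.
#' @export
frequency_sweep <- function(ch, thresholds, aspect = "BP",
                            config = train_config(),
                            modules = c("taxonomy", "relation"),
                            test_fraction = 0.1, seed = 0) {
  stopifnot(!is.unsorted(thresholds))
  graph <- split_subontology(ch$ontology$terms, ch$ontology$edges, aspect)
  ann <- dplyr::filter(ch$annotations, .data$aspect == !!aspect)
  rows <- lapply(thresholds, function(th) {
    ls <- tryCatch(prune_by_frequency(graph, ann, th),
                   gofusion_prune_error = function(e) NULL)
    if (is.null(ls)) {
      return(tibble::tibble(threshold = th, gamma_retained = 0L,
                            fmax = NA_real_, valid = FALSE))
    }
    splits <- split_cohort(ch, test_fraction, seed, label_space = ls)
    model <- train_model(splits$train, aspect, label_space = ls,
                         modules = modules, config = config)
    ev <- evaluate_model(model, splits$test)
    tibble::tibble(threshold = th, gamma_retained = ls$gamma,
                   fmax = ev$fmax, valid = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Module ablation sweep
#'
#' Trains and evaluates every subset of the three module switches (8
#' variants) under identical data and seeds.
#'
#' @param train_ch,test_ch Train and test [cohort()]s.
#' @param aspect Aspect.
#' @param label_space Shared [prune_by_frequency()] label space.
#' @param config [train_config()].
#' @param variants Optional list of module-switch character vectors;
#'   defaults to all 8 subsets.
#' @return Tibble with `variant`, `modules` (list-column), `fmax`, `f1`,
#'   `aupr`, `mcc`.
#' @export
ablation_sweep <- function(train_ch, test_ch, aspect = "BP",
                           label_space = NULL, config = train_config(),
                           variants = NULL) {
  if (is.null(variants)) {
    switches <- c("text", "taxonomy", "relation")
    variants <- unlist(lapply(0:3, function(k) {
      utils::combn(switches, k, simplify = FALSE)
    }), recursive = FALSE)
  }
  rows <- lapply(variants, function(mods) {
    model <- train_model(train_ch, aspect, label_space = label_space,
                         modules = mods, config = config)
    ev <- evaluate_model(model, test_ch)
    tibble::tibble(
      variant = if (length(mods)) paste(sort(mods), collapse = "+") else
        "none",
      modules = list(mods),
      fmax = ev$fmax, f1 = ev$f1, aupr = ev$aupr, mcc = ev$mcc
    )
  })
  dplyr::bind_rows(rows)
}
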