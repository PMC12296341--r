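#' Load a bundled benchmark fixture table
#'
#' The package ships small CSV transcriptions of published CAFA5 benchmark
#' summaries for protein-language-model-based GO predictors: `"fmax"` and
#' `"f1"` (per-model, per-aspect scores in percent, with and without
#' multi-modal enhancement), `"ppi_counts"` (per-aspect selected/matched
#' interaction pair counts) and `"pruning_counts"` (per-aspect total and
#' pruned GO term counts at the default frequency threshold), plus
#' `"dataset_stats"` (cohort-level constants).
#'
#' @param name One of `"fmax"`, `"f1"`, `"ppi_counts"`,
#'   `"pruning_counts"`, `"dataset_stats"`.
#' @return A tibble.
#' @export
benchmark_table <- function(name = c("fmax", "f1", "ppi_counts",
                                     "pruning_counts", "dataset_stats")) {
  name <- match.arg(name)
  file <- c(fmax = "cafa5_benchmark_fmax.csv",
            f1 = "cafa5_benchmark_f1.csv",
            ppi_counts = "cafa5_ppi_match_counts.csv",
            pruning_counts = "cafa5_go_pruning_counts.csv",
            dataset_stats = "cafa5_dataset_stats.csv")[[name]]
  path <- system.file("extdata", file, package = "gofusion")
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Mean paired improvement across a benchmark table
#'
#' Mean over all (model, aspect) cells of `enhanced - base`. Errors on
#' unpaired cells.
#'
#' @param table Tibble with columns `model`, `aspect`, `base`, `enhanced`.
#' @return One-row tibble with `n_cells` and `mean_improvement`.
#' @export
improvement_summary <- function(table) {
  need <- c("model", "aspect", "base", "enhanced")
  if (!all(need %in% names(table))) {
    abort("table needs columns model, aspect, base, enhanced",
          class = "gofusion_value_error")
  }
  bad <- is.na(table$base) | is.na(table$enhanced)
  if (any(bad)) {
    abort(paste0("unpaired cell: ", table$model[bad][1], "/",
                 table$aspect[bad][1]),
          class = "gofusion_value_error")
  }
  tibble::tibble(
    n_cells = nrow(table),
    mean_improvement = mean(table$enhanced - table$base)
  )
}

#' Retained-term fraction after frequency pruning
#'
#' @param counts Tibble with columns `aspect`, `total_terms`,
#'   `pruned_terms`.
#' @return One-row tibble with `total`, `retained` and `retained_pct`.
#' @export
retained_fraction <- function(counts) {
  stopifnot(all(c("total_terms", "pruned_terms") %in% names(counts)))
  total <- sum(counts$total_terms)
  retained <- total - sum(counts$pruned_terms)
  tibble::tibble(total = total, retained = retained,
                 retained_pct = 100 * retained / total)
}
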