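#' Pipeline run configuration
#'
#' Bundles paths, switches and sub-configurations for the orchestrated
#' commands ([run_simulate()], [run_train()], [run_evaluate()]). All
#' artifacts written by a run embed the configuration digest.
#'
#' @param cohort_dir Directory with the on-disk cohort (see
#'   [write_cohort()]).
#' @param out_dir Output directory for checkpoints and reports.
#' @param aspect Aspect to model.
#' @param modules Module switches.
#' @param threshold Pruning threshold (`NULL` = automatic from cohort
#'   size).
#' @param propagate Propagate annotations to ancestors.
#' @param test_fraction,seed Split control.
#' @param train [train_config()].
#' @param sim [sim_config()] (used by [run_simulate()]).
#' @return A `run_config` list with a `digest` field.
#' @export
run_config <- function(cohort_dir, out_dir, aspect = "BP",
                       modules = c("text", "taxonomy", "relation"),
                       threshold = NULL, propagate = FALSE,
                       test_fraction = 0.1, seed = 0,
                       train = train_config(seed = seed),
                       sim = sim_config(seed = seed)) {
  cfg <- list(cohort_dir = cohort_dir, out_dir = out_dir, aspect = aspect,
              modules = validate_modules(modules), threshold = threshold,
              propagate = propagate, test_fraction = test_fraction,
              seed = seed, train = unclass(train), sim = unclass(sim))
  cfg$digest <- digest_string(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                               null = "null"))
  structure(cfg, class = "run_config")
}

#' Simulate a cohort to disk
#'
#' @param config A [run_config()].
#' @return The cohort directory, invisibly.
#' @export
run_simulate <- function(config) {
  ch <- generate_cohort(structure(config$sim, class = "sim_config"))
  write_cohort(ch, config$cohort_dir)
  log_stage(config, "simulate", paste0("n=", config$sim$n_proteins))
  invisible(config$cohort_dir)
}

validate_run_inputs <- function(config) {
  need <- file.path(config$cohort_dir,
                    c("ontology.obo", "annotations.tsv",
                      "seq_embeddings.bin", "seq_embeddings.bin.json"))
  if ("text" %in% config$modules) {
    need <- c(need, file.path(config$cohort_dir,
                              c("text_embeddings.bin",
                                "text_embeddings.bin.json")))
  }
  if ("taxonomy" %in% config$modules) {
    need <- c(need, file.path(config$cohort_dir, "taxonomy.tsv"))
  }
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    abort(paste0("missing inputs for stage train [config ", config$digest,
                 "]: ", paste(basename(missing), collapse = ", ")),
          class = "gofusion_config_error")
  }
}

read_run_cohort <- function(config) {
  onto <- read_obo(file.path(config$cohort_dir, "ontology.obo"))
  seq_arc <- read_archive(file.path(config$cohort_dir,
                                    "seq_embeddings.bin"))
  text_path <- file.path(config$cohort_dir, "text_embeddings.bin")
  text_arc <- if (file.exists(text_path)) read_archive(text_path) else
    list(entries = list(), dim = 0L, metadata = list())
  tax_path <- file.path(config$cohort_dir, "taxonomy.tsv")
  tax <- if (file.exists(tax_path)) read_taxonomy(tax_path) else
    setNames(integer(), character())
  cohort(names(seq_arc$entries), seq_arc, text_arc, tax,
         read_annotations(file.path(config$cohort_dir, "annotations.tsv")),
         onto)
}

#' Train from an on-disk cohort
#'
#' Validates inputs, builds the pruned label space, splits the cohort with
#' the coverage guarantee, trains the model and writes the checkpoint, the
#' label-space manifest, the held-out protein list and the per-epoch loss
#' trace into `out_dir`.
#'
#' @param config A [run_config()].
#' @return The fitted `gofusion_model`, invisibly.
#' @export
run_train <- function(config) {
  validate_run_inputs(config)
  ch <- read_run_cohort(config)
  graph <- split_subontology(ch$ontology$terms, ch$ontology$edges,
                             config$aspect)
  ann <- dplyr::filter(ch$annotations, .data$aspect == config$aspect)
  th <- config$threshold %||% auto_threshold(length(ch$protein_ids))
  ls <- prune_by_frequency(graph, ann, th)
  splits <- split_cohort(ch, config$test_fraction, config$seed,
                         label_space = ls)
  tc <- structure(config$train, class = "train_config")
  model <- train_model(splits$train, config$aspect, label_space = ls,
                       modules = config$modules, config = tc,
                       propagate = config$propagate)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_checkpoint(model, config$out_dir, config_digest = config$digest)
  write_label_manifest(ls, file.path(config$out_dir, "label_space.json"))
  writeLines(splits$test$protein_ids,
             file.path(config$out_dir, "test_proteins.txt"))
  trace <- tidy(model)
  write.table(trace, file.path(config$out_dir, "loss_trace.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (e in seq_len(nrow(trace))) {
    log_stage(config, "train",
              sprintf("epoch=%d lr=%.3g loss=%.6f", trace$epoch[e],
                      trace$lr[e], trace$loss[e]))
  }
  invisible(model)
}

#' Evaluate a checkpoint on its held-out split
#'
#' Reloads the checkpoint, verifies that its term-order digest matches the
#' label-space manifest next to it (refusing to score on a mismatched
#' label space), and evaluates on the proteins recorded at train time.
#'
#' @param config A [run_config()].
#' @param checkpoint_dir Directory written by [run_train()] (defaults to
#'   `config$out_dir`).
#' @return A `gofusion_eval`, invisibly; the JSON/TSV report lands in
#'   `checkpoint_dir`.
#' @export
run_evaluate <- function(config, checkpoint_dir = config$out_dir) {
  model <- read_checkpoint(checkpoint_dir)
  manifest <- jsonlite::read_json(file.path(checkpoint_dir,
                                            "label_space.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$term_digest, model$term_digest)) {
    abort("label-space manifest does not match checkpoint term digest",
          class = "gofusion_digest_error")
  }
  ch <- read_run_cohort(config)
  test_ids <- readLines(file.path(checkpoint_dir, "test_proteins.txt"))
  test_ch <- subset_cohort(ch, intersect(ch$protein_ids, test_ids))
  ev <- evaluate_model(model, test_ch, propagate = config$propagate)
  write_eval_report(ev, file.path(checkpoint_dir, "eval_report"))
  log_stage(config, "evaluate",
            sprintf("Fmax=%.4f tau=%.2f AUPR=%.4f", ev$fmax, ev$tau,
                    ev$aupr))
  invisible(ev)
}

log_stage <- function(config, stage, msg) {
  inform(sprintf("[%s %s] %s", stage, substr(config$digest, 1, 8), msg))
}

# ---- checkpoints -----------------------------------------------------------

model_param_list <- function(model) {
  p <- list(head_W1 = model$head$W1, head_b1 = model$head$b1,
            head_W2 = model$head$W2, head_b2 = model$head$b2,
            head_W_A = model$head$W_A, tax_table = model$tax$table,
            adjacency = model$adjacency)
  if (!is.null(model$align)) {
    p <- c(p, list(align_P = model$align$P, align_W1f = model$align$W1f,
                   align_b1f = model$align$b1f,
                   align_W2f = model$align$W2f,
                   align_b2f = model$align$b2f))
  }
  p
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a flat binary parameter container (`params.bin`, little
#' endian doubles) plus a JSON manifest recording tensor shapes, the
#' aspect, module switches, the term order and its digest, the taxonomy
#' weight and the training schedule. `read_checkpoint()` verifies the term
#' digest before reconstructing the model.
#'
#' @param model A `gofusion_model`.
#' @param dir Checkpoint directory.
#' @param config_digest Optional configuration digest to embed.
#' @return `write_checkpoint()`: `dir` invisibly; `read_checkpoint()`: the
#'   reconstructed `gofusion_model`.
#' @export
write_checkpoint <- function(model, dir, config_digest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- model_param_list(model)
  con <- file(file.path(dir, "params.bin"), "wb")
  for (p in params) writeBin(as.vector(p), con, size = 8L,
                             endian = "little")
  close(con)
  ls <- model$label_space
  manifest <- list(
    format = "gofusion-checkpoint-v1",
    aspect = model$aspect,
    modules = model$modules,
    d = model$d,
    gamma = ls$gamma,
    shapes = lapply(params, function(p) dim(p) %||% length(p)),
    term_order = ls$graph$terms$id,
    term_digest = model$term_digest,
    frequencies = as.list(ls$frequencies),
    threshold = ls$threshold,
    terms = as.list(ls$graph$terms),
    edges = as.list(ls$graph$edges),
    w_tax = model$tax$w_tax,
    n_species = model$tax$n_species,
    align_meta = if (!is.null(model$align)) {
      list(n_heads = model$align$n_heads,
           fragment_length = model$align$fragment_length,
           top_k_texts = model$align$top_k_texts,
           dropout = model$align$dropout)
    },
    train = unclass(model$config),
    loss_trace = model$loss_trace,
    n_train = model$n_train,
    config_digest = config_digest
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "gofusion-checkpoint-v1")) {
    abort("not a checkpoint directory", class = "gofusion_io_error")
  }
  if (!identical(
    digest_string(paste(manifest$term_order, collapse = ",")),
    manifest$term_digest)) {
    abort("term digest mismatch in checkpoint manifest",
          class = "gofusion_digest_error")
  }
  shapes <- manifest$shapes
  con <- file(file.path(dir, "params.bin"), "rb")
  on.exit(close(con))
  params <- lapply(shapes, function(sh) {
    sh <- as.integer(sh)
    v <- readBin(con, "double", n = prod(sh), size = 8L, endian = "little")
    if (length(sh) == 2L) matrix(v, sh[1], sh[2]) else v
  })

  graph <- go_graph(tibble::as_tibble(manifest$terms),
                    tibble::as_tibble(manifest$edges))
  freqs <- unlist(manifest$frequencies)
  ls <- structure(list(
    graph = graph,
    gamma = as.integer(manifest$gamma),
    adjacency_hat = normalized_adjacency(graph),
    frequencies = setNames(as.integer(freqs), names(freqs)),
    threshold = manifest$threshold
  ), class = "go_label_space")

  headp <- structure(list(W1 = params$head_W1, b1 = params$head_b1,
                          W2 = params$head_W2, b2 = params$head_b2,
                          W_A = params$head_W_A), class = "head_params")
  tax <- structure(list(table = params$tax_table, w_tax = manifest$w_tax,
                        n_species = as.integer(manifest$n_species)),
                   class = "taxonomy_encoder")
  align <- if (!is.null(params$align_P)) {
    structure(list(P = params$align_P, W1f = params$align_W1f,
                   b1f = params$align_b1f, W2f = params$align_W2f,
                   b2f = params$align_b2f,
                   n_heads = as.integer(manifest$align_meta$n_heads),
                   fragment_length =
                     as.integer(manifest$align_meta$fragment_length),
                   top_k_texts =
                     as.integer(manifest$align_meta$top_k_texts),
                   dropout = manifest$align_meta$dropout),
              class = "alignment_params")
  }
  structure(list(
    aspect = manifest$aspect,
    label_space = ls,
    modules = manifest$modules,
    align = align,
    tax = tax,
    head = headp,
    adjacency = params$adjacency,
    config = structure(manifest$train, class = "train_config"),
    loss_trace = manifest$loss_trace,
    d = as.integer(manifest$d),
    term_digest = manifest$term_digest,
    n_train = manifest$n_train
  ), class = "gofusion_model")
}
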