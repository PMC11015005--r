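#' Save / load a pre-training checkpoint
#'
#' The checkpoint file holds the trunk and head weights, batch-norm state and
#' every configuration; a `model_card.json` written next to it records the
#' architecture, parameter count and training provenance.
#'
#' @param checkpoint a `harssl_checkpoint` from [pretrain()].
#' @param path checkpoint file path (conventionally `<run_id>_best.ckpt`).
#' @return `save_checkpoint`: the path, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "harssl_checkpoint"))
  saveRDS(checkpoint, path)
  card <- list(
    encoder = list(layers = encoder_layer_count(checkpoint$encoder),
                   parameters = count_parameters(checkpoint$encoder),
                   feature_dim = checkpoint$encoder$cfg$feature_dim,
                   base_width = checkpoint$encoder$cfg$base_width,
                   kernel_size = checkpoint$encoder$cfg$kernel_size,
                   input_len = checkpoint$encoder$cfg$input_len),
    tasks = checkpoint$tasks,
    weighted_sampling = checkpoint$weighted,
    best_epoch = checkpoint$best_epoch,
    seed = checkpoint$seed)
  jsonlite::write_json(card, paste0(path, ".model_card.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the restored `harssl_checkpoint`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "harssl_checkpoint"))
    stop_format("file does not contain a checkpoint")
  ck
}

#' Write a per-epoch history table as TSV
#'
#' Long format: epoch, metric, value — one row per recorded quantity.
#'
#' @param history history data frame (from [pretrain()] or [finetune()]).
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_history_tsv <- function(history, path) {
  long <- do.call(rbind, lapply(setdiff(names(history), "epoch"), function(m)
    data.frame(epoch = history$epoch, metric = m, value = history[[m]])))
  utils::write.table(long[order(long$epoch), ], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest capturing configs and seeds
#'
#' @param configs named list of configuration objects (classes are dropped;
#'   values serialised as YAML).
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(configs, path) {
  strip <- function(x) {
    if (inherits(x, "harssl_activity_spec")) return(unclass(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  yaml::write_yaml(lapply(configs, strip), path)
  invisible(path)
}

#' Write an evaluation metrics report as TSV
#'
#' One row per (model, metric): mean and standard deviation across subjects.
#'
#' @param reports named list (by model, e.g. `random_forest`, `scratch`,
#'   `head_only`, `all_layers`) of [score_subjectwise()] results.
#' @param path output TSV path.
#' @param dataset dataset name recorded in the table.
#' @return The path, invisibly.
#' @export
write_metrics_tsv <- function(reports, path, dataset = "dataset") {
  rows <- list()
  for (model in names(reports)) {
    ag <- reports[[model]]$aggregate
    rows[[length(rows) + 1L]] <- data.frame(
      dataset = dataset, model = model,
      metric = c("macro_f1", "kappa"),
      mean = c(ag$mean_f1, ag$mean_kappa),
      sd = c(ag$sd_f1, ag$sd_kappa))
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
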