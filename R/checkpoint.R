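# Checkpointing and transfer: save/load, head replacement, trunk freezing,
# fine-tuning. Checkpoints embed the architecture config so a model can be
# rebuilt from the file alone; optimizer state is deliberately excluded
# (fine-tuning restarts with a fresh optimizer).

CHECKPOINT_FORMAT <- "s2t-checkpoint/1"

#' Save a model checkpoint
#'
#' @param model An `s2t_model`.
#' @param path Output file path.
#' @param provenance Optional list recorded verbatim (e.g. training seed,
#'   epochs, dataset fingerprint).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, "s2t_model"))
  saveRDS(list(format = CHECKPOINT_FORMAT,
               config = unclass(model$config),
               params = model$params,
               provenance = provenance), path)
  invisible(path)
}

#' Load a model from a checkpoint
#'
#' Rebuilds the model from the embedded config and restores parameters; a
#' save/load round trip reproduces forward passes exactly. Corrupted files
#' and format-version mismatches give structured errors; when
#' `expect_num_tracks` is supplied, a head-width mismatch is an explicit
#' error naming both values.
#'
#' @param path Checkpoint file.
#' @param expect_num_tracks Optional expected head width.
#' @return An `s2t_model`.
#' @export
load_checkpoint <- function(path, expect_num_tracks = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(errorCondition(
      sprintf("load_checkpoint: cannot parse '%s': %s", path, conditionMessage(e)),
      class = c("s2t_io_error", "error")))
  })
  if (!is.list(obj) || is.null(obj$format) || is.null(obj$config) || is.null(obj$params)) {
    stop(errorCondition("load_checkpoint: not a checkpoint container",
                        class = c("s2t_io_error", "error")))
  }
  if (!identical(obj$format, CHECKPOINT_FORMAT)) {
    stop(errorCondition(
      sprintf("load_checkpoint: format version mismatch: file has '%s', reader supports '%s'",
              obj$format, CHECKPOINT_FORMAT),
      class = c("s2t_io_error", "error")))
  }
  cfg <- do.call(architecture_config, obj$config)
  if (!is.null(expect_num_tracks) && cfg$num_tracks != expect_num_tracks) {
    stop(errorCondition(
      sprintf("load_checkpoint: embedded num_tracks (%d) != expected (%d)",
              cfg$num_tracks, as.integer(expect_num_tracks)),
      class = c("s2t_config_error", "error")))
  }
  expected <- names(param_spec(cfg))
  if (!identical(sort(expected), sort(names(obj$params)))) {
    stop(errorCondition("load_checkpoint: parameter names do not match the embedded config",
                        class = c("s2t_io_error", "error")))
  }
  model <- list(config = cfg, params = obj$params[expected],
                static = model_static(cfg), frozen_trunk = FALSE,
                provenance = obj$provenance)
  class(model) <- "s2t_model"
  model
}

# Stable checksum over a parameter group, for freezing/trunk-identity tests.
param_checksum <- function(model, group = "trunk") {
  nm <- names(model$params)
  keep <- nm[startsWith(nm, paste0(group, "."))]
  sum(vapply(model$params[keep], function(p) sum(p) + sum(p * p), numeric(1)))
}

#' Replace the output head
#'
#' Deletes the linear head and installs a freshly initialized one with
#' `new_num_tracks` outputs; trunk parameters are numerically untouched.
#'
#' @param model An `s2t_model`.
#' @param new_num_tracks New head width (>= 1).
#' @param seed Seed for the new head's initialization.
#' @return The modified model.
#' @export
replace_head <- function(model, new_num_tracks, seed = 1L) {
  stopifnot(inherits(model, "s2t_model"), new_num_tracks >= 1L)
  cfg <- model$config
  cfg$num_tracks <- as.integer(new_num_tracks)
  validate_config(cfg)
  spec <- param_spec(cfg)
  model$config <- cfg
  withr::with_seed(seed, {
    model$params[["head.W"]] <- init_one(spec[["head.W"]])
    model$params[["head.b"]] <- init_one(spec[["head.b"]])
  })
  model
}

#' Freeze or unfreeze the trunk
#'
#' When frozen, optimization updates only head parameters (the training
#' loop skips the trunk). Reversible.
#'
#' @param model An `s2t_model`.
#' @param freeze_trunk Logical flag.
#' @return The modified model.
#' @export
set_frozen <- function(model, freeze_trunk = TRUE) {
  stopifnot(inherits(model, "s2t_model"))
  model$frozen_trunk <- isTRUE(freeze_trunk)
  model
}

#' Number of trainable parameters
#'
#' @param model An `s2t_model`.
#' @return Head parameter count when the trunk is frozen, else the full
#'   count.
#' @export
count_trainable <- function(model) {
  if (isTRUE(model$frozen_trunk)) count_parameters(model, "head")
  else count_parameters(model, "all")
}

#' Fine-tune from a checkpoint
#'
#' The composition the transfer protocol prescribes: load the checkpoint,
#' delete and re-initialize the head at the fine-tuning dataset's track
#' count, optionally freeze the trunk, and train.
#'
#' @param checkpoint Path to a checkpoint file, or an already loaded
#'   `s2t_model`.
#' @param dataset Fine-tuning `track_dataset`; its window length and bin
#'   count must match the checkpoint config.
#' @param cfg A [training_config()].
#' @param freeze_trunk Update only the head if `TRUE`.
#' @param head_seed Seed for the fresh head.
#' @param eval_dataset Optional per-epoch evaluation dataset.
#' @param verbose Passed to [train()].
#' @return `list(model, history)` as from [train()].
#' @export
finetune <- function(checkpoint, dataset, cfg, freeze_trunk = FALSE,
                     head_seed = 1L, eval_dataset = NULL, verbose = FALSE) {
  model <- if (inherits(checkpoint, "s2t_model")) checkpoint else load_checkpoint(checkpoint)
  if (model$config$sequence_length != dataset$window ||
      model$config$output_bins != n_bins(dataset)) {
    stop(errorCondition(
      sprintf("finetune: checkpoint geometry (%d bp, %d bins) != dataset (%s bp, %d bins)",
              model$config$sequence_length, model$config$output_bins,
              dataset$window, n_bins(dataset)),
      class = c("s2t_config_error", "error")))
  }
  model <- replace_head(model, n_tracks(dataset), seed = head_seed)
  model <- set_frozen(model, freeze_trunk)
  train(model, dataset, cfg, eval_dataset = eval_dataset, verbose = verbose)
}
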