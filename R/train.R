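# Training protocol: AdamW, batch size 1, Poisson NLL in single- or
# multi-track mode, per-iteration linear warmup/decay of the learning rate.

#' Training configuration
#'
#' Defaults follow the training protocol this package implements: 10 epochs,
#' AdamW with peak learning rate 3e-5 and weight decay 1e-4, a linear warmup
#' over the first epoch followed by linear decay to zero, batch size 1.
#' Desk-scale experiments on the synthetic benchmark typically raise
#' `peak_lr` (see the package vignette) because they take orders of magnitude
#' fewer optimization steps than a genome-scale run.
#'
#' @param epochs Number of passes over the training set.
#' @param peak_lr Peak learning rate reached at the end of warmup.
#' @param weight_decay Decoupled AdamW weight decay.
#' @param warmup_epochs Epochs of linear warmup (must be < `epochs`).
#' @param batch_size Examples per optimization step (gradients averaged).
#' @param mode `"multi_track"` (loss averaged over all tracks) or
#'   `"single_track"` (loss on `track_index` only).
#' @param track_index Track column used in single-track mode.
#' @param shuffle_seed Seed driving per-epoch shuffling (and dropout).
#' @param grad_clip Optional global gradient-norm bound; `NULL` disables.
#' @return An object of class `s2t_train_config`.
#' @export
training_config <- function(epochs = 10L, peak_lr = 3e-5, weight_decay = 1e-4,
                            warmup_epochs = 1L, batch_size = 1L,
                            mode = c("multi_track", "single_track"),
                            track_index = NULL, shuffle_seed = 1L,
                            grad_clip = NULL) {
  cfg <- list(epochs = as.integer(epochs), peak_lr = peak_lr,
              weight_decay = weight_decay, warmup_epochs = as.integer(warmup_epochs),
              batch_size = as.integer(batch_size), mode = match.arg(mode),
              track_index = if (is.null(track_index)) NULL else as.integer(track_index),
              shuffle_seed = as.integer(shuffle_seed), grad_clip = grad_clip)
  if (cfg$epochs > 0L && cfg$warmup_epochs >= cfg$epochs) {
    stop(errorCondition("training_config: warmup_epochs must be < epochs",
                        class = c("s2t_config_error", "error")))
  }
  if (cfg$peak_lr <= 0) {
    stop(errorCondition("training_config: peak_lr must be > 0",
                        class = c("s2t_config_error", "error")))
  }
  class(cfg) <- "s2t_train_config"
  cfg
}

# Deterministic seed mixing, kept below 2^31.
derive_seed <- function(...) {
  v <- c(...)
  h <- 0
  for (x in v) h <- (h * 1000003 + (as.numeric(x) %% 2147483647)) %% 2147483629
  as.integer(h)
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       skip = character(0), beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd - lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

example_loss_grad <- function(rates, y, cfg) {
  if (cfg$mode == "single_track") {
    j <- cfg$track_index
    loss <- poisson_nll(rates[, j, drop = FALSE], y[, j, drop = FALSE])
    dr <- matrix(0, nrow(rates), ncol(rates))
    dr[, j] <- poisson_nll_grad(rates[, j, drop = FALSE], y[, j, drop = FALSE])
  } else {
    loss <- poisson_nll(rates, y)
    dr <- poisson_nll_grad(rates, y)
  }
  list(loss = loss, dr = dr)
}

#' Train a model
#'
#' Runs `epochs x ceiling(n / batch_size)` AdamW steps over the dataset with
#' the piecewise-linear learning-rate schedule of [lr_at()]. Multi-track mode
#' averages the Poisson NLL over all tracks; single-track mode restricts the
#' objective to `track_index`. Shuffling (and dropout, when active) is seeded
#' per epoch from `shuffle_seed` and the epoch index, so the loss trajectory
#' is reproducible.
#'
#' @param model An `s2t_model`. A frozen trunk ([set_frozen()]) is honored:
#'   only head parameters are updated.
#' @param dataset A `track_dataset` whose geometry matches the model.
#' @param cfg A [training_config()].
#' @param eval_dataset Optional dataset evaluated after each epoch.
#' @param verbose Emit a per-epoch log line.
#' @return `list(model, history)` where `history` is a data frame with one
#'   row per epoch: `epoch`, `mean_loss`, `lr_end`, `eval_pearson`,
#'   `seconds`.
#' @export
train <- function(model, dataset, cfg, eval_dataset = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "s2t_model"), inherits(cfg, "s2t_train_config"))
  n <- n_examples(dataset)
  if (n == 0L) {
    stop(errorCondition("train: dataset is empty", class = c("s2t_value_error", "error")))
  }
  if (cfg$mode == "single_track") {
    if (is.null(cfg$track_index)) {
      stop(errorCondition("train: single_track mode requires track_index",
                          class = c("s2t_config_error", "error")))
    }
    if (cfg$track_index < 1L || cfg$track_index > n_tracks(dataset)) {
      stop(errorCondition("train: track_index out of range for dataset",
                          class = c("s2t_config_error", "error")))
    }
  }
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                        lr_end = numeric(0), eval_pearson = numeric(0),
                        seconds = numeric(0))
  if (cfg$epochs == 0L) return(list(model = model, history = history))
  spe <- as.integer(ceiling(n / cfg$batch_size))
  skip <- if (isTRUE(model$frozen_trunk)) {
    nm <- names(model$params); nm[startsWith(nm, "trunk.")]
  } else character(0)
  state <- adamw_init(model$params)
  gstep <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    set.seed(derive_seed(cfg$shuffle_seed, epoch))
    order <- sample.int(n)
    losses <- numeric(spe)
    lr <- NA_real_
    for (s in seq_len(spe)) {
      gstep <- gstep + 1L
      idx <- order[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n)]
      acc <- NULL
      loss_b <- 0
      for (i in idx) {
        ex <- dataset_example(dataset, i)
        fw <- model_forward_one(model, ex$x, train = TRUE, keep_cache = TRUE)
        lg <- example_loss_grad(fw$rates, ex$y, cfg)
        if (!is.finite(lg$loss)) {
          stop(errorCondition(
            sprintf("train: non-finite loss at epoch %d step %d (example %d)", epoch, s, i),
            class = c("s2t_numeric_error", "error")))
        }
        loss_b <- loss_b + lg$loss / length(idx)
        g <- model_backward_one(model, fw$cache, lg$dr / length(idx))
        acc <- if (is.null(acc)) g else {
          for (nmg in names(g)) acc[[nmg]] <- acc[[nmg]] + g[[nmg]]
          acc
        }
      }
      if (!is.null(cfg$grad_clip)) {
        gn <- sqrt(sum(vapply(acc, function(g) sum(g * g), numeric(1))))
        if (gn > cfg$grad_clip) acc <- lapply(acc, function(g) g * cfg$grad_clip / gn)
      }
      lr <- lr_at(gstep, spe, cfg)
      upd <- adamw_step(model$params, acc, state, lr, cfg$weight_decay, skip = skip)
      model$params <- upd$params
      state <- upd$state
      losses[s] <- loss_b
    }
    ev <- NA_real_
    if (!is.null(eval_dataset)) {
      rep <- evaluate(model, eval_dataset)
      ev <- rep$average
    }
    secs <- proc.time()[["elapsed"]] - t0
    history <- rbind(history, data.frame(
      epoch = epoch, mean_loss = mean(losses), lr_end = lr,
      eval_pearson = ev, seconds = secs))
    if (verbose) {
      message(sprintf("epoch %d/%d loss %.5f lr %.3g%s (%.1fs)",
                      epoch, cfg$epochs, mean(losses), lr,
                      if (is.na(ev)) "" else sprintf(" eval r %.4f", ev), secs))
    }
  }
  list(model = model, history = history)
}

#' Evaluate a model by pooled per-track Pearson correlation
#'
#' For each track, all bins of all examples are pooled into one
#' prediction/target vector pair and correlated; the report average is the
#' arithmetic mean over non-degenerate tracks. Tracks with constant targets
#' (or constant predictions) are skipped with a warning and listed.
#'
#' @param model An `s2t_model`.
#' @param dataset A non-empty `track_dataset`.
#' @param tracks Optional integer vector restricting the report.
#' @return An `s2t_evaluation_report`: list with `per_track`, `average`,
#'   `n_bins`, `skipped`, `n_examples`.
#' @export
evaluate <- function(model, dataset, tracks = NULL) {
  n <- n_examples(dataset)
  if (n == 0L) {
    stop(errorCondition("evaluate: dataset is empty", class = c("s2t_value_error", "error")))
  }
  nt <- n_tracks(dataset)
  tracks <- if (is.null(tracks)) seq_len(nt) else as.integer(tracks)
  stopifnot(all(tracks >= 1L & tracks <= nt))
  bins <- model$config$output_bins
  preds <- matrix(0, n * bins, length(tracks))
  targs <- matrix(0, n * bins, length(tracks))
  for (i in seq_len(n)) {
    ex <- dataset_example(dataset, i)
    r <- model_forward_one(model, ex$x, train = FALSE, keep_cache = FALSE)$rates
    rows <- ((i - 1L) * bins + 1L):(i * bins)
    preds[rows, ] <- r[, tracks, drop = FALSE]
    targs[rows, ] <- ex$y[, tracks, drop = FALSE]
  }
  per_track <- rep(NA_real_, length(tracks))
  names(per_track) <- track_names(dataset)[tracks]
  skipped <- integer(0)
  for (k in seq_along(tracks)) {
    r <- tryCatch(pearson(preds[, k], targs[, k]),
                  s2t_degenerate_metric = function(e) NA_real_)
    if (is.na(r)) skipped <- c(skipped, tracks[k]) else per_track[k] <- r
  }
  if (length(skipped) == length(tracks)) {
    stop(errorCondition("evaluate: all requested tracks are constant",
                        class = c("s2t_value_error", "error")))
  }
  if (length(skipped) > 0L) {
    warning(sprintf("evaluate: skipped %d constant track(s): %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  out <- list(per_track = per_track,
              average = mean(per_track, na.rm = TRUE),
              n_bins = n * bins, skipped = skipped, n_examples = n)
  class(out) <- "s2t_evaluation_report"
  out
}

#' @export
print.s2t_evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation> average Pearson %.4f over %d track(s), %d pooled bins (%d examples)\n",
              x$average, sum(!is.na(x$per_track)), x$n_bins, x$n_examples))
  if (length(x$skipped)) cat("  skipped constant tracks:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
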