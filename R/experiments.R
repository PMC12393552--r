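# Paired experimental designs: architecture ablations and the track-count
# generalization/specialization sweep.

#' Compare architecture variants under a paired design
#'
#' Builds each variant from the same seed, trains all of them with identical
#' data order (same training config, hence same per-epoch shuffles), and
#' evaluates on the same dataset, so rows differ only in architecture. All
#' variants are validated before any training starts, and must share input
#' geometry (`sequence_length`, `output_bins`, `num_tracks`) to be
#' comparable.
#'
#' @param variants Named list of [architecture_config()]s.
#' @param dataset Training `track_dataset`.
#' @param cfg A [training_config()].
#' @param eval_dataset Evaluation dataset (defaults to `dataset`).
#' @param seed Model initialization seed shared by all variants.
#' @param verbose Passed to [train()].
#' @return Data frame with one row per variant: `variant`, `n_params`,
#'   `final_loss`, `pearson`. Loss trajectories and the dataset fingerprint
#'   are attached as attributes `histories` and `dataset_fingerprint`.
#' @export
run_ablation <- function(variants, dataset, cfg, eval_dataset = NULL,
                         seed = 1L, verbose = FALSE) {
  stopifnot(is.list(variants), length(variants) >= 1L)
  if (is.null(names(variants)) || any(names(variants) == "")) {
    names(variants) <- sprintf("variant%d", seq_along(variants))
  }
  for (v in variants) validate_config(v)
  geom <- vapply(variants, function(v)
    paste(v$sequence_length, v$output_bins, v$num_tracks), character(1))
  if (length(unique(geom)) != 1L) {
    stop(errorCondition(
      "run_ablation: variants differ in sequence_length/output_bins/num_tracks; not comparable",
      class = c("s2t_config_error", "error")))
  }
  if (is.null(eval_dataset)) eval_dataset <- dataset
  rows <- list(); histories <- list()
  for (nm in names(variants)) {
    model <- build_model(variants[[nm]], seed = seed)
    fit <- train(model, dataset, cfg, verbose = verbose)
    rep <- evaluate(fit$model, eval_dataset)
    rows[[nm]] <- data.frame(variant = nm,
                             n_params = count_parameters(fit$model),
                             final_loss = utils::tail(fit$history$mean_loss, 1),
                             pearson = rep$average)
    histories[[nm]] <- fit$history
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histories") <- histories
  attr(out, "dataset_fingerprint") <- dataset_fingerprint(dataset)
  out
}

#' The four standard ablation variants of a baseline configuration
#'
#' Given a baseline with both the attention linear layer and the final
#' pointwise convolution present, returns the baseline plus: (1) the final
#' pointwise convolution removed, (2) the attention linear layer removed,
#' (3) both removed, and (4) the attention depth reduced (both removed,
#' fewer attention blocks).
#'
#' @param baseline An [architecture_config()] with `use_attention_linear`
#'   and `use_final_pointwise` both `TRUE`.
#' @param reduced_attention Attention depth of variant (4); default 5.
#' @return Named list of configs.
#' @export
ablation_variants <- function(baseline, reduced_attention = 5L) {
  stopifnot(baseline$use_attention_linear, baseline$use_final_pointwise)
  tweak <- function(cfg, ...) {
    mods <- list(...)
    for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
    validate_config(cfg)
    cfg
  }
  list(
    baseline = baseline,
    no_pointwise = tweak(baseline, use_final_pointwise = FALSE),
    no_attention_linear = tweak(baseline, use_attention_linear = FALSE),
    no_both = tweak(baseline, use_final_pointwise = FALSE, use_attention_linear = FALSE),
    reduced_attention = tweak(baseline, use_final_pointwise = FALSE,
                              use_attention_linear = FALSE,
                              num_attention_blocks = as.integer(reduced_attention))
  )
}

#' Track-count generalization/specialization sweep
#'
#' For each `(count, replicate)` cell: sample `count` additional tracks
#' (uniform, without replacement, never the track of interest), build a
#' fresh model from the cell seed, train in multi-track mode on the sampled
#' tracks plus the track of interest, evaluate (all-track average and the
#' track of interest), then fine-tune for another `cfg$epochs` epochs on the
#' single track of interest at `finetune_lr` and re-evaluate. Cell seeds are
#' a deterministic mix of `(base_seed, count, replicate)`, so adding counts
#' never perturbs existing cells; data order is identical across cells
#' (paired design).
#'
#' @param dataset Training `track_dataset`.
#' @param track_of_interest Track index the sweep focuses on.
#' @param counts Vector of additional-track counts (each `<= n_tracks - 1`).
#' @param replicates Replicates per count (fresh model init each).
#' @param cfg A [training_config()] (multi-track phase).
#' @param finetune_lr Peak learning rate of the post-hoc single-track phase.
#' @param base_seed Integer seed.
#' @param eval_dataset Evaluation dataset (defaults to `dataset`).
#' @param resample_tracks If `TRUE` (default) each replicate resamples the
#'   additional tracks; if `FALSE` the sample depends only on the count.
#' @param verbose Emit one message per cell.
#' @return An `s2t_sweep_result` data frame: one row per cell with
#'   `additional_track_count`, `replicate`, `seed`,
#'   `avg_pearson_all_tracks`, `pearson_track_of_interest`,
#'   `post_finetune_avg_pearson`, `post_finetune_track_pearson`.
#' @export
track_sweep <- function(dataset, track_of_interest, counts, replicates, cfg,
                        finetune_lr, base_seed = 1L, eval_dataset = NULL,
                        model_config, resample_tracks = TRUE, verbose = FALSE) {
  nt <- n_tracks(dataset)
  if (any(counts > nt - 1L)) {
    stop(errorCondition(
      sprintf("track_sweep: count %d exceeds available additional tracks (%d)",
              max(counts), nt - 1L),
      class = c("s2t_argument_error", "error")))
  }
  stopifnot(replicates >= 1L, track_of_interest >= 1L, track_of_interest <= nt)
  if (is.null(eval_dataset)) eval_dataset <- dataset
  pool <- setdiff(seq_len(nt), track_of_interest)
  rows <- list()
  for (count in counts) {
    for (r in seq_len(replicates)) {
      seed <- derive_seed(base_seed, count, r)
      track_seed <- if (resample_tracks) seed else derive_seed(base_seed, count)
      extra <- if (count == length(pool)) pool else
        withr::with_seed(track_seed, sort(sample(pool, count)))
      sel <- c(track_of_interest, extra)
      sub_train <- subset_tracks(dataset, sel)
      sub_eval <- subset_tracks(eval_dataset, sel)
      mcfg <- model_config
      mcfg$num_tracks <- length(sel)
      validate_config(mcfg)
      model <- build_model(mcfg, seed = seed)
      fit <- train(model, sub_train, cfg)
      ev <- suppressWarnings(evaluate(fit$model, sub_eval))
      ft_cfg <- cfg
      ft_cfg$mode <- "single_track"
      ft_cfg$track_index <- 1L
      ft_cfg$peak_lr <- finetune_lr
      ft <- train(fit$model, sub_train, ft_cfg)
      ev2 <- suppressWarnings(evaluate(ft$model, sub_eval))
      rows[[length(rows) + 1L]] <- data.frame(
        additional_track_count = count, replicate = r, seed = seed,
        avg_pearson_all_tracks = ev$average,
        pearson_track_of_interest = unname(ev$per_track[1]),
        post_finetune_avg_pearson = ev2$average,
        post_finetune_track_pearson = unname(ev2$per_track[1]))
      if (verbose) {
        message(sprintf("sweep count %d rep %d: toi r %.4f -> %.4f (avg %.4f -> %.4f)",
                        count, r, utils::tail(rows, 1)[[1]]$pearson_track_of_interest,
                        utils::tail(rows, 1)[[1]]$post_finetune_track_pearson,
                        utils::tail(rows, 1)[[1]]$avg_pearson_all_tracks,
                        utils::tail(rows, 1)[[1]]$post_finetune_avg_pearson))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dataset_fingerprint") <- dataset_fingerprint(dataset)
  class(out) <- c("s2t_sweep_result", "data.frame")
  out
}
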