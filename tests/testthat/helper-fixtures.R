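# Shared fixtures: a tiny config for structural tests, the desk-scale
# geometry used by the training experiments, and canonical grammar specs.
# Heavy multi-seed experiment results are computed once per test run and
# memoised in `.s2t_cache` so several tests can assert on different facets
# of the same runs.

tiny_config <- function(num_tracks = 2L, output_bins = 12L, ...) {
  architecture_config(
    sequence_length = 64L, bin_size = 4L, num_pooling_stages = 2L,
    num_conv_blocks = 2L, num_attention_blocks = 1L, model_width = 8L,
    num_heads = 2L, head_dim = 4L, output_bins = as.integer(output_bins),
    num_tracks = as.integer(num_tracks), ...)
}

# Desk-scale geometry: 512 bp windows at 32 bp bins (5 pooling stages),
# 16 output bins, a 32-channel trunk with 2 attention blocks.
desk_config <- function(num_tracks = 1L, ...) {
  architecture_config(
    sequence_length = 512L, bin_size = 32L, num_pooling_stages = 5L,
    num_conv_blocks = 5L, num_attention_blocks = 2L, model_width = 32L,
    num_heads = 2L, head_dim = 16L, output_bins = 16L,
    num_tracks = as.integer(num_tracks), ...)
}

# Fixed 4-motif single-track grammar for memorization/learnability tests.
desk_grammar <- function(n_tracks = 1L, window = 512L) {
  motifs <- data.frame(
    consensus = c("TGACGTCA", "GGGCGCCC", "TTTACGTA", "CACGTGAC"),
    mut_rate = 0.05, max_mismatch = 1L, mean_occurrences = 4)
  w <- matrix(c(2.5, 3, 2, 2.8), 4L, 1L)[, rep(1L, n_tracks), drop = FALSE]
  grammar_spec(motifs, w, baseline = 0.5, window = window, bin_size = 32L)
}

desk_train_config <- function(...) {
  training_config(peak_lr = 1e-3, ...)
}

.s2t_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(name, fn) {
  if (is.null(.s2t_cache[[name]])) .s2t_cache[[name]] <- fn()
  .s2t_cache[[name]]
}

# --- memorization runs: 8 examples, 200 epochs, 3 seeds ---------------------

memorization_runs <- function() {
  memoise_fixture("memorization", function() {
    sapply(1:3, function(seed) {
      ds <- make_dataset(desk_grammar(), 8L, seed = 100 + seed, split = "train")
      cfg <- desk_train_config(epochs = 200L, warmup_epochs = 10L, shuffle_seed = seed)
      fit <- train(build_model(desk_config(1L), seed = seed), ds, cfg)
      c(train_pearson = evaluate(fit$model, ds)$average,
        first_loss = fit$history$mean_loss[1],
        last_loss = utils::tail(fit$history$mean_loss, 1))
    })
  })
}

# --- transfer runs: pretrain on 20 tracks of member A, fine-tune / scratch
#     on the single member-B track; 3 paired seeds ---------------------------

transfer_runs <- function() {
  memoise_fixture("transfer", function() {
    res <- lapply(1:3, function(seed) {
      fam <- task_family(n_motifs = 8L, overlap = 0.75, n_tracks_a = 20L,
                         n_tracks_b = 1L, seed = seed, window = 512L,
                         bin_size = 32L, weight_range = c(2, 4),
                         mean_occurrences = 4)
      pair <- make_transfer_pair(fam, n_pretrain = 256L, n_finetune_train = 96L,
                                 n_finetune_val = 64L, seed = seed + 100)
      tc <- desk_train_config(shuffle_seed = seed)
      pre <- train(build_model(desk_config(20L), seed = seed), pair$pretrain, tc)
      ckpt <- tempfile(fileext = ".ckpt")
      on.exit(unlink(ckpt), add = TRUE)
      save_checkpoint(pre$model, ckpt)
      scratch <- train(build_model(desk_config(1L), seed = seed + 1), pair$finetune_train, tc)
      ft <- finetune(ckpt, pair$finetune_train, tc, head_seed = seed + 1)
      ft1 <- finetune(ckpt, pair$finetune_train,
                      desk_train_config(epochs = 1L, warmup_epochs = 0L, shuffle_seed = seed),
                      head_seed = seed + 1)
      frz <- finetune(ckpt, pair$finetune_train, tc, freeze_trunk = TRUE, head_seed = seed + 1)
      nop <- train(set_frozen(build_model(desk_config(1L), seed = seed + 1), TRUE),
                   pair$finetune_train, tc)
      ev <- function(fit) evaluate(fit$model, pair$finetune_val)$average
      c(scratch = ev(scratch), finetune = ev(ft), finetune_1ep = ev(ft1),
        pretrain_frozen = ev(frz), nopretrain_frozen = ev(nop))
    })
    do.call(rbind, res)
  })
}

# --- sweep dataset: 4 informative + 64 permuted distractor tracks -----------

sweep_dataset <- function() {
  memoise_fixture("sweep_data", function() {
    spec <- withr::with_seed(42, {
      vocab <- replicate(6, paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                                  collapse = ""))
      w <- matrix(stats::runif(6 * 4, 2, 4) * (stats::runif(6 * 4) < 0.75), 6, 4)
      for (m in 1:6) if (all(w[m, ] == 0)) w[m, sample(4, 1)] <- stats::runif(1, 2, 4)
      grammar_spec(data.frame(consensus = vocab, mean_occurrences = 4), w,
                   baseline = 0.5, window = 512L, bin_size = 32L)
    })
    train_ds <- make_distractor_tracks(
      make_dataset(spec, 96L, seed = 7, split = "train"), 64L, "permuted", seed = 9)
    val_ds <- make_distractor_tracks(
      make_dataset(spec, 64L, seed = 8, split = "validation"), 64L, "permuted", seed = 10)
    list(train = train_ds, val = val_ds, spec = spec)
  })
}

sweep_runs <- function() {
  memoise_fixture("sweep", function() {
    d <- sweep_dataset()
    track_sweep(d$train, track_of_interest = 1L, counts = c(1L, 4L, 16L, 64L),
                replicates = 3L, cfg = training_config(peak_lr = 2e-4, shuffle_seed = 5),
                finetune_lr = 2e-5, base_seed = 11, eval_dataset = d$val,
                model_config = desk_config(1L))
  })
}
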