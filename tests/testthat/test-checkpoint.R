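fixed_input <- function(cfg, seed = 33) {
  withr::with_seed(seed, one_hot_encode(paste(
    sample(c("A", "C", "G", "T"), cfg$sequence_length, replace = TRUE), collapse = "")))
}

test_that("checkpoint round trip reproduces forwards exactly", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 2)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path, provenance = list(training_seed = 2, epochs = 0))
  m2 <- load_checkpoint(path)
  x <- fixed_input(cfg)
  expect_identical(forward(m2, x), forward(m, x))
  expect_identical(m2$config, cfg)
  expect_equal(m2$provenance$training_seed, 2)
})

test_that("checkpoint loading gives structured errors", {
  bad <- withr::local_tempfile(fileext = ".ckpt")
  writeLines("garbage", bad)
  expect_error(load_checkpoint(bad), class = "s2t_io_error")
  wrong <- withr::local_tempfile(fileext = ".ckpt")
  saveRDS(list(format = "s2t-checkpoint/99", config = list(), params = list()), wrong)
  err <- tryCatch(load_checkpoint(wrong), error = identity)
  expect_s3_class(err, "s2t_io_error")
  expect_match(conditionMessage(err), "s2t-checkpoint/99")
  expect_match(conditionMessage(err), "s2t-checkpoint/1")
  # num_tracks expectation mismatch is explicit
  m <- build_model(tiny_config(num_tracks = 2L), seed = 1)
  ok <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, ok)
  err2 <- tryCatch(load_checkpoint(ok, expect_num_tracks = 5L), error = identity)
  expect_s3_class(err2, "s2t_config_error")
  expect_match(conditionMessage(err2), "2")
  expect_match(conditionMessage(err2), "5")
})

test_that("head replacement leaves the trunk numerically untouched", {
  ns <- asNamespace("seq2track")
  m <- build_model(tiny_config(num_tracks = 3L), seed = 4)
  before <- ns$param_checksum(m, "trunk")
  m2 <- replace_head(m, 5L, seed = 9)
  expect_equal(ns$param_checksum(m2, "trunk"), before)
  expect_equal(m2$config$num_tracks, 5L)
  r <- forward(m2, fixed_input(m2$config))
  expect_equal(dim(r), c(m2$config$output_bins, 5L))
  expect_equal(count_parameters(m2, "head"),
               m2$config$model_width * 5L + 5L)
  # single-track head
  m1 <- replace_head(m, 1L, seed = 9)
  expect_equal(dim(forward(m1, fixed_input(m1$config))), c(m1$config$output_bins, 1L))
})

test_that("freezing restricts updates to the head and is reversible", {
  ns <- asNamespace("seq2track")
  ds <- withr::with_seed(81, {
    cfg <- tiny_config()
    seqs <- replicate(2, paste(sample(c("A", "C", "G", "T"), cfg$sequence_length,
                                      replace = TRUE), collapse = ""))
    track_dataset(seqs, array(rpois(2 * cfg$output_bins * 2, 2),
                              c(2, cfg$output_bins, 2)), bin_size = cfg$bin_size)
  })
  m <- set_frozen(build_model(tiny_config(), seed = 5), TRUE)
  expect_equal(count_trainable(m), count_parameters(m, "head"))
  trunk_before <- ns$param_checksum(m, "trunk")
  head_before <- ns$param_checksum(m, "head")
  fit <- train(m, ds, training_config(epochs = 1L, warmup_epochs = 0L, peak_lr = 1e-3))
  expect_equal(ns$param_checksum(fit$model, "trunk"), trunk_before)
  expect_false(isTRUE(all.equal(ns$param_checksum(fit$model, "head"), head_before)))
  unfrozen <- set_frozen(fit$model, FALSE)
  expect_equal(count_trainable(unfrozen), count_parameters(unfrozen, "all"))
})

test_that("finetune composes load -> replace_head -> freeze -> train", {
  ns <- asNamespace("seq2track")
  cfg <- tiny_config(num_tracks = 3L)
  m <- build_model(cfg, seed = 6)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  ds <- withr::with_seed(91, {
    seqs <- replicate(3, paste(sample(c("A", "C", "G", "T"), cfg$sequence_length,
                                      replace = TRUE), collapse = ""))
    track_dataset(seqs, array(rpois(3 * cfg$output_bins, 2),
                              c(3, cfg$output_bins, 1)), bin_size = cfg$bin_size)
  })
  # frozen fine-tuning: trunk checksum invariant across the whole run
  trunk <- ns$param_checksum(m, "trunk")
  fit <- finetune(path, ds, training_config(epochs = 2L, peak_lr = 1e-3,
                                            warmup_epochs = 1L),
                  freeze_trunk = TRUE, head_seed = 3)
  expect_equal(ns$param_checksum(fit$model, "trunk"), trunk)
  expect_equal(n_tracks(ds), fit$model$config$num_tracks)
  # zero-epoch fine-tune: pretrained trunk plus a fresh head, unchanged
  fit0 <- finetune(path, ds, training_config(epochs = 0L, warmup_epochs = 0L,
                                             peak_lr = 1e-3), head_seed = 3)
  expect_equal(ns$param_checksum(fit0$model, "trunk"), trunk)
  ref <- replace_head(load_checkpoint(path), 1L, seed = 3)
  expect_identical(fit0$model$params, ref$params)
  # geometry mismatch is a config error
  short_ds <- withr::with_seed(92, {
    seqs <- replicate(2, paste(sample(c("A", "C", "G", "T"), 32, replace = TRUE),
                               collapse = ""))
    track_dataset(seqs, array(1, c(2, 8, 1)), bin_size = 4L)
  })
  expect_error(finetune(path, short_ds, training_config(peak_lr = 1e-3)),
               class = "s2t_config_error")
})
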