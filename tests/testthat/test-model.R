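random_input <- function(cfg, seed = 1) {
  withr::with_seed(seed, one_hot_encode(paste(
    sample(c("A", "C", "G", "T"), cfg$sequence_length, replace = TRUE), collapse = "")))
}

test_that("forward output geometry closes the resolution arithmetic", {
  for (cfg in list(tiny_config(), desk_config(3L),
                   tiny_config(output_bins = 16L))) {
    m <- build_model(cfg, seed = 2)
    r <- forward(m, random_input(cfg))
    expect_equal(dim(r), c(cfg$output_bins, cfg$num_tracks))
    expect_equal(cfg$sequence_length / cfg$bin_size - 2 * crop_per_side(cfg),
                 cfg$output_bins)
  }
})

test_that("outputs are strictly positive regardless of input", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 5)
  expect_true(all(forward(m, random_input(cfg, 1)) > 0))
  expect_true(all(forward(m, matrix(0, cfg$sequence_length, 4)) > 0))  # all-N
})

test_that("wrong input length gives a shape error naming expected vs got", {
  m <- build_model(tiny_config(), seed = 1)
  err <- tryCatch(forward(m, matrix(0, 32, 4)), error = identity)
  expect_s3_class(err, "s2t_shape_error")
  expect_match(conditionMessage(err), "64")
  expect_match(conditionMessage(err), "32")
})

test_that("same (config, seed) builds identical models; forwards are deterministic", {
  cfg <- tiny_config()
  m1 <- build_model(cfg, seed = 7)
  m2 <- build_model(cfg, seed = 7)
  expect_identical(names(m1$params), names(m2$params))
  expect_identical(m1$params, m2$params)
  x <- random_input(cfg, 3)
  expect_identical(forward(m1, x), forward(m2, x))
  # different seed -> different weights
  expect_false(identical(m1$params, build_model(cfg, seed = 8)$params))
})

test_that("batch semantics: identical inputs give identical outputs, order is preserved", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 4)
  x1 <- random_input(cfg, 1); x2 <- random_input(cfg, 2)
  out <- forward(m, list(x1, x1, x2))
  expect_identical(out[[1]], out[[2]])
  rev_out <- forward(m, list(x2, x1, x1))
  expect_identical(rev_out[[1]], out[[3]])
  expect_identical(rev_out[[2]], out[[1]])
})

test_that("parameter counts partition into trunk + head, with exact head arithmetic", {
  cfg <- desk_config(3L)  # head: model_width x 3 weights + 3 biases
  m <- build_model(cfg, seed = 1)
  expect_equal(count_parameters(m, "head"),
               cfg$model_width * cfg$num_tracks + cfg$num_tracks)
  expect_equal(count_parameters(m, "all"),
               count_parameters(m, "trunk") + count_parameters(m, "head"))
  expect_error(count_parameters(m, "bogus"))
})

test_that("ablations remove parameters structurally and monotonically", {
  base <- tiny_config(use_attention_linear = TRUE, use_final_pointwise = TRUE)
  n_base <- count_parameters(build_model(base, seed = 1))
  no_pw <- base; no_pw$use_final_pointwise <- FALSE
  no_lin <- base; no_lin$use_attention_linear <- FALSE
  no_both <- no_pw; no_both$use_attention_linear <- FALSE
  n_no_pw <- count_parameters(build_model(no_pw, seed = 1))
  n_no_lin <- count_parameters(build_model(no_lin, seed = 1))
  n_no_both <- count_parameters(build_model(no_both, seed = 1))
  expect_lt(n_no_pw, n_base)
  expect_lt(n_no_lin, n_base)
  expect_lt(n_no_both, min(n_no_pw, n_no_lin))
  # removed layers do not exist in the parameter set
  expect_false(any(grepl("final", names(build_model(no_pw, seed = 1)$params))))
  expect_false(any(grepl("\\.Wo$", names(build_model(no_lin, seed = 1)$params))))
  # the alternative reading removes the second feed-forward linear instead
  no_ffn2 <- tiny_config(use_attention_linear = FALSE,
                         attention_linear_site = "ffn_second")
  expect_false(any(grepl("\\.W2$", names(build_model(no_ffn2, seed = 1)$params))))
  expect_true(any(grepl("\\.Wo$", names(build_model(no_ffn2, seed = 1)$params))))
})

test_that("every structurally present layer group receives gradient", {
  cfg <- tiny_config(use_attention_linear = TRUE, use_final_pointwise = TRUE,
                     dropout_rate = 0)
  m <- build_model(cfg, seed = 3)
  x <- random_input(cfg, 6)
  y <- withr::with_seed(8, matrix(rpois(cfg$output_bins * cfg$num_tracks, 2),
                                  cfg$output_bins, cfg$num_tracks))
  ns <- asNamespace("seq2track")
  fw <- ns$model_forward_one(m, x, train = FALSE, keep_cache = TRUE)
  G <- ns$model_backward_one(m, fw$cache, ns$poisson_nll_grad(fw$rates, y))
  expect_setequal(names(G), names(m$params))
  groups <- unique(sub("\\.[^.]+$", "", names(m$params)))
  for (g in groups) {
    gn <- names(G)[startsWith(names(G), g)]
    expect_true(any(vapply(G[gn], function(x) any(x != 0), logical(1))),
                info = paste("no gradient in group", g))
  }
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_config(use_attention_linear = TRUE, use_final_pointwise = TRUE)
  m <- build_model(cfg, seed = 11)
  x <- random_input(cfg, 12)
  y <- withr::with_seed(13, matrix(rpois(cfg$output_bins * cfg$num_tracks, 2),
                                   cfg$output_bins, cfg$num_tracks))
  ns <- asNamespace("seq2track")
  fw <- ns$model_forward_one(m, x, train = FALSE, keep_cache = TRUE)
  G <- ns$model_backward_one(m, fw$cache, ns$poisson_nll_grad(fw$rates, y))
  lossfn <- function(params) {
    m2 <- m; m2$params <- params
    poisson_nll(ns$model_forward_one(m2, x, FALSE, FALSE)$rates, y)
  }
  eps <- 1e-6
  withr::with_seed(14, {
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      idx <- if (length(p) > 6) sort(sample(length(p), 6)) else seq_along(p)
      for (ii in idx) {
        pp <- m$params
        pp[[nm]][ii] <- pp[[nm]][ii] + eps; f1 <- lossfn(pp)
        pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps; f0 <- lossfn(pp)
        gn <- (f1 - f0) / (2 * eps)
        expect_lt(abs(gn - G[[nm]][ii]) / max(1e-4, abs(gn), abs(G[[nm]][ii])),
                  1e-4)
      }
    }
  })
})
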