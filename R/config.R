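#' Architecture configuration for a sequence-to-track model
#'
#' Collects every structural knob of the simplified Enformer-style network:
#' input geometry (sequence length, bin size, number of pooling stages),
#' depth (convolutional and attention blocks), width (channels, heads), the
#' two ablation flags (final pointwise convolution; the linear layer inside
#' each attention block), cropping, and the output head.
#'
#' Resolution arithmetic must close: each pooling stage halves the sequence,
#' so `2^num_pooling_stages` must equal `bin_size`, the model's internal
#' positions then sit at one per bin, and central cropping reduces
#' `sequence_length / bin_size` positions to `output_bins`.
#'
#' @param sequence_length Input window length in bp. Default 196608.
#' @param bin_size Target resolution in bp per bin. Default 128.
#' @param num_pooling_stages Number of 2x pooling stages (stem pool plus
#'   tower pools). Must satisfy `2^num_pooling_stages == bin_size`.
#' @param num_conv_blocks Number of convolutional residual blocks including
#'   the stem. Must be at least `num_pooling_stages`; each of the first
#'   `num_pooling_stages` blocks is followed by a pooling stage.
#' @param num_attention_blocks Number of self-attention blocks. Default 11;
#'   the reduced variant uses 5.
#' @param model_width Channel width at the top of the conv tower and through
#'   the attention stack.
#' @param num_heads Number of attention heads.
#' @param head_dim Per-head key/query/value dimension. When the attention
#'   output projection is removed (the adopted variant), concatenated heads
#'   feed the residual stream directly, so `num_heads * head_dim` must equal
#'   `model_width`.
#' @param use_attention_linear Keep (`TRUE`) or structurally remove (`FALSE`,
#'   the adopted variant) the linear layer at `attention_linear_site`.
#' @param attention_linear_site Which linear layer the ablation removes:
#'   `"output_projection"` (default) or `"ffn_second"`.
#' @param use_final_pointwise Keep (`TRUE`) or remove (`FALSE`, the adopted
#'   variant) the final pointwise convolutional layer.
#' @param output_bins Number of central bins predicted per track.
#' @param num_tracks Number of output tracks (head width).
#' @param positional_scheme Relative-position information added to attention
#'   logits: `"learned_relative"` (default; one learned symmetric bias per
#'   distance per head), `"relative_bias"` (fixed exponential-decay basis
#'   with learned per-head coefficients), or `"none"`.
#' @param pool_type `"attention"` (softmax-weighted, default) or `"max"`.
#' @param dropout_rate Dropout applied to residual branches during training
#'   only. Default 0.
#' @param output_nonlinearity Only `"softplus"` is supported; it guarantees
#'   strictly positive Poisson rates.
#'
#' @return An object of class `s2t_config` (a validated list).
#' @export
architecture_config <- function(sequence_length = 196608L,
                                bin_size = 128L,
                                num_pooling_stages = 7L,
                                num_conv_blocks = 7L,
                                num_attention_blocks = 11L,
                                model_width = 128L,
                                num_heads = 4L,
                                head_dim = 32L,
                                use_attention_linear = FALSE,
                                attention_linear_site = c("output_projection", "ffn_second"),
                                use_final_pointwise = FALSE,
                                output_bins = 896L,
                                num_tracks = 1L,
                                positional_scheme = c("learned_relative", "relative_bias", "none"),
                                pool_type = c("attention", "max"),
                                dropout_rate = 0,
                                output_nonlinearity = "softplus") {
  cfg <- list(
    sequence_length = as.integer(sequence_length),
    bin_size = as.integer(bin_size),
    num_pooling_stages = as.integer(num_pooling_stages),
    num_conv_blocks = as.integer(num_conv_blocks),
    num_attention_blocks = as.integer(num_attention_blocks),
    model_width = as.integer(model_width),
    num_heads = as.integer(num_heads),
    head_dim = as.integer(head_dim),
    use_attention_linear = isTRUE(use_attention_linear),
    attention_linear_site = match.arg(attention_linear_site),
    use_final_pointwise = isTRUE(use_final_pointwise),
    output_bins = as.integer(output_bins),
    num_tracks = as.integer(num_tracks),
    positional_scheme = match.arg(positional_scheme),
    pool_type = match.arg(pool_type),
    dropout_rate = as.numeric(dropout_rate),
    output_nonlinearity = match.arg(output_nonlinearity, "softplus")
  )
  class(cfg) <- "s2t_config"
  validate_config(cfg)
  cfg
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("s2t_config_error", "error")))
}

#' Validate an architecture configuration
#'
#' Checks the resolution-arithmetic invariants and returns the config
#' invisibly, or signals an `s2t_config_error` naming the violated invariant.
#'
#' @param cfg An `s2t_config`.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "s2t_config")) config_error("not an s2t_config object")
  with(cfg, {
    if (sequence_length <= 0 || bin_size <= 0) {
      config_error("sequence_length and bin_size must be positive")
    }
    if (2^num_pooling_stages != bin_size) {
      config_error(sprintf(
        "invariant violated: 2^num_pooling_stages (%d) != bin_size (%d)",
        2^num_pooling_stages, bin_size))
    }
    if (sequence_length %% bin_size != 0) {
      config_error(sprintf(
        "invariant violated: sequence_length (%d) not divisible by bin_size (%d)",
        sequence_length, bin_size))
    }
    n_pos <- sequence_length %/% bin_size
    crop2 <- n_pos - output_bins
    if (crop2 < 0 || crop2 %% 2 != 0) {
      config_error(sprintf(
        "invariant violated: crop_per_side = (sequence_length/bin_size - output_bins)/2 = (%d - %d)/2 is not a non-negative integer",
        n_pos, output_bins))
    }
    if (num_conv_blocks < num_pooling_stages) {
      config_error("invariant violated: num_conv_blocks < num_pooling_stages (each pooling stage needs a conv block)")
    }
    if (!use_attention_linear && attention_linear_site == "output_projection" &&
        num_heads * head_dim != model_width) {
      config_error(sprintf(
        "invariant violated: with the attention output projection removed, num_heads * head_dim (%d) must equal model_width (%d)",
        num_heads * head_dim, model_width))
    }
    if (num_tracks < 1L) config_error("num_tracks must be >= 1")
    if (num_attention_blocks < 0L) config_error("num_attention_blocks must be >= 0")
    if (dropout_rate < 0 || dropout_rate >= 1) config_error("dropout_rate must be in [0, 1)")
  })
  invisible(cfg)
}

#' Central crop width implied by a configuration
#'
#' @param cfg An `s2t_config`.
#' @return Number of bins cropped from each side.
#' @export
crop_per_side <- function(cfg) {
  (cfg$sequence_length %/% cfg$bin_size - cfg$output_bins) %/% 2L
}

# Channel width of each conv block: stem at model_width/2, geometric growth
# to model_width at the last block (Enformer-lineage convention).
conv_widths <- function(cfg) {
  n <- cfg$num_conv_blocks
  if (n == 1L) return(cfg$model_width)
  w0 <- cfg$model_width / 2
  w <- round(w0 * 2^((seq_len(n) - 1) / (n - 1)))
  w[n] <- cfg$model_width
  as.integer(w)
}

#' Write / read a configuration as YAML
#'
#' The YAML file mirrors the configuration fields exactly; a checkpoint
#' embeds the same structure so a model can be rebuilt from either.
#'
#' @param cfg An `s2t_config`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `write_config`: `path`, invisibly. `read_config`: an `s2t_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  x <- unclass(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  do.call(architecture_config, x)
}
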