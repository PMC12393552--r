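#' Poisson negative log-likelihood
#'
#' Mean over all elements of `lambda - y * log(lambda)`, the Poisson NLL up
#' to the `y`-only constant `log(y!)`, which is dropped because it does not
#' affect optimization. A floor of 1e-8 is applied inside the logarithm.
#' Reported losses are therefore comparable only within this toolkit.
#'
#' @param rates Strictly positive predicted rates (vector or matrix).
#' @param targets Non-negative observed counts, same shape.
#' @return A finite scalar.
#' @export
poisson_nll <- function(rates, targets) {
  if (!identical(dim(rates) %||% length(rates), dim(targets) %||% length(targets))) {
    stop(errorCondition("poisson_nll: shape mismatch between rates and targets",
                        class = c("s2t_value_error", "error")))
  }
  if (any(rates <= 0)) {
    stop(errorCondition("poisson_nll: rates must be strictly positive",
                        class = c("s2t_value_error", "error")))
  }
  if (any(targets < 0)) {
    stop(errorCondition("poisson_nll: targets must be non-negative",
                        class = c("s2t_value_error", "error")))
  }
  mean(rates - targets * log(pmax(rates, 1e-8)))
}

# Gradient of poisson_nll wrt rates: (1 - y/lambda) / n.
poisson_nll_grad <- function(rates, targets) {
  (1 - targets / pmax(rates, 1e-8)) / length(rates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation between predictions and targets
#'
#' The evaluation metric: `Avg((x - xavg)(y - yavg)) / sqrt(Var[x] Var[y])`.
#' Scale factors cancel, so sample versus population moments are immaterial.
#' Constant inputs are degenerate; callers (e.g. [evaluate()]) may catch the
#' condition and skip the track.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A scalar in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop(errorCondition("pearson: inputs must have equal length >= 2",
                        class = c("s2t_value_error", "error")))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(errorCondition("pearson: constant input, correlation undefined",
                        class = c("s2t_degenerate_metric", "error")))
  }
  stats::cor(x, y)
}

#' Learning rate at a given optimization step
#'
#' Piecewise-linear schedule: 0 at step 0, rising linearly to `peak_lr` at
#' the end of the warmup epochs, then decaying linearly to exactly 0 at the
#' final step. Interpolation is per iteration, not per epoch.
#'
#' @param step Step index in `[0, epochs * steps_per_epoch]`.
#' @param steps_per_epoch Number of optimization steps per epoch.
#' @param cfg A [training_config()].
#' @return The learning rate at that step.
#' @export
lr_at <- function(step, steps_per_epoch, cfg) {
  total <- cfg$epochs * steps_per_epoch
  warm <- cfg$warmup_epochs * steps_per_epoch
  if (any(step < 0) || any(step > total)) {
    stop(errorCondition(
      sprintf("lr_at: step out of range [0, %d]", total),
      class = c("s2t_argument_error", "error")))
  }
  ifelse(step <= warm & warm > 0,
         cfg$peak_lr * step / warm,
         cfg$peak_lr * (total - step) / (total - warm))
}
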