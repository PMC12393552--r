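#' Bins-independent k-mer regression baseline
#'
#' A deliberately local reference model: each bin's target is regressed (by
#' least squares) on the k-mer counts of that bin's own sequence, pooled
#' across all training examples and bins. Because a bin sees only its own
#' sequence, the baseline cannot represent long-range motif-pair
#' interactions, which is what makes it a useful comparison point for the
#' attention model on interaction-driven tasks.
#'
#' @param train_ds,eval_ds `track_dataset`s sharing geometry.
#' @param track Track index to model.
#' @param k k-mer length (default 3).
#' @return List with `pearson` (pooled evaluation correlation),
#'   `predictions` (matrix `n_eval x bins`), and the fitted `coefficients`.
#' @export
kmer_baseline <- function(train_ds, eval_ds, track = 1L, k = 3L) {
  feat <- function(ds) {
    bins <- n_bins(ds)
    nb_full <- ds$window %/% ds$bin_size
    crop <- (nb_full - bins) %/% 2L
    pieces <- lapply(seq_len(n_examples(ds)), function(i) {
      s <- ds$sequences[i]
      substring(s, (crop + seq_len(bins) - 1L) * ds$bin_size + 1L,
                (crop + seq_len(bins)) * ds$bin_size)
    })
    xs <- Biostrings::DNAStringSet(unlist(pieces))
    Biostrings::oligonucleotideFrequency(xs, width = k)
  }
  Xtr <- feat(train_ds)
  ytr <- as.vector(t(train_ds$targets[, , track]))
  fit <- stats::lm.fit(cbind(1, Xtr), ytr)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  Xev <- feat(eval_ds)
  pred <- as.vector(cbind(1, Xev) %*% beta)
  yev <- as.vector(t(eval_ds$targets[, , track]))
  list(pearson = pearson(pred, yev),
       predictions = matrix(pred, n_examples(eval_ds), n_bins(eval_ds), byrow = TRUE),
       coefficients = beta)
}
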