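# Synthetic regulatory-grammar benchmark: sequences with planted motifs
# (including long-range motif pairs) whose occurrences drive per-bin Poisson
# rates. The rate model is additive with a positivity floor so planted
# effect sizes map linearly to coverage and every oracle is hand-checkable.

#' Specify a synthetic regulatory grammar
#'
#' A grammar is a motif vocabulary, per-track additive weights on motif
#' occurrences, optional pairwise long-range interaction terms, and a
#' baseline rate. For a sequence, the per-bin Poisson rate of track `t` is
#'
#'   `lambda = baseline + sum_m w[m, t] * (occurrences of m overlapping the
#'   bin) + sum_pairs interaction weight * (co-occurrence within
#'   max_distance, credited to both partner bins)`,
#'
#' floored at `rate_floor`.
#'
#' @param motifs Data frame with columns `consensus` (6-10 bp string) and
#'   optionally `mut_rate` (per-position mutation probability when planting,
#'   default 0.05), `max_mismatch` (mismatches tolerated when scanning,
#'   default 1), `mean_occurrences` (expected plants per window, default 3).
#' @param weights Numeric `(n_motifs, n_tracks)` matrix of additive rate
#'   contributions per occurrence.
#' @param interactions Optional data frame with `motif_i`, `motif_j`
#'   (indices), `max_distance` (bp between occurrence starts), `weight`.
#'   Applied to every track.
#' @param baseline Baseline rate per bin (> 0).
#' @param window Window length in bp.
#' @param bin_size Bin width in bp (must divide `window`).
#' @param gc Background GC fraction.
#' @param rate_floor Positivity floor for rates.
#' @return An object of class `s2t_grammar`.
#' @export
grammar_spec <- function(motifs, weights, interactions = NULL,
                         baseline = 0.5, window = 8192L, bin_size = 32L,
                         gc = 0.5, rate_floor = 1e-3) {
  if (is.character(motifs)) motifs <- data.frame(consensus = motifs)
  stopifnot(is.data.frame(motifs), !is.null(motifs$consensus))
  if (is.null(motifs$mut_rate)) motifs$mut_rate <- 0.05
  if (is.null(motifs$max_mismatch)) motifs$max_mismatch <- 1L
  if (is.null(motifs$mean_occurrences)) motifs$mean_occurrences <- 3
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == nrow(motifs), all(is.finite(weights)))
  if (baseline <= 0) {
    stop(errorCondition("grammar_spec: baseline must be > 0",
                        class = c("s2t_argument_error", "error")))
  }
  if (window %% bin_size != 0L) {
    stop(errorCondition("grammar_spec: window must be divisible by bin_size",
                        class = c("s2t_argument_error", "error")))
  }
  if (!is.null(interactions)) {
    stopifnot(all(c("motif_i", "motif_j", "max_distance", "weight") %in% names(interactions)))
  }
  spec <- list(motifs = motifs, weights = weights, interactions = interactions,
               baseline = baseline, window = as.integer(window),
               bin_size = as.integer(bin_size), gc = gc, rate_floor = rate_floor)
  class(spec) <- "s2t_grammar"
  spec
}

grammar_fingerprint <- function(spec) {
  sprintf("g.%s.w%.6g.b%g",
          paste(substr(spec$motifs$consensus, 1, 4), collapse = ""),
          sum(spec$weights), spec$baseline)
}

#' Sample a background DNA sequence
#'
#' i.i.d. bases with `P(G) + P(C) = gc`, reproducible from `seed`.
#'
#' @param length Sequence length in bp (0 allowed).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
sample_sequence <- function(length, gc = 0.5, seed = 1L) {
  if (gc <= 0 || gc >= 1) {
    stop(errorCondition("sample_sequence: gc must be in (0, 1)",
                        class = c("s2t_argument_error", "error")))
  }
  if (length == 0L) return("")
  withr::with_seed(seed, {
    paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  })
}

# Scan one sequence for motif occurrences (forward strand, mismatch
# tolerance per motif). Returns a list of integer start vectors per motif.
scan_motifs <- function(sequence, spec) {
  subj <- Biostrings::DNAString(sequence)
  len <- nchar(sequence)
  lapply(seq_len(nrow(spec$motifs)), function(m) {
    w <- nchar(spec$motifs$consensus[m])
    st <- Biostrings::start(Biostrings::matchPattern(
      spec$motifs$consensus[m], subj,
      max.mismatch = spec$motifs$max_mismatch[m]))
    # mismatch matching can report edge-overhanging hits; occurrences must
    # lie fully inside the window
    st[st >= 1L & st + w - 1L <= len]
  })
}

bins_of_occurrence <- function(start, width, bin_size, n_bins) {
  b1 <- (start - 1L) %/% bin_size + 1L
  b2 <- (start + width - 2L) %/% bin_size + 1L
  b1:min(b2, n_bins)
}

#' Per-bin Poisson rates implied by a grammar for a sequence
#'
#' Deterministic pure function of `(sequence, spec)`: scans for motif
#' occurrences (with each motif's mismatch tolerance), adds per-track motif
#' weights to every bin an occurrence overlaps, adds interaction weights to
#' both partner bins for motif pairs co-occurring within `max_distance`
#' (start-to-start), and floors at `rate_floor`.
#'
#' @param sequence DNA string of length `spec$window`.
#' @param spec An [grammar_spec()] object.
#' @return A `(window / bin_size, n_tracks)` matrix of positive rates.
#' @export
rate_profile <- function(sequence, spec) {
  if (nchar(sequence) != spec$window) {
    stop(errorCondition(
      sprintf("rate_profile: sequence length %d != spec window %d",
              nchar(sequence), spec$window),
      class = c("s2t_argument_error", "error")))
  }
  nb <- spec$window %/% spec$bin_size
  nt <- ncol(spec$weights)
  rates <- matrix(spec$baseline, nb, nt)
  occ <- scan_motifs(sequence, spec)
  widths <- nchar(spec$motifs$consensus)
  for (m in seq_along(occ)) {
    for (s in occ[[m]]) {
      b <- bins_of_occurrence(s, widths[m], spec$bin_size, nb)
      rates[b, ] <- rates[b, ] + rep(spec$weights[m, ], each = length(b))
    }
  }
  if (!is.null(spec$interactions)) {
    for (r in seq_len(nrow(spec$interactions))) {
      i <- spec$interactions$motif_i[r]; j <- spec$interactions$motif_j[r]
      maxd <- spec$interactions$max_distance[r]; wt <- spec$interactions$weight[r]
      si <- occ[[i]]; sj <- occ[[j]]
      if (length(si) == 0L || length(sj) == 0L) next
      for (a in si) {
        for (b in sj) {
          if (i == j && b <= a) next    # unordered pairs, no self-pairing
          if (abs(a - b) > maxd) next
          ba <- bins_of_occurrence(a, widths[i], spec$bin_size, nb)
          bb <- bins_of_occurrence(b, widths[j], spec$bin_size, nb)
          rates[ba, ] <- rates[ba, ] + wt
          rates[bb, ] <- rates[bb, ] + wt
        }
      }
    }
  }
  pmax(rates, spec$rate_floor)
}

# Plant motif instances into a background sequence: seeded uniform
# positions, Poisson-distributed plant counts, per-position mutation of the
# consensus. Overlapping plants are allowed. Assumes an active RNG stream.
plant_motifs <- function(background, spec) {
  s <- background
  bases <- c("A", "C", "G", "T")
  for (m in seq_len(nrow(spec$motifs))) {
    cons <- spec$motifs$consensus[m]
    w <- nchar(cons)
    k <- stats::rpois(1, spec$motifs$mean_occurrences[m])
    if (k == 0L) next
    pos <- sample.int(spec$window - w + 1L, k, replace = TRUE)
    for (p in pos) {
      inst <- strsplit(cons, "")[[1]]
      mut <- stats::runif(w) < spec$motifs$mut_rate[m]
      for (q in which(mut)) inst[q] <- sample(setdiff(bases, inst[q]), 1L)
      substr(s, p, p + w - 1L) <- paste(inst, collapse = "")
    }
  }
  s
}

#' Generate a synthetic track dataset from a grammar
#'
#' Each example is a seeded background sequence with motif instances planted
#' at seeded positions; targets are independent Poisson draws with mean
#' [rate_profile()] per track (or the exact rates when `noise = FALSE`,
#' giving a known Pearson-1 ceiling for an oracle predictor).
#'
#' @param spec An [grammar_spec()].
#' @param n_examples Number of examples (>= 1).
#' @param noise Draw Poisson counts (`TRUE`) or emit exact rates (`FALSE`).
#' @param seed Integer seed; every example derives its own substream.
#' @param output_bins Optional central crop of the target bins (to match a
#'   model that crops); default all bins.
#' @param split Optional split label stored on the dataset.
#' @return A `track_dataset` whose `meta` records the generating-spec
#'   fingerprint.
#' @export
make_dataset <- function(spec, n_examples, noise = TRUE, seed = 1L,
                         output_bins = NULL, split = NA_character_) {
  stopifnot(inherits(spec, "s2t_grammar"), n_examples >= 1L)
  nb_full <- spec$window %/% spec$bin_size
  nb <- if (is.null(output_bins)) nb_full else as.integer(output_bins)
  crop <- (nb_full - nb) %/% 2L
  stopifnot(crop >= 0L, (nb_full - nb) %% 2L == 0L)
  nt <- ncol(spec$weights)
  sequences <- character(n_examples)
  targets <- array(0, c(n_examples, nb, nt))
  for (i in seq_len(n_examples)) {
    sequences[i] <- withr::with_seed(derive_seed(seed, i, 1L), {
      plant_motifs(sample_sequence_raw(spec$window, spec$gc), spec)
    })
    rates <- rate_profile(sequences[i], spec)[(crop + 1L):(crop + nb), , drop = FALSE]
    targets[i, , ] <- if (noise) {
      withr::with_seed(derive_seed(seed, i, 2L),
                       matrix(stats::rpois(length(rates), rates), nb, nt))
    } else rates
  }
  track_dataset(sequences, targets,
                tracks = data.frame(name = sprintf("track%d", seq_len(nt))),
                bin_size = spec$bin_size, split = split,
                meta = list(spec_fingerprint = grammar_fingerprint(spec),
                            seed = seed, noise = noise))
}

# sample_sequence without its own seed handling (caller owns the stream)
sample_sequence_raw <- function(length, gc) {
  paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# ---- task families for transfer --------------------------------------------

#' A family of related tasks sharing a motif vocabulary
#'
#' Builds two grammar members ("species" A and B) over one random motif
#' vocabulary with a controlled support overlap: exactly
#' `round(overlap * n_motifs)` motifs carry nonzero weight in both members,
#' and the remaining motifs are divided between the members. Each member
#' gets its own per-track weight maps over its support.
#'
#' @param n_motifs Vocabulary size.
#' @param motif_length Consensus length in bp.
#' @param overlap Fraction of the vocabulary with nonzero weight in both
#'   members, in `[0, 1]`.
#' @param n_tracks_a,n_tracks_b Tracks per member.
#' @param seed Integer seed.
#' @param weight_range Per-occurrence weight range (uniform draw).
#' @param window,bin_size,baseline,gc,mut_rate,mean_occurrences Passed to the
#'   member grammars.
#' @return An object of class `s2t_task_family`: list with `members` (two
#'   [grammar_spec()]s), `vocabulary`, `shared` (indices), `overlap`.
#' @export
task_family <- function(n_motifs = 8L, motif_length = 8L, overlap = 0.75,
                        n_tracks_a = 20L, n_tracks_b = 1L, seed = 1L,
                        weight_range = c(1.5, 3), window = 1024L, bin_size = 32L,
                        baseline = 0.5, gc = 0.5, mut_rate = 0.05,
                        mean_occurrences = 3) {
  stopifnot(overlap >= 0, overlap <= 1)
  withr::with_seed(seed, {
    vocab <- replicate(n_motifs, paste(sample(c("A", "C", "G", "T"), motif_length,
                                              replace = TRUE), collapse = ""))
    while (anyDuplicated(vocab)) {
      vocab[duplicated(vocab)] <- replicate(sum(duplicated(vocab)),
        paste(sample(c("A", "C", "G", "T"), motif_length, replace = TRUE), collapse = ""))
    }
    n_shared <- round(overlap * n_motifs)
    perm <- sample.int(n_motifs)
    shared <- perm[seq_len(n_shared)]
    rest <- setdiff(perm, shared)
    only_a <- rest[seq_len(length(rest) %/% 2L)]
    only_b <- setdiff(rest, only_a)
    support_a <- sort(c(shared, only_a))
    support_b <- sort(c(shared, only_b))
    draw_weights <- function(support, n_tracks) {
      w <- matrix(0, n_motifs, n_tracks)
      for (t in seq_len(n_tracks)) {
        use <- support[stats::runif(length(support)) < 0.75]
        if (length(use) == 0L) use <- support[sample.int(length(support), 1L)]
        w[use, t] <- stats::runif(length(use), weight_range[1], weight_range[2])
      }
      # member support must be exactly `support`: re-seat all-zero rows
      for (m in support) {
        if (all(w[m, ] == 0)) w[m, sample.int(n_tracks, 1L)] <-
            stats::runif(1, weight_range[1], weight_range[2])
      }
      w
    }
    motifs <- data.frame(consensus = vocab, mut_rate = mut_rate,
                         max_mismatch = 1L, mean_occurrences = mean_occurrences)
    mk <- function(support, n_tracks) {
      grammar_spec(motifs, draw_weights(support, n_tracks),
                   baseline = baseline, window = window, bin_size = bin_size, gc = gc)
    }
    fam <- list(members = list(A = mk(support_a, n_tracks_a),
                               B = mk(support_b, n_tracks_b)),
                vocabulary = vocab, shared = sort(shared), overlap = overlap,
                seed = as.integer(seed))
  })
  class(fam) <- "s2t_task_family"
  fam
}

#' Measured support overlap of a task family
#'
#' Fraction of the vocabulary with nonzero weight in both members (row-wise
#' over each member's weight matrix).
#'
#' @param family An `s2t_task_family`.
#' @return Scalar in `[0, 1]`.
#' @export
family_overlap <- function(family) {
  sa <- rowSums(family$members$A$weights) > 0
  sb <- rowSums(family$members$B$weights) > 0
  sum(sa & sb) / length(sa)
}

#' Materialize a pretrain/fine-tune dataset pair from a task family
#'
#' The pretraining dataset comes from member A (many tracks), the
#' fine-tuning datasets from member B. Sequence seeds are disjoint across
#' the three datasets, so no sequence leaks between them.
#'
#' @param family An [task_family()].
#' @param n_pretrain,n_finetune_train,n_finetune_val Example counts.
#' @param seed Integer seed.
#' @param noise Poisson noise flag passed to [make_dataset()].
#' @return List with `pretrain`, `finetune_train`, `finetune_val`
#'   `track_dataset`s, each carrying the family fingerprint and overlap in
#'   `meta`.
#' @export
make_transfer_pair <- function(family, n_pretrain, n_finetune_train,
                               n_finetune_val = 0L, seed = 1L, noise = TRUE) {
  stopifnot(inherits(family, "s2t_task_family"))
  mk <- function(member, n, sub, split) {
    if (n == 0L) return(NULL)
    ds <- make_dataset(family$members[[member]], n, noise = noise,
                       seed = derive_seed(seed, sub), split = split)
    ds$meta$family_overlap <- family_overlap(family)
    ds$meta$family_seed <- family$seed
    ds
  }
  list(pretrain = mk("A", n_pretrain, 1L, "train"),
       finetune_train = mk("B", n_finetune_train, 2L, "train"),
       finetune_val = mk("B", n_finetune_val, 3L, "validation"))
}

# ---- distractor tracks -----------------------------------------------------

#' Append distractor tracks to a dataset
#'
#' Three modes: `"permuted"` (seeded global permutations of existing tracks'
#' bin values — the value multiset is preserved but all sequence association
#' is destroyed), `"independent_grammar"` (tracks generated from a fresh
#' random-vocabulary grammar evaluated on the same sequences), and
#' `"pure_noise"` (i.i.d. Poisson at the base dataset's mean rate). Track
#' metadata labels distractors via the `role` column.
#'
#' @param base A `track_dataset` (`k >= 1` tracks appended to it).
#' @param k Number of distractor tracks to append.
#' @param mode One of `"permuted"`, `"independent_grammar"`, `"pure_noise"`.
#' @param seed Integer seed.
#' @return A `track_dataset` with `n_tracks(base) + k` tracks.
#' @export
make_distractor_tracks <- function(base, k,
                                   mode = c("permuted", "independent_grammar", "pure_noise"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  if (k < 1L) {
    stop(errorCondition("make_distractor_tracks: k must be >= 1",
                        class = c("s2t_argument_error", "error")))
  }
  n <- n_examples(base); nb <- n_bins(base); nt <- n_tracks(base)
  new <- array(0, c(n, nb, k))
  if (mode == "permuted") {
    withr::with_seed(seed, {
      for (j in seq_len(k)) {
        src <- as.vector(base$targets[, , ((j - 1L) %% nt) + 1L])
        new[, , j] <- array(src[sample.int(length(src))], c(n, nb))
      }
    })
  } else if (mode == "pure_noise") {
    lam <- mean(base$targets)
    withr::with_seed(seed, {
      new[] <- stats::rpois(length(new), lam)
    })
  } else {
    spec <- withr::with_seed(derive_seed(seed, 1L), {
      vocab <- replicate(max(4L, min(8L, k)), paste(
        sample(c("A", "C", "G", "T"), 8L, replace = TRUE), collapse = ""))
      w <- matrix(stats::runif(length(vocab) * k, 1, 3) *
                    (stats::runif(length(vocab) * k) < 0.6), length(vocab), k)
      grammar_spec(data.frame(consensus = vocab), w,
                   baseline = mean(base$targets) / 2 + 1e-3,
                   window = base$window, bin_size = base$bin_size)
    })
    for (i in seq_len(n)) {
      nb_full <- base$window %/% base$bin_size
      crop <- (nb_full - nb) %/% 2L
      rates <- rate_profile(base$sequences[i], spec)[(crop + 1L):(crop + nb), , drop = FALSE]
      new[i, , ] <- withr::with_seed(derive_seed(seed, i, 3L),
                                     matrix(stats::rpois(length(rates), rates), nb, k))
    }
  }
  tracks <- rbind(base$tracks,
                  data.frame(name = sprintf("distractor_%s_%d", mode, seq_len(k)),
                             assay = "synthetic", species = "synthetic",
                             role = paste0("distractor:", mode)))
  out <- base
  combined <- array(0, c(n, nb, nt + k))
  combined[, , seq_len(nt)] <- base$targets
  combined[, , nt + seq_len(k)] <- new
  out$targets <- combined
  out$tracks <- tracks
  out
}
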