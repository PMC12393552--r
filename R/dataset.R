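# The track_dataset container: aligned pairs of fixed-length sequence
# windows and (bins x tracks) non-negative target matrices, plus track
# metadata. Sequences are stored as strings and one-hot encoded on access.

#' Construct a track dataset
#'
#' @param sequences Character vector of equal-length DNA windows.
#' @param targets Numeric array `(n_examples, bins, tracks)` of non-negative
#'   per-bin counts, or a list of `(bins, tracks)` matrices.
#' @param tracks Data frame of track metadata with at least a `name` column;
#'   `assay`, `species` and `role` are filled with defaults if absent.
#' @param bin_size Bin width in bp.
#' @param split Optional split label (`"train"`, `"validation"`, `"test"`).
#' @param meta Optional list of provenance fields (e.g. generating-spec
#'   fingerprint).
#' @return An object of class `track_dataset`.
#' @export
track_dataset <- function(sequences, targets, tracks = NULL, bin_size,
                          split = NA_character_, meta = list()) {
  stopifnot(is.character(sequences), length(sequences) >= 0L)
  if (is.list(targets) && !is.array(targets)) {
    stopifnot(length(targets) == length(sequences))
    bins <- nrow(targets[[1]]); nt <- ncol(targets[[1]])
    arr <- array(0, c(length(targets), bins, nt))
    for (i in seq_along(targets)) arr[i, , ] <- targets[[i]]
    targets <- arr
  }
  stopifnot(length(dim(targets)) == 3L, dim(targets)[1] == length(sequences))
  if (any(targets < 0)) {
    stop(errorCondition("track_dataset: negative target values",
                        class = c("s2t_data_error", "error")))
  }
  if (length(sequences) > 0L && length(unique(nchar(sequences))) > 1L) {
    stop(errorCondition("track_dataset: sequences must share one window length",
                        class = c("s2t_data_error", "error")))
  }
  nt <- dim(targets)[3]
  if (is.null(tracks)) tracks <- data.frame(name = sprintf("track%d", seq_len(nt)))
  if (nrow(tracks) != nt) {
    stop(errorCondition("track_dataset: track metadata rows != target track count",
                        class = c("s2t_data_error", "error")))
  }
  for (col in c("assay", "species", "role")) {
    if (is.null(tracks[[col]])) {
      tracks[[col]] <- c(assay = "synthetic", species = "synthetic",
                         role = "informative")[[col]]
    }
  }
  ds <- list(sequences = sequences, targets = targets, tracks = tracks,
             window = if (length(sequences)) nchar(sequences[1]) else NA_integer_,
             bin_size = as.integer(bin_size), split = split, meta = meta)
  class(ds) <- "track_dataset"
  ds
}

#' Dataset accessors
#'
#' @param ds A `track_dataset`.
#' @return `n_examples` / `n_tracks`: integer counts. `track_names`: the
#'   track name vector. `dataset_example`: `list(x, y)` with the one-hot
#'   `(window, 4)` encoding and the `(bins, tracks)` target matrix.
#' @export
n_examples <- function(ds) length(ds$sequences)

#' @rdname n_examples
#' @export
n_tracks <- function(ds) dim(ds$targets)[3]

#' @rdname n_examples
#' @export
n_bins <- function(ds) dim(ds$targets)[2]

#' @rdname n_examples
#' @export
track_names <- function(ds) ds$tracks$name

#' @rdname n_examples
#' @param i Example index.
#' @export
dataset_example <- function(ds, i) {
  stopifnot(i >= 1L, i <= n_examples(ds))
  list(x = one_hot_encode(ds$sequences[i]),
       y = matrix(ds$targets[i, , ], dim(ds$targets)[2], dim(ds$targets)[3]))
}

#' @export
print.track_dataset <- function(x, ...) {
  cat(sprintf("<track_dataset> %d example(s) x %d bin(s) x %d track(s), window %s bp, bin %d bp%s\n",
              n_examples(x), n_bins(x), n_tracks(x),
              ifelse(is.na(x$window), "?", x$window), x$bin_size,
              if (!is.na(x$split)) paste0(" [", x$split, "]") else ""))
  invisible(x)
}

# Cheap stable fingerprint of contents for paired-design bookkeeping.
dataset_fingerprint <- function(ds) {
  sprintf("n%d.b%d.t%d.s%.6g.q%.6g.c%d",
          n_examples(ds), n_bins(ds), n_tracks(ds),
          sum(ds$targets), sum(ds$targets^2),
          sum(utf8ToInt(paste(substr(ds$sequences, 1, 50), collapse = ""))))
}

#' Bin a per-bp coverage signal into per-bin totals
#'
#' Each bin value is the sum of the per-bp signal in that bin (coverage
#' counts are extensive, so the binning statistic is a sum, not a mean).
#'
#' @param coverage Non-negative numeric vector of per-bp signal.
#' @param bin_size Bin width; must divide `length(coverage)`.
#' @return Numeric vector of `length(coverage) / bin_size` bin totals.
#' @export
extract_targets <- function(coverage, bin_size) {
  if (any(coverage < 0)) {
    stop(errorCondition("extract_targets: negative signal values",
                        class = c("s2t_data_error", "error")))
  }
  if (length(coverage) %% bin_size != 0L) {
    stop(errorCondition("extract_targets: region length not divisible by bin_size",
                        class = c("s2t_data_error", "error")))
  }
  as.numeric(colSums(matrix(coverage, nrow = bin_size)))
}

#' Subsample examples without replacement
#'
#' Seeded uniform subsample preserving the source order (used to balance
#' training sets across tasks).
#'
#' @param ds A `track_dataset`.
#' @param n Number of examples to keep (`<=` dataset size).
#' @param seed Integer seed.
#' @return A `track_dataset` with `n` examples and intact metadata.
#' @export
subsample_examples <- function(ds, n, seed) {
  if (n > n_examples(ds)) {
    stop(errorCondition("subsample_examples: n exceeds dataset size",
                        class = c("s2t_argument_error", "error")))
  }
  keep <- sort(withr::with_seed(seed, sample.int(n_examples(ds), n)))
  subset_examples(ds, keep)
}

subset_examples <- function(ds, keep) {
  ds$sequences <- ds$sequences[keep]
  ds$targets <- ds$targets[keep, , , drop = FALSE]
  ds
}

#' Restrict a dataset to a subset of tracks
#'
#' @param ds A `track_dataset`.
#' @param idx Integer track indices (order preserved as given).
#' @return A `track_dataset` with `length(idx)` tracks.
#' @export
subset_tracks <- function(ds, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L & idx <= n_tracks(ds)))
  ds$targets <- ds$targets[, , idx, drop = FALSE]
  ds$tracks <- ds$tracks[idx, , drop = FALSE]
  rownames(ds$tracks) <- NULL
  ds
}

# ---- container IO ----------------------------------------------------------

DATASET_FORMAT <- "s2t-dataset/1"

#' Write / read the versioned dataset container
#'
#' The container is a single serialized file holding sequences, the dense
#' target array, track metadata and provenance, tagged with a format version
#' checked on read. Round trips are exact.
#'
#' @param ds A `track_dataset`.
#' @param path File path (conventionally `.dset`).
#' @return `write_dataset`: `path` invisibly; `read_dataset`: the dataset.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "track_dataset"))
  saveRDS(list(format = DATASET_FORMAT, dataset = unclass(ds)), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(errorCondition(sprintf("read_dataset: cannot parse '%s': %s", path, conditionMessage(e)),
                        class = c("s2t_io_error", "error")))
  })
  if (!is.list(obj) || !identical(obj$format, DATASET_FORMAT)) {
    stop(errorCondition(
      sprintf("read_dataset: format mismatch: expected '%s', got '%s'",
              DATASET_FORMAT, if (is.list(obj)) obj$format %||% "<none>" else "<not a container>"),
      class = c("s2t_io_error", "error")))
  }
  ds <- obj$dataset
  class(ds) <- "track_dataset"
  ds
}

# ---- standard-format exports ----------------------------------------------

#' Export dataset sequences, regions and coverage to standard formats
#'
#' Each example gets a synthetic contig named `exN` spanning
#' `[0, window)`. `export_fasta` writes the sequences; `export_bed` the
#' regions (0-based half-open); `export_bedgraph` one track's per-bin
#' coverage.
#'
#' @param ds A `track_dataset`.
#' @param path Output file path (gzip inferred from `.gz` suffix by the
#'   underlying writers where supported).
#' @param track Track index for `export_bedgraph`.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(ds, path) {
  xs <- Biostrings::DNAStringSet(ds$sequences)
  names(xs) <- sprintf("ex%d", seq_along(ds$sequences))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' @rdname export_fasta
#' @export
export_bed <- function(ds, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sprintf("ex%d", seq_len(n_examples(ds))),
    ranges = IRanges::IRanges(start = 1L, end = ds$window))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname export_fasta
#' @export
export_bedgraph <- function(ds, path, track = 1L) {
  bins <- n_bins(ds)
  n <- n_examples(ds)
  starts <- rep(seq_len(bins) - 1L, times = n) * ds$bin_size
  gr <- GenomicRanges::GRanges(
    seqnames = rep(sprintf("ex%d", seq_len(n)), each = bins),
    ranges = IRanges::IRanges(start = starts + 1L, width = ds$bin_size),
    score = as.vector(t(ds$targets[, , track])))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` returning a named
#' character vector of sequences (gzip tolerated).
#'
#' @param path FASTA file path (`.gz` accepted).
#' @return Named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(xs), names(xs))
}

#' Read per-position coverage from a bedGraph file
#'
#' Expands interval scores to a per-bp signal vector for one contig,
#' suitable for [extract_targets()]. Gzip input is handled by the importer.
#'
#' @param path bedGraph file.
#' @param seqname Contig to extract.
#' @param length Contig length in bp.
#' @return Numeric per-bp coverage vector of the given length.
#' @export
read_coverage_bedgraph <- function(path, seqname, length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == seqname]
  cov <- numeric(length)
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  sc <- gr$score
  for (k in seq_along(gr)) cov[st[k]:min(en[k], length)] <- sc[k]
  cov
}
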