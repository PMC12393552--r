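# Genomic regions (0-based half-open, BED convention throughout) and
# homology-aware train/validation/test splitting.

#' Tile chromosomes into fixed-length regions
#'
#' Splits each chromosome into windows fully contained in the chromosome,
#' in deterministic order (chromosome order as given, then start). A
#' chromosome shorter than the window contributes zero regions (with a
#' message), not an error.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param window Region length in bp.
#' @param stride Distance between region starts (`>= 1`).
#' @return Data frame with `chrom`, `start` (0-based), `end` (exclusive).
#' @export
make_regions <- function(chrom_lengths, window, stride) {
  stopifnot(stride >= 1L, window >= 1L)
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    if (len < window) {
      message(sprintf("make_regions: chromosome '%s' (%d bp) shorter than window (%d bp); skipped",
                      chrom, len, window))
      next
    }
    starts <- seq(0L, len - window, by = stride)
    out[[chrom]] <- data.frame(chrom = chrom, start = as.integer(starts),
                               end = as.integer(starts + window))
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

region_key <- function(df) paste(df$chrom, df$start, df$end, sep = ":")

#' Randomly partition regions into train/validation/test
#'
#' Group sizes follow largest-remainder rounding of the fractions; the
#' assignment itself is a seeded uniform permutation. Provenance columns are
#' initialized for later homology reassignment.
#'
#' @param regions Data frame from [make_regions()].
#' @param fractions Numeric length-3 vector `(train, validation, test)`,
#'   non-negative, summing to 1.
#' @param seed Integer seed.
#' @return An `s2t_split` data frame: the regions plus `label`,
#'   `originally_assigned`, `reassigned_in`, `reassigned_out`; the seed is
#'   kept as an attribute.
#' @export
partition_regions <- function(regions, fractions, seed) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop(errorCondition("partition_regions: fractions must sum to 1",
                        class = c("s2t_argument_error", "error")))
  }
  n <- nrow(regions)
  groups <- c("train", "validation", "test")
  nonzero <- sum(fractions > 0)
  if (n < nonzero) {
    stop(errorCondition("partition_regions: fewer regions than nonzero split groups",
                        class = c("s2t_partition_error", "error")))
  }
  base <- floor(n * fractions)
  rem <- n - sum(base)
  if (rem > 0L) {
    frac_part <- n * fractions - base
    bump <- order(-frac_part, seq_along(fractions))[seq_len(rem)]
    base[bump] <- base[bump] + 1L
  }
  labels <- rep(groups, times = base)
  perm <- withr::with_seed(seed, sample.int(n))
  out <- regions
  out$label <- NA_character_
  out$label[perm] <- labels
  out$originally_assigned <- out$label
  out$reassigned_in <- FALSE
  out$reassigned_out <- FALSE
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("s2t_split", "data.frame")
  out
}

#' Split sizes
#'
#' @param split An `s2t_split`.
#' @return Named integer vector of group sizes.
#' @export
split_sizes <- function(split) {
  vapply(c("train", "validation", "test"),
         function(g) sum(split$label == g), integer(1))
}

#' Reassign homologous regions into the training set
#'
#' Every region appearing in the homology table is relabeled `train` (so no
#' evaluation region shares homology with external training data). To
#' preserve split sizes, an equal number of non-homologous regions that were
#' originally assigned to train are moved out to the labels the homologous
#' regions came from, chosen uniformly at random under `seed`. When fewer
#' such regions are available than needed, the shortfall is logged (message
#' and attribute), not fatal.
#'
#' @param split An `s2t_split` from [partition_regions()].
#' @param homology Data frame with `chrom`, `start`, `end` columns naming
#'   regions of the split that are homologous to external training regions
#'   (see [read_homology_table()]).
#' @param seed Integer seed for the move-out draw.
#' @return The updated `s2t_split`, with provenance flags set and a
#'   `shortfall` attribute.
#' @export
homology_reassign <- function(split, homology, seed) {
  keys <- region_key(split)
  hkeys <- unique(region_key(homology))
  missing <- setdiff(hkeys, keys)
  if (length(missing) > 0L) {
    stop(errorCondition(
      sprintf("homology_reassign: %d homology region(s) not in the region set (first: %s)",
              length(missing), missing[1]),
      class = c("s2t_value_error", "error")))
  }
  hom <- keys %in% hkeys
  moved_in <- which(hom & split$label != "train")
  source_labels <- split$label[moved_in]
  split$label[moved_in] <- "train"
  split$reassigned_in[moved_in] <- TRUE
  shortfall <- 0L
  if (length(moved_in) > 0L) {
    candidates <- which(!hom & split$label == "train" &
                          split$originally_assigned == "train" & !split$reassigned_out)
    need <- table(factor(source_labels, levels = c("validation", "test")))
    withr::with_seed(seed, {
      for (lab in names(need)) {
        k <- as.integer(need[[lab]])
        if (k == 0L) next
        take <- min(k, length(candidates))
        shortfall <- shortfall + (k - take)
        if (take > 0L) {
          pick <- if (length(candidates) == 1L) candidates else sample(candidates, take)
          pick <- pick[seq_len(take)]
          split$label[pick] <- lab
          split$reassigned_out[pick] <- TRUE
          candidates <- setdiff(candidates, pick)
        }
      }
    })
  }
  if (shortfall > 0L) {
    message(sprintf("homology_reassign: shortfall of %d region(s); train grew by %d",
                    shortfall, shortfall))
  }
  attr(split, "shortfall") <- shortfall
  attr(split, "reassign_seed") <- as.integer(seed)
  split
}

#' Audit a split for homology leakage
#'
#' @param split An `s2t_split`.
#' @param homology Homology table as in [homology_reassign()].
#' @return Integer: number of homologous regions outside the training set
#'   (0 means the leakage audit passes).
#' @export
homology_leakage <- function(split, homology) {
  hom <- region_key(split) %in% unique(region_key(homology))
  sum(hom & split$label != "train")
}

# ---- standard-format IO ----------------------------------------------------

#' Read / write regions as BED (0-based half-open)
#'
#' @param path BED file path (gzip tolerated on read).
#' @param regions Data frame with `chrom`, `start`, `end`.
#' @return `read_bed`: a regions data frame; `write_bed`: `path` invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a tab-separated homology-pair table
#'
#' Expected columns: `chrom`, `start`, `end` (the region in this region
#' set, 0-based half-open) and `ext_chrom`, `ext_start`, `ext_end` (the
#' matched external region). Gzip tolerated. Homology detection itself is
#' assumed done upstream.
#'
#' @param path TSV file path.
#' @return A data frame with the six columns above.
#' @export
read_homology_table <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  df <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end")
  if (!all(required %in% names(df))) {
    stop(errorCondition("read_homology_table: need columns chrom, start, end",
                        class = c("s2t_io_error", "error")))
  }
  df
}
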