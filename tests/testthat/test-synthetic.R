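test_that("background sequences hit the requested GC content and are seeded", {
  expect_identical(sample_sequence(0, 0.5, 1), "")
  s <- sample_sequence(1e5, 0.5, seed = 3)
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.49); expect_lt(gc, 0.51)
  s2 <- sample_sequence(1e4, 0.7, seed = 4)
  gc2 <- mean(strsplit(s2, "")[[1]] %in% c("G", "C"))
  expect_gt(gc2, 0.68); expect_lt(gc2, 0.72)
  expect_identical(sample_sequence(500, 0.5, seed = 9), sample_sequence(500, 0.5, seed = 9))
  expect_error(sample_sequence(10, 1.2, 1), class = "s2t_argument_error")
})

test_that("rate profiles follow the additive occurrence arithmetic", {
  motifs <- data.frame(consensus = "ACGTACGT", mut_rate = 0, max_mismatch = 0L,
                       mean_occurrences = 0)
  spec <- grammar_spec(motifs, matrix(1.0, 1, 1), baseline = 0.5,
                       window = 256L, bin_size = 128L)
  # no occurrences -> constant baseline
  s_plain <- paste(rep("TTTT", 64), collapse = "")
  expect_equal(rate_profile(s_plain, spec), matrix(0.5, 2, 1))
  # two exact occurrences inside bin 1 -> lambda = 0.5 + 2
  s2 <- paste0("ACGTACGT", "TT", "ACGTACGT", paste(rep("T", 238), collapse = ""))
  expect_equal(rate_profile(s2, spec)[, 1], c(2.5, 0.5))
  # an occurrence straddling the bin boundary counts in both bins
  s3 <- paste0(paste(rep("T", 124), collapse = ""), "ACGTACGT",
               paste(rep("T", 124), collapse = ""))
  expect_equal(rate_profile(s3, spec)[, 1], c(1.5, 1.5))
  expect_error(rate_profile("ACGT", spec), class = "s2t_argument_error")
})

test_that("pair interactions require co-occurrence within the distance bound", {
  motifs <- data.frame(consensus = c("AAAAAAGG", "CCTTTTTT"), mut_rate = 0,
                       max_mismatch = 0L, mean_occurrences = 0)
  inter <- data.frame(motif_i = 1L, motif_j = 2L, max_distance = 200L, weight = 2)
  spec <- grammar_spec(motifs, matrix(0, 2, 1), interactions = inter,
                       baseline = 0.5, window = 512L, bin_size = 32L)
  put <- function(pos_a, pos_b) {
    s <- strsplit(sample_sequence(512, 0.5, seed = 5), "")[[1]]
    s[s == "A"] <- "G"; s[s == "T"] <- "C"  # purge spurious matches
    s <- paste(s, collapse = "")
    substr(s, pos_a, pos_a + 7) <- "AAAAAAGG"
    substr(s, pos_b, pos_b + 7) <- "CCTTTTTT"
    s
  }
  # brute-force oracle: scan occurrence starts directly
  near <- put(10, 150)   # distance 140 <= 200
  far <- put(10, 400)    # distance 390 > 200
  rp_near <- rate_profile(near, spec)
  rp_far <- rate_profile(far, spec)
  bin_of <- function(p) (p - 1) %/% 32 + 1
  expect_equal(rp_near[bin_of(10), 1], 0.5 + 2)
  expect_equal(rp_near[bin_of(150), 1], 0.5 + 2)
  expect_equal(rp_far[bin_of(10), 1], 0.5)
  expect_equal(rp_far[bin_of(400), 1], 0.5)
})

test_that("datasets are deterministic and Poisson noise matches its rates", {
  spec <- desk_grammar()
  d1 <- make_dataset(spec, 4L, seed = 12)
  d2 <- make_dataset(spec, 4L, seed = 12)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$targets, d2$targets)
  expect_false(identical(d1$sequences, make_dataset(spec, 4L, seed = 13)$sequences))
  # noiseless targets equal the rate profile: the oracle predictor is exact
  d0 <- make_dataset(spec, 3L, noise = FALSE, seed = 14)
  for (i in 1:3) {
    rp <- rate_profile(d0$sequences[i], spec)
    expect_equal(d0$targets[i, , 1], rp[, 1])
    expect_equal(pearson(rp[, 1], d0$targets[i, , 1]), 1)
  }
  # Poisson moments: repeated draws of one bin average to its rate
  one <- make_dataset(spec, 1L, noise = FALSE, seed = 15)
  lam <- one$targets[1, , 1]
  j <- which.max(lam)
  draws <- withr::with_seed(16, rpois(500, lam[j]))
  se <- sqrt(lam[j] / 500)
  expect_lt(abs(mean(draws) - lam[j]), 3 * se)
})

test_that("task families control support overlap exactly", {
  fam <- task_family(n_motifs = 8L, overlap = 0.5, n_tracks_a = 4L,
                     n_tracks_b = 2L, seed = 3, window = 512L)
  sa <- rowSums(fam$members$A$weights) > 0
  sb <- rowSums(fam$members$B$weights) > 0
  expect_equal(sum(sa & sb), 4L)
  expect_equal(family_overlap(fam), 0.5)
  # zero overlap: disjoint supports (negative-control pair)
  fam0 <- task_family(n_motifs = 8L, overlap = 0, n_tracks_a = 2L,
                      n_tracks_b = 2L, seed = 4, window = 512L)
  expect_equal(family_overlap(fam0), 0)
  # full overlap: identical support
  fam1 <- task_family(n_motifs = 6L, overlap = 1, n_tracks_a = 2L,
                      n_tracks_b = 2L, seed = 5, window = 512L)
  expect_equal(family_overlap(fam1), 1)
})

test_that("transfer pairs share no sequences and carry provenance", {
  fam <- task_family(n_motifs = 8L, overlap = 0.75, n_tracks_a = 3L,
                     n_tracks_b = 1L, seed = 6, window = 512L)
  pair <- make_transfer_pair(fam, n_pretrain = 4L, n_finetune_train = 4L,
                             n_finetune_val = 2L, seed = 7)
  expect_equal(n_tracks(pair$pretrain), 3L)
  expect_equal(n_tracks(pair$finetune_train), 1L)
  expect_length(intersect(pair$pretrain$sequences, pair$finetune_train$sequences), 0)
  expect_length(intersect(pair$finetune_train$sequences, pair$finetune_val$sequences), 0)
  expect_equal(pair$pretrain$meta$family_overlap, 0.75)
})

test_that("distractor tracks behave per mode", {
  base <- make_dataset(desk_grammar(), 6L, seed = 21)
  expect_error(make_distractor_tracks(base, 0L, "permuted", 1), class = "s2t_argument_error")
  # permuted: value multiset preserved, metadata labeled
  d <- make_distractor_tracks(base, 1L, "permuted", seed = 2)
  expect_equal(n_tracks(d), 2L)
  expect_equal(sort(as.vector(d$targets[, , 2])), sort(as.vector(base$targets[, , 1])))
  expect_match(d$tracks$role[2], "distractor")
  # pure noise is uncorrelated with the informative track (3 seeds)
  big <- make_dataset(desk_grammar(), 40L, seed = 22)
  for (s in 1:3) {
    dn <- make_distractor_tracks(big, 1L, "pure_noise", seed = s)
    r <- pearson(as.vector(dn$targets[, , 2]), as.vector(dn$targets[, , 1]))
    expect_lt(abs(r), 0.1)
  }
  # independent grammar mode appends learnable but unrelated tracks
  dg <- make_distractor_tracks(base, 2L, "independent_grammar", seed = 3)
  expect_equal(n_tracks(dg), 3L)
  expect_true(all(dg$targets >= 0))
})
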