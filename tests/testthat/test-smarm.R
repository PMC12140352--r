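test_that("poly-A trimming removes the adapter and drops short reads", {
  out <- trim_polya("ACGTACGTACGTACGTAAAAAAAAAA", min_len = 10)
  expect_equal(out$seq, "ACGTACGTACGTACGT")
  # one mismatch inside the adapter is tolerated at the default 10% rate
  out2 <- trim_polya("ACGTACGTACGTACGTAAAAGAAAAA", min_len = 10)
  expect_equal(out2$seq, "ACGTACGTACGTACGT")
  # no A-run at the allowed mismatch rate: read unchanged
  noA <- "ACGTACGTACGTACGTACGTACGT"
  expect_equal(trim_polya(noA, min_len = 10)$seq, noA)
  # too short after trimming: dropped
  out3 <- trim_polya("ACGAAAAAAAAAA", min_len = 15)
  expect_length(out3$seq, 0)
  expect_false(out3$kept)
})

test_that("5' end counting is strand-aware and filters as requested", {
  reads <- make_reads(start = c(5, 5, 5, 7), end = c(30, 30, 40, 30))
  tr <- count_five_prime_ends(reads, ref_length = 100)
  expect_equal(tr$n[6], 3)
  expect_equal(tr$n[8], 1)
  expect_equal(sum(tr$n), 4)
  # minus-strand 5' end is the last aligned base
  rev <- make_reads(start = 5, end = 30, strand = "-")
  expect_equal(which(count_five_prime_ends(rev, 100)$n == 1) - 1L, 29)
  # dedup collapses identical (start, end, strand)
  expect_equal(sum(count_five_prime_ends(reads, 100, dedup = TRUE)$n), 3)
  # unique_only drops multimappers
  reads$is_unique[1] <- FALSE
  expect_equal(sum(count_five_prime_ends(reads, 100,
                                         unique_only = TRUE)$n), 3)
  expect_error(count_five_prime_ends(make_reads(120, 150), 100),
               "outside")
})

test_that("the RiboMeth score is the flank-relative start depletion", {
  tr <- end_count_track(c(10, 10, 2, 10, 10, 10))
  sc <- ribometh_score(tr, k_flank = 2, weights = c(1, 1), cov_min = 5)
  # base i = 1 is read out at position 2: F = 10, S = 1 - 2/10
  expect_equal(sc$score[sc$position == 1], 0.8)
  # complete depletion scores 1
  tr0 <- end_count_track(c(10, 10, 0, 10, 10, 10))
  expect_equal(ribometh_score(tr0, 2, c(1, 1), 5)$score[2], 1)
  # excess counts clip to 0
  trx <- end_count_track(c(10, 10, 50, 10, 10, 10))
  expect_equal(ribometh_score(trx, 2, c(1, 1), 5)$score[2], 0)
  # coverage gate: undefined below cov_min
  lo <- ribometh_score(end_count_track(c(2, 2, 0, 2, 2, 2)), 2, c(1, 1),
                       cov_min = 10)
  expect_true(is.na(lo$score[2]))
  expect_false(lo$coverage_ok[2])
  expect_error(ribometh_score(end_count_track(rep(5, 5)), k_flank = 2),
               "shorter")
})

test_that("defined scores stay in [0, 1] for arbitrary integer tracks", {
  withr::with_seed(13, {
    for (rep in 1:25) {
      n <- rpois(sample(50:200, 1), lambda = sample(c(1, 5, 50), 1))
      sc <- ribometh_score(end_count_track(n), cov_min = 1)
      ok <- !is.na(sc$score)
      expect_true(all(sc$score[ok] >= 0 & sc$score[ok] <= 1))
      expect_true(all(is.na(sc$score[!sc$coverage_ok])))
    }
  })
})

test_that("site calling applies score and coverage thresholds", {
  tr <- end_count_track(c(50, 50, 2, 50, 50, 50, 50, 3, 50, 50))
  sc <- ribometh_score(tr, cov_min = 10)
  calls <- call_methylated_sites(sc, score_min = 0.8, cov_min = 10)
  expect_equal(calls$position, c(1, 6))
  expect_true(all(calls$score >= 0.8))
  expect_true(all(calls$called))
  # high score with failed coverage never surfaces
  weak <- ribometh_score(end_count_track(c(3, 3, 0, 3, 3, 3)),
                         cov_min = 10)
  expect_equal(nrow(call_methylated_sites(weak, 0.5, 10)), 0)
})

test_that("scores recover the methylated fraction from simulation", {
  p <- gen_methylation_profile(1000, 8, 0.3, 1.0, min_spacing = 30,
                               seed = 41)
  scores <- sapply(1:20, function(s) {
    tr <- simulate_end_counts(p, depth = 300, seed = 100 + s)
    ribometh_score(tr)$score[p$positions + 1L]
  })
  expect_lt(max(abs(rowMeans(scores) - p$m)), 0.06)
})

test_that("group comparison reports zero delta for identical groups", {
  p <- gen_methylation_profile(500, 4, 0.5, 0.9, min_spacing = 30,
                               seed = 51)
  tracks <- lapply(1:3, function(s) simulate_end_counts(p, 200, seed = s))
  cmp <- compare_methylation(tracks, tracks, positions = p$positions)
  expect_equal(cmp$delta, rep(0, 4))
  expect_error(compare_methylation(tracks[1], tracks), "at least 2")
})

test_that("group comparison detects a simulated methylation difference", {
  pos <- 250L
  pA <- structure(list(ref_length = 500L, positions = pos, m = 0.9),
                  class = "methylation_profile")
  pB <- structure(list(ref_length = 500L, positions = pos, m = 0.7),
                  class = "methylation_profile")
  tracks_a <- lapply(1:5, function(s) simulate_end_counts(pA, 300, s))
  tracks_b <- lapply(1:5, function(s) simulate_end_counts(pB, 300,
                                                          s + 50))
  cmp <- compare_methylation(tracks_a, tracks_b, positions = pos)
  expect_lt(abs(cmp$delta - 0.2), 0.05)
  expect_lt(cmp$p, 0.05)
})

test_that("exact placement recovers true fragment positions", {
  ref <- random_reference(300, seed = 61)
  p0 <- gen_methylation_profile(300, 0, seed = 1)
  sim <- simulate_hydrolysis_reads(ref, p0, n_fragments = 500,
                                   cleavage_prob = 0.03, seed = 62)
  trim <- trim_polya(sim$seq, min_len = 20)
  placed <- place_reads_exact(trim$seq, ref)
  truth <- sim$start[trim$kept]
  # every placed read sits at its true origin (k-mer uniqueness permitting)
  expect_gt(nrow(placed), 0.9 * length(truth))
  expect_true(all(placed$start %in% truth))
  matched <- merge(
    data.frame(start = placed$start, n_placed = 1),
    data.frame(start = truth, n_true = 1), by = "start")
  expect_gt(nrow(matched), 0)
})
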