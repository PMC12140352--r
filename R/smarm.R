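# RiboMeth scoring from 5'-end read-start frequencies.
#
# 2'-O-methylation of the ribose at base i protects the phosphodiester bond
# 3' of it from alkaline hydrolysis, so read starts at position i+1 are
# depleted in proportion to the methylated fraction. The score reads that
# depletion out against the local read-start level.

#' Construct a per-position 5'-end count track
#'
#' @param n Integer vector of read-start counts, position 0 first.
#' @param ref_name Reference name.
#' @return An `end_count_track` object.
#' @export
end_count_track <- function(n, ref_name = "rDNA") {
  stopifnot(all(n >= 0), !anyNA(n))
  structure(list(ref_name = ref_name, n = as.integer(n),
                 ref_length = length(n)),
            class = "end_count_track")
}

#' Trim templated poly-A tails from reads
#'
#' Removes the leftmost occurrence of the adapter (a run of A's by default)
#' and everything 3' of it, allowing `max_error_rate` mismatches within the
#' adapter; reads shorter than `min_len` after trimming are dropped.
#'
#' @param seqs Character vector of read sequences.
#' @param adapter Adapter sequence; default ten A's.
#' @param min_len Minimum retained length after trimming.
#' @param max_error_rate Allowed mismatch fraction within the adapter.
#' @return List with `seq` (trimmed sequences of the kept reads) and
#'   `kept` (logical index into the input).
#' @export
trim_polya <- function(seqs, adapter = strrep("A", 10), min_len = 15,
                       max_error_rate = 0.1) {
  max_mm <- floor(nchar(adapter) * max_error_rate)
  pat <- Biostrings::DNAString(adapter)
  subject <- Biostrings::DNAStringSet(seqs)
  # exact occurrences take precedence; mismatched ones are a fallback so a
  # near-miss just upstream cannot pre-empt a perfect adapter hit
  exact <- Biostrings::startIndex(Biostrings::vmatchPattern(pat, subject))
  fuzzy <- if (max_mm > 0)
    Biostrings::startIndex(Biostrings::vmatchPattern(
      pat, subject, max.mismatch = max_mm)) else exact
  first_or_na <- function(s)
    if (is.null(s) || !length(s)) NA_integer_ else min(s)
  cut_at <- mapply(function(e, f) {
    ce <- first_or_na(e)
    if (!is.na(ce)) ce else first_or_na(f)
  }, exact, fuzzy)
  trimmed <- ifelse(is.na(cut_at), seqs, substr(seqs, 1L, cut_at - 1L))
  kept <- nchar(trimmed) >= min_len
  list(seq = trimmed[kept], kept = kept)
}

#' Place reads on a reference by exact matching
#'
#' Desk-scale stand-in for an aligner: each read is located by looking up
#' its first `k` bases in a hash of all reference k-mers and verifying the
#' full read matches at that position. Reads without a unique exact match
#' are dropped.
#'
#' @param seqs Character vector of (trimmed) read sequences.
#' @param reference Reference sequence (single string).
#' @param k Seed length for the k-mer lookup.
#' @return Aligned-read data frame (plus strand, single block per read).
#' @export
place_reads_exact <- function(seqs, reference, k = 20) {
  L <- nchar(reference)
  kmers <- substring(reference, seq_len(L - k + 1L),
                     seq_len(L - k + 1L) + k - 1L)
  seed <- substr(seqs, 1L, k)
  pos <- match(seed, kmers)  # first occurrence; reference k-mers ~unique
  ok <- !is.na(pos) & nchar(seqs) >= k
  full <- substring(reference, pos[ok], pos[ok] + nchar(seqs[ok]) - 1L)
  ok2 <- full == seqs[ok]
  idx <- which(ok)[ok2]
  start0 <- pos[idx] - 1L
  end0 <- start0 + nchar(seqs[idx])
  reads <- data.frame(query_id = paste0("placed_", seq_along(idx)),
                      ref_name = "rDNA", start = start0, end = end0,
                      strand = "+", is_unique = TRUE, is_duplicate = FALSE,
                      stringsAsFactors = FALSE)
  reads$blocks <- lapply(seq_along(idx),
                         function(i) cbind(start = start0[i], end = end0[i]))
  reads
}

#' Count read 5' ends per reference position
#'
#' Increments the track at each read's biological 5'-most aligned base
#' (first base of the first block on `+`, last base of the last block on
#' `-`). With `dedup`, reads sharing `(start, end, strand)` collapse to one
#' before counting (position-based PCR-duplicate removal); with
#' `unique_only`, reads not flagged uniquely mapped are excluded.
#'
#' @param reads Aligned-read data frame (see [read_alignments()]).
#' @param ref_length Reference length in bases.
#' @param dedup Collapse position-duplicates before counting.
#' @param unique_only Keep uniquely mapped reads only.
#' @param ref_name Reference name stored in the track.
#' @return An [end_count_track()].
#' @export
count_five_prime_ends <- function(reads, ref_length, dedup = FALSE,
                                  unique_only = FALSE, ref_name = "rDNA") {
  if (unique_only) reads <- reads[reads$is_unique, , drop = FALSE]
  if (dedup && nrow(reads)) {
    key <- paste(reads$start, reads$end, reads$strand)
    reads <- reads[!duplicated(key), , drop = FALSE]
  }
  pos <- five_prime_position(reads)
  if (length(pos) && (any(pos >= ref_length) || any(pos < 0)))
    stop("read 5' position outside [0, ref_length)")
  n <- tabulate(pos + 1L, nbins = ref_length)
  end_count_track(n, ref_name = ref_name)
}

#' Compute per-base RiboMeth scores from a 5'-end count track
#'
#' Candidate methylation at base `i` is read out at start-count position
#' `i + 1`: `S_i = 1 - n_{i+1} / F_i`, clipped to `[0, 1]`, where `F_i` is
#' the weighted mean of the counts over the `2 * k_flank` flanking
#' positions `{i+1-k_flank, ..., i}` and `{i+2, ..., i+1+k_flank}`
#' (position `i + 1` itself excluded). Weights are nearest-first:
#' `weights[1]` applies to the positions adjacent to `i + 1`. The score is
#' undefined (`coverage_ok = FALSE`) where `F_i < cov_min` or the window
#' leaves the track.
#'
#' @param track An [end_count_track()].
#' @param k_flank Flank half-width in positions (>= 1).
#' @param weights Positive weights of length `k_flank`, nearest-first.
#' @param cov_min Minimum flank coverage for a defined score.
#' @return A `score_track` data frame: `position` (0-based base index),
#'   `score`, `flank` (weighted flank mean) and `coverage_ok`; `score` is
#'   `NA` where undefined.
#' @export
ribometh_score <- function(track, k_flank = 2, weights = c(2, 1),
                           cov_min = 10) {
  stopifnot(inherits(track, "end_count_track"), k_flank >= 1,
            length(weights) == k_flank, all(weights > 0))
  n <- track$n
  L <- length(n)
  if (L < 2 * k_flank + 2)
    stop("track shorter than 2 * k_flank + 2 positions")
  # j = i + 1 in 0-based positions; R index of n_j is j + 1
  shift <- function(v, d) {   # v offset by d positions, NA outside
    if (d >= 0) c(v[(d + 1L):L], rep(NA_real_, d))
    else c(rep(NA_real_, -d), v[seq_len(L + d)])
  }
  num <- 0; den <- 2 * sum(weights)
  for (d in seq_len(k_flank))
    num <- num + weights[d] * (shift(n, d) + shift(n, -d))
  Fj <- num / den                       # flank mean around position j
  Sj <- 1 - n / Fj
  Sj <- pmin(pmax(Sj, 0), 1)
  ok <- !is.na(Fj) & Fj >= cov_min
  Sj[!ok] <- NA_real_
  # score for base i sits at j = i + 1: drop j = 0, append NA for i = L - 1
  score <- c(Sj[-1L], NA_real_)
  flank <- c(Fj[-1L], NA_real_)
  cov_ok <- c(ok[-1L], FALSE)
  structure(data.frame(position = 0:(L - 1L), score = score, flank = flank,
                       coverage_ok = cov_ok),
            class = c("score_track", "data.frame"))
}

#' Call 2'-O-methylated sites from a score track
#'
#' Returns the positions whose score is defined, at least `score_min`, and
#' whose flank coverage is at least `cov_min`, sorted by position. The
#' thresholds used are attached as attributes of the result.
#'
#' @param score_track Result of [ribometh_score()].
#' @param score_min Minimum score for a call.
#' @param cov_min Minimum mean flank coverage for a call.
#' @return Data frame `position`, `score`, `mean_flank_coverage`, `called`.
#' @export
call_methylated_sites <- function(score_track, score_min = 0.4,
                                  cov_min = 10) {
  ok <- !is.na(score_track$score) & score_track$score >= score_min &
    score_track$flank >= cov_min
  calls <- data.frame(position = score_track$position[ok],
                      score = score_track$score[ok],
                      mean_flank_coverage = score_track$flank[ok],
                      called = rep(TRUE, sum(ok)))
  calls <- calls[order(calls$position), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "score_min") <- score_min
  attr(calls, "cov_min") <- cov_min
  calls
}

#' Compare methylation scores between two replicate groups
#'
#' Scores each replicate track and, per position, reports the group mean
#' difference `delta = mean(A) - mean(B)` and a two-tailed two-sample
#' t-test p-value. Positions with an undefined score in any replicate are
#' reported `NA`; the p-value is `NA` where the t statistic is degenerate
#' (e.g. both groups constant).
#'
#' @param tracks_a,tracks_b Lists (length >= 2 each) of
#'   [end_count_track()] objects, one per replicate.
#' @param positions 0-based base positions to test; defaults to every
#'   position.
#' @param ... Passed to [ribometh_score()].
#' @return Data frame `position`, `delta`, `p`.
#' @export
compare_methylation <- function(tracks_a, tracks_b, positions = NULL, ...) {
  if (length(tracks_a) < 2L || length(tracks_b) < 2L)
    stop("each group needs at least 2 replicate tracks")
  score_of <- function(tr) ribometh_score(tr, ...)$score
  A <- vapply(tracks_a, score_of, numeric(tracks_a[[1]]$ref_length))
  B <- vapply(tracks_b, score_of, numeric(tracks_b[[1]]$ref_length))
  if (is.null(positions)) positions <- 0:(nrow(A) - 1L)
  idx <- positions + 1L
  delta <- rep(NA_real_, length(idx)); p <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    a <- A[idx[k], ]; b <- B[idx[k], ]
    if (anyNA(a) || anyNA(b)) next
    delta[k] <- mean(a) - mean(b)
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    p[k] <- if (is.null(tt)) NA_real_ else tt$p.value
  }
  data.frame(position = positions, delta = delta, p = p)
}
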