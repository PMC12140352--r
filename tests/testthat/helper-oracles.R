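# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles scan reference bases one by one and never share code
# with the implementation they check.

# Longest contiguous intronic run of a read, by per-base scan: mark every
# intronic reference base, then walk each aligned block base by base.
oracle_max_intron_run <- function(blocks, model) {
  introns <- do.call(rbind, model$introns)
  hi <- max(vapply(model$exons, function(e) max(e[, 2]), 0),
            blocks[, 2]) + 10
  intronic <- logical(hi)
  if (!is.null(introns) && nrow(introns))
    for (k in seq_len(nrow(introns)))
      intronic[(introns[k, 1] + 1):introns[k, 2]] <- TRUE
  best <- 0L
  for (bi in seq_len(nrow(blocks))) {
    run <- 0L
    for (pos in seq(blocks[bi, 1], blocks[bi, 2] - 1L)) {
      if (intronic[pos + 1L]) {
        run <- run + 1L
        best <- max(best, run)
      } else run <- 0L
    }
  }
  best
}

# Per-base exonic check: every aligned base inside the exon union of at
# least one transcript.
oracle_is_exonic <- function(blocks, model) {
  for (tx in names(model$exons)) {
    ex <- model$exons[[tx]]
    hi <- max(ex[, 2], blocks[, 2]) + 10
    inside <- logical(hi)
    for (k in seq_len(nrow(ex)))
      inside[(ex[k, 1] + 1):ex[k, 2]] <- TRUE
    all_in <- TRUE
    for (bi in seq_len(nrow(blocks)))
      for (pos in seq(blocks[bi, 1], blocks[bi, 2] - 1L))
        if (!inside[pos + 1L]) { all_in <- FALSE; break }
    if (all_in) return(TRUE)
  }
  FALSE
}

oracle_classify <- function(reads, model, min_more_than = 3) {
  vapply(seq_len(nrow(reads)), function(i) {
    b <- reads$blocks[[i]]
    if (oracle_max_intron_run(b, model) > min_more_than) "intron"
    else if (oracle_is_exonic(b, model)) "exonic"
    else "other"
  }, "")
}

# Per-base majority-overlap feature assignment for rDNA counting.
oracle_rdna_counts <- function(reads, features) {
  counts <- stats::setNames(integer(nrow(features) + 1L),
                            c(features$name, "unassigned"))
  hi <- max(features$end, vapply(reads$blocks, function(b) max(b[, 2]), 0))
  base_feat <- integer(hi)  # 0 = none
  for (k in seq_len(nrow(features)))
    base_feat[(features$start[k] + 1):features$end[k]] <- k
  for (i in seq_len(nrow(reads))) {
    b <- reads$blocks[[i]]
    per_feat <- integer(nrow(features))
    for (bi in seq_len(nrow(b)))
      for (pos in seq(b[bi, 1], b[bi, 2] - 1L)) {
        f <- base_feat[pos + 1L]
        if (f > 0L) per_feat[f] <- per_feat[f] + 1L
      }
    best <- max(per_feat)
    if (best > 0L && sum(per_feat == best) == 1L)
      counts[which.max(per_feat)] <- counts[which.max(per_feat)] + 1L
    else counts["unassigned"] <- counts["unassigned"] + 1L
  }
  counts
}

# Random multi-transcript gene model; transcripts occupy disjoint regions
# so intron intervals never abut across transcripts.
random_gene_model <- function(n_tx = 3, seed = 1) {
  withr::with_seed(seed, {
    recs <- list()
    for (t in seq_len(n_tx)) {
      offset <- (t - 1L) * 2000L
      n_ex <- sample(2:5, 1)
      pos <- offset + 50L
      for (e in seq_len(n_ex)) {
        w <- sample(30:80, 1)
        recs[[length(recs) + 1L]] <- data.frame(
          transcript_id = paste0("tx", t), gene_id = paste0("g", t),
          seqname = "chr1", start = pos, end = pos + w, strand = "+",
          stringsAsFactors = FALSE)
        pos <- pos + w + sample(20:100, 1)
      }
    }
    build_gene_model(do.call(rbind, recs))
  })
}

# Random single- or two-block reads over a gene model's span.
random_reads <- function(model, n, seed = 1) {
  span <- range(do.call(rbind, model$exons))
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n), function(i) {
      s <- sample(span[1]:(span[2] - 10L), 1)
      w1 <- sample(5:60, 1)
      if (runif(1) < 0.3) {
        gap <- sample(10:120, 1)
        w2 <- sample(5:60, 1)
        blocks <- cbind(start = c(s, s + w1 + gap),
                        end = c(s + w1, s + w1 + gap + w2))
      } else {
        blocks <- cbind(start = s, end = s + w1)
      }
      blocks
    })
    reads <- data.frame(query_id = paste0("r", seq_len(n)),
                        ref_name = "chr1",
                        start = vapply(recs, function(b) b[1, 1], 0),
                        end = vapply(recs, function(b) b[nrow(b), 2], 0),
                        strand = "+", is_unique = TRUE,
                        is_duplicate = FALSE, stringsAsFactors = FALSE)
    reads$blocks <- recs
    reads
  })
}

# Aligned-read data frame with given single-block coordinates.
make_reads <- function(start, end, strand = "+", unique = TRUE,
                       dup = FALSE, ref = "rDNA") {
  n <- length(start)
  reads <- data.frame(query_id = paste0("q", seq_len(n)), ref_name = ref,
                      start = start, end = end,
                      strand = rep_len(strand, n),
                      is_unique = rep_len(unique, n),
                      is_duplicate = rep_len(dup, n),
                      stringsAsFactors = FALSE)
  reads$blocks <- lapply(seq_len(n),
                         function(i) cbind(start = start[i], end = end[i]))
  reads
}
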