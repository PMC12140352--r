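# Intron-retention quantification. A read is an "effective intron read"
# when a single aligned block shares more than `min_more_than` contiguous
# bases with a single annotated intron; N-gaps in spliced reads contribute
# nothing. The per-sample retention statistic is
# intron / (intron + exonic), with intergenic reads excluded.

#' Build a gene model (exons + derived introns) from exon records
#'
#' Exons are grouped by transcript and sorted by start; introns are the
#' gaps `[exon_k.end, exon_{k+1}.start)` between consecutive exons.
#' Zero-length gaps (abutting exons) are dropped; overlapping exons within
#' one transcript are an error.
#'
#' @param annotation Data frame from [read_annotation()] (`transcript_id`,
#'   `gene_id`, `start`, `end`, `strand`, optional `seqname`).
#' @return A `gene_model`: list with `exons` and `introns` (per-transcript
#'   lists of two-column `[start, end)` matrices), `strand`, `gene_id`
#'   (both named by transcript) and `seqname`.
#' @export
build_gene_model <- function(annotation) {
  stopifnot(nrow(annotation) > 0)
  by_tx <- split(annotation, annotation$transcript_id)
  exons <- list(); introns <- list(); strand <- character(0)
  gene_id <- character(0)
  for (tx in names(by_tx)) {
    df <- by_tx[[tx]]
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)]))
      stop("overlapping exons in transcript ", tx)
    ex <- cbind(start = df$start, end = df$end)
    if (nrow(ex) > 1L) {
      gap_start <- ex[-nrow(ex), 2]
      gap_end <- ex[-1L, 1]
      keep <- gap_end > gap_start
      intr <- cbind(start = gap_start[keep], end = gap_end[keep])
    } else {
      intr <- cbind(start = integer(0), end = integer(0))
    }
    exons[[tx]] <- ex
    introns[[tx]] <- intr
    strand[tx] <- df$strand[1]
    gene_id[tx] <- df$gene_id[1]
  }
  structure(list(exons = exons, introns = introns, strand = strand,
                 gene_id = gene_id,
                 seqname = if ("seqname" %in% names(annotation))
                   annotation$seqname[1] else "chr"),
            class = "gene_model")
}

# Maximum contiguous intronic overlap of a read: the largest intersection
# between any single aligned block and any single intron, in bases.
max_contiguous_intron_overlap <- function(read_blocks, model) {
  introns <- do.call(rbind, model$introns)
  if (is.null(introns) || nrow(introns) == 0L) return(0)
  best <- 0
  for (bi in seq_len(nrow(read_blocks))) {
    ov <- pmin(read_blocks[bi, 2], introns[, 2]) -
      pmax(read_blocks[bi, 1], introns[, 1])
    best <- max(best, ov)
  }
  max(0, best)
}

#' Is a read an effective intron read?
#'
#' `TRUE` iff some single aligned block shares strictly more than
#' `min_more_than` contiguous bases with some single intron of the model
#' (default: at least 4 contiguous intronic bases). Contiguity is within
#' one block and one intron; spliced reads whose N-gap spans an intron
#' contribute nothing.
#'
#' @param read One row of an aligned-read data frame (or a list with a
#'   `blocks` matrix).
#' @param model A `gene_model`.
#' @param min_more_than Overlap must exceed this many bases.
#' @return Logical scalar.
#' @export
is_effective_intron_read <- function(read, model, min_more_than = 3) {
  blocks <- if (is.data.frame(read)) read$blocks[[1]] else read$blocks
  max_contiguous_intron_overlap(blocks, model) > min_more_than
}

#' Classify reads as effective-intron, exonic or other
#'
#' A read is `intron` under the contiguous-overlap rule; otherwise it is
#' `exonic` iff every aligned base lies within the exon union of at least
#' one single transcript (strand-agnostic); anything else (intergenic or
#' partially overlapping no transcript) is `other`.
#'
#' @param reads Aligned-read data frame.
#' @param model A `gene_model`.
#' @param min_more_than Rule threshold (see
#'   [is_effective_intron_read()]).
#' @return Character vector in `c("intron", "exonic", "other")`, one per
#'   read.
#' @export
classify_intron_reads <- function(reads, model, min_more_than = 3) {
  vapply(seq_len(nrow(reads)), function(i) {
    blocks <- reads$blocks[[i]]
    if (max_contiguous_intron_overlap(blocks, model) > min_more_than)
      return("intron")
    contained <- any(vapply(model$exons, function(ex)
      all(vapply(seq_len(nrow(blocks)), function(bi)
        covered_by_union(blocks[bi, 1], blocks[bi, 2], ex), NA)), NA))
    if (contained) "exonic" else "other"
  }, "")
}

# Is [start, end) fully covered by the union of sorted disjoint intervals?
covered_by_union <- function(start, end, intervals) {
  pos <- start
  for (k in seq_len(nrow(intervals))) {
    if (intervals[k, 1] <= pos && pos < intervals[k, 2])
      pos <- intervals[k, 2]
    if (pos >= end) return(TRUE)
  }
  pos >= end
}

#' Count exonic reads
#'
#' Number of reads whose aligned bases all lie within the exon union of at
#' least one transcript and that are not effective intron reads.
#'
#' @inheritParams classify_intron_reads
#' @return Integer count.
#' @export
count_exonic_reads <- function(reads, model, min_more_than = 3) {
  sum(classify_intron_reads(reads, model, min_more_than) == "exonic")
}

#' Per-sample intron-retention statistic
#'
#' Classifies reads with [classify_intron_reads()] and reports
#' `ratio = n_intron / (n_intron + n_exonic)`; reads in neither class are
#' excluded from both numerator and denominator. With zero classified
#' reads the ratio is `NA` and the result is flagged.
#'
#' @param reads Aligned-read data frame.
#' @param model A `gene_model`.
#' @param sample_id Label carried into the result.
#' @param min_more_than Rule threshold.
#' @return One-row data frame: `sample_id`, `n_effective_intron`,
#'   `n_exonic`, `n_other`, `ratio`, `min_more_than`.
#' @export
intronic_ratio <- function(reads, model, sample_id = "sample",
                           min_more_than = 3) {
  cls <- classify_intron_reads(reads, model, min_more_than)
  n_in <- sum(cls == "intron"); n_ex <- sum(cls == "exonic")
  ratio <- if (n_in + n_ex > 0) n_in / (n_in + n_ex) else NA_real_
  data.frame(sample_id = sample_id, n_effective_intron = n_in,
             n_exonic = n_ex, n_other = sum(cls == "other"),
             ratio = ratio, min_more_than = min_more_than,
             stringsAsFactors = FALSE)
}
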