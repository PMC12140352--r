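# ERCC spike-in quantification of single-embryo / blastomere count
# matrices. The spike amount is constant per sample, so the per-sample
# spike total tracks capture efficiency; dividing endogenous quantities by
# the spike-derived scale factor puts samples on an absolute
# (per-embryo) scale.

#' Construct a gene-by-sample count matrix with gene annotation
#'
#' A light container in the style of edgeR's `DGEList`: an integer count
#' matrix (genes x samples, dimnames required) plus a per-gene annotation
#' data frame carrying `biotype` (one of `mRNA`, `rRNA`, `snoRNA`, `ERCC`,
#' `other`) and `length` in bases.
#'
#' @param counts Non-negative integer matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param biotype Named character vector (names = gene ids).
#' @param length Named numeric vector of gene lengths (> 0).
#' @return A `count_matrix` object: list with `counts` and `genes`.
#' @export
count_matrix <- function(counts, biotype, length) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  ids <- rownames(counts)
  stopifnot(all(ids %in% names(biotype)), all(ids %in% names(length)))
  len <- as.numeric(length[ids])
  if (any(len <= 0)) stop("gene lengths must be positive")
  structure(list(counts = counts,
                 genes = data.frame(gene_id = ids,
                                    biotype = as.character(biotype[ids]),
                                    length = len,
                                    row.names = ids,
                                    stringsAsFactors = FALSE)),
            class = "count_matrix")
}

is_ercc_row <- function(mat) mat$genes$biotype == "ERCC"

#' Per-sample ERCC scale factors
#'
#' `f_s` is the sample's total spike-in count divided by the median spike
#' total across samples, so a sample with median capture has `f_s = 1`.
#' Normalized values are obtained as `X_s / f_s`.
#'
#' @param mat A [count_matrix()] containing at least one ERCC row.
#' @return Named numeric vector of scale factors, one per sample.
#' @export
ercc_scale_factors <- function(mat) {
  ercc <- mat$counts[is_ercc_row(mat), , drop = FALSE]
  if (nrow(ercc) == 0L) stop("no ERCC rows in matrix")
  totals <- colSums(ercc)
  if (any(totals == 0))
    stop("zero ERCC total in sample(s): ",
         paste(names(totals)[totals == 0], collapse = ", "))
  totals / median(totals)
}

#' Spike-normalized total endogenous RNA per sample
#'
#' @param mat A [count_matrix()].
#' @param factors Scale factors from [ercc_scale_factors()] computed on the
#'   same matrix.
#' @return Named numeric vector: sum of non-ERCC counts per sample divided
#'   by its scale factor.
#' @export
total_rna_abundance <- function(mat, factors) {
  endo <- mat$counts[!is_ercc_row(mat), , drop = FALSE]
  colSums(endo) / factors[colnames(endo)]
}

#' Transcripts-per-million matrix
#'
#' `rate = count / length` per gene; each sample's rates are rescaled to
#' sum to 1e6 over the genes in the denominator. ERCC rows are excluded
#' from the denominator by default (their TPM values are still reported on
#' the endogenous scale).
#'
#' @param mat A [count_matrix()] with lengths set for all genes.
#' @param exclude_ercc Exclude spike-in rows from the per-sample
#'   denominator.
#' @return Numeric matrix of TPM values, same dimensions as the counts.
#' @export
compute_tpm <- function(mat, exclude_ercc = TRUE) {
  rate <- mat$counts / mat$genes$length
  denom_rows <- if (exclude_ercc) !is_ercc_row(mat) else
    rep(TRUE, nrow(rate))
  denom <- colSums(rate[denom_rows, , drop = FALSE])
  if (any(denom == 0))
    stop("all-zero sample(s): ",
         paste(colnames(rate)[denom == 0], collapse = ", "))
  sweep(rate, 2, denom, "/") * 1e6
}

#' Spike-normalized abundance of a biotype class
#'
#' Sums counts over the genes of one biotype and divides by the per-sample
#' scale factor; with `per_gene = TRUE` returns each gene's normalized
#' value instead (for per-snoRNA scatter comparisons).
#'
#' @param mat A [count_matrix()].
#' @param factors Scale factors from [ercc_scale_factors()].
#' @param biotype Biotype label present in the matrix.
#' @param per_gene Return a genes-by-samples matrix instead of the class
#'   total.
#' @return Named vector (or matrix when `per_gene`) of normalized values.
#' @export
class_abundance <- function(mat, factors, biotype, per_gene = FALSE) {
  rows <- mat$genes$biotype == biotype
  if (!any(rows)) stop("biotype '", biotype, "' absent from matrix")
  sub <- mat$counts[rows, , drop = FALSE]
  norm <- sweep(sub, 2, factors[colnames(sub)], "/")
  if (per_gene) norm else colSums(norm)
}

#' Assign reads to rDNA features by majority overlap
#'
#' Each read is assigned to the feature with which its aligned blocks share
#' the largest total overlap; ties (including zero overlap everywhere) are
#' left unassigned. Feature intervals must not overlap one another.
#'
#' @param reads Aligned-read data frame on the rDNA contig.
#' @param features Data frame with `name`, `start`, `end`
#'   (0-based half-open, non-overlapping).
#' @param unique_only Exclude reads not flagged uniquely mapped.
#' @return Named integer vector of per-feature counts plus an
#'   `unassigned` element.
#' @export
quantify_rdna <- function(reads, features, unique_only = TRUE) {
  stopifnot(all(c("name", "start", "end") %in% names(features)),
            all(features$end > features$start))
  o <- order(features$start)
  f <- features[o, , drop = FALSE]
  if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)]))
    stop("overlapping feature definitions")
  if (unique_only) reads <- reads[reads$is_unique, , drop = FALSE]
  counts <- setNames(integer(nrow(features) + 1L),
                     c(features$name, "unassigned"))
  for (i in seq_len(nrow(reads))) {
    b <- reads$blocks[[i]]
    ov <- vapply(seq_len(nrow(features)), function(k)
      sum(pmax(0, pmin(b[, 2], features$end[k]) -
                    pmax(b[, 1], features$start[k]))), 0)
    best <- max(ov)
    if (best > 0L && sum(ov == best) == 1L) {
      counts[which.max(ov)] <- counts[which.max(ov)] + 1L
    } else {
      counts["unassigned"] <- counts["unassigned"] + 1L
    }
  }
  counts
}

#' Spike-normalized log2 fold change between sample groups
#'
#' `LFC_g = log2((meanA_g + pseudocount) / (meanB_g + pseudocount))` on
#' counts divided per sample by the ERCC scale factor. An effect size
#' only; no dispersion model or significance test is attached.
#'
#' @param mat A [count_matrix()].
#' @param factors Scale factors from [ercc_scale_factors()].
#' @param group_a,group_b Non-empty character vectors of sample ids.
#' @param pseudocount Non-negative value added to both group means.
#' @return Named numeric vector of per-gene log2 fold changes
#'   (endogenous genes only).
#' @export
log2_fold_change <- function(mat, factors, group_a, group_b,
                             pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  stopifnot(all(c(group_a, group_b) %in% colnames(mat$counts)))
  endo <- !is_ercc_row(mat)
  norm <- sweep(mat$counts[endo, , drop = FALSE], 2,
                factors[colnames(mat$counts)], "/")
  mean_a <- rowMeans(norm[, group_a, drop = FALSE])
  mean_b <- rowMeans(norm[, group_b, drop = FALSE])
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}
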