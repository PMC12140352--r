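#' @importFrom stats median rpois runif rlnorm setNames pchisq t.test
#' @importFrom utils read.delim write.table
NULL

# All coordinates inside the package are 0-based half-open [start, end).
# SAM (1-based) and GTF (1-based inclusive) are converted at parse/write time
# and nowhere else.

REF_CIGAR_OPS <- c("M", "D", "N", "=", "X")

#' Parse SAM-format alignments into aligned-read records
#'
#' Reads SAM text (a file path or a character vector of lines) into a
#' data frame of aligned reads with 0-based half-open coordinates and
#' reference-consuming blocks decomposed from the CIGAR string. `N`
#' (skipped-region) operators open a new block, so spliced reads carry one
#' block per aligned segment. Unmapped records (FLAG bit 0x4) are skipped.
#'
#' Uniqueness of mapping is taken from the `NH` tag when present (`NH == 1`);
#' when absent, reads with MAPQ at or above `mapq_min` are treated as
#' uniquely mapped.
#'
#' @param sam Path to a SAM file, or a character vector of SAM lines.
#' @param unique_only Drop reads not flagged uniquely mapped.
#' @param mapq_min MAPQ floor used as the uniqueness criterion when the
#'   `NH` tag is absent.
#' @return A data frame with one row per mapped read: `query_id`,
#'   `ref_name`, `start` (0-based), `end` (past-the-end of the last block),
#'   `strand`, `is_unique`, `is_duplicate`, and a `blocks` list column of
#'   two-column matrices of `[start, end)` reference intervals.
#' @export
read_alignments <- function(sam, unique_only = FALSE, mapq_min = 30) {
  lines <- if (length(sam) == 1L && file.exists(sam)) readLines(sam) else sam
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  out <- vector("list", length(body_idx))
  keep <- logical(length(body_idx))
  for (k in seq_along(body_idx)) {
    ln <- body_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop("SAM line ", ln, ": fewer than 6 fields")
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stop("SAM line ", ln, ": non-numeric FLAG")
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(pos) || pos < 1L)
      stop("SAM line ", ln, ": invalid POS '", f[4], "'")
    blocks <- cigar_to_blocks(f[6], pos - 1L, line = ln)
    mapq <- suppressWarnings(as.integer(f[5]))
    nh <- NA_integer_
    if (length(f) > 11L) {
      tag <- grep("^NH:i:", f[12:length(f)], value = TRUE)
      if (length(tag)) nh <- as.integer(sub("^NH:i:", "", tag[1]))
    }
    is_unique <- if (!is.na(nh)) nh == 1L else !is.na(mapq) && mapq >= mapq_min
    out[[k]] <- list(
      query_id = f[1], ref_name = f[3], start = blocks[1L, 1L],
      end = blocks[nrow(blocks), 2L],
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      is_unique = is_unique,
      is_duplicate = bitwAnd(flag, 1024L) != 0L,
      blocks = blocks)
    keep[k] <- TRUE
  }
  out <- out[keep]
  reads <- data.frame(
    query_id = vapply(out, `[[`, "", "query_id"),
    ref_name = vapply(out, `[[`, "", "ref_name"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    strand = vapply(out, `[[`, "", "strand"),
    is_unique = vapply(out, `[[`, NA, "is_unique"),
    is_duplicate = vapply(out, `[[`, NA, "is_duplicate"),
    stringsAsFactors = FALSE)
  reads$blocks <- lapply(out, `[[`, "blocks")
  if (unique_only) reads <- reads[reads$is_unique, , drop = FALSE]
  rownames(reads) <- NULL
  reads
}

# Decompose a CIGAR string into 0-based half-open reference blocks.
# M/=/X and D extend the current block; N closes it and opens a new one;
# I/S/H consume no reference.
cigar_to_blocks <- function(cigar, start0, line = NA) {
  where <- if (is.na(line)) "" else paste0("SAM line ", line, ": ")
  if (is.na(cigar) || cigar == "" || cigar == "*")
    stop(where, "missing CIGAR")
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop(where, "malformed CIGAR '", cigar, "'")
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^\\d+", "", toks)
  if (any(ops == "P"))
    stop(where, "unsupported CIGAR operator 'P'")
  starts <- integer(0); ends <- integer(0)
  cur_start <- start0; cur <- start0; open <- FALSE
  for (i in seq_along(ops)) {
    op <- ops[i]
    if (op %in% REF_CIGAR_OPS) {
      if (op == "N") {
        if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
        cur <- cur + lens[i]
        cur_start <- cur; open <- FALSE
      } else {
        cur <- cur + lens[i]; open <- TRUE
      }
    }
  }
  if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
  if (!length(starts))
    stop(where, "CIGAR '", cigar, "' consumes no reference bases")
  cbind(start = starts, end = ends)
}

#' Write aligned reads as SAM text
#'
#' Emits a minimal SAM representation (one `@SQ` header line per reference)
#' that round-trips through [read_alignments()]: `start`, `blocks` and
#' `strand` are preserved exactly. Blocks separated by gaps become `N`
#' operators; uniqueness is encoded in the `NH` tag and duplicate status in
#' FLAG bit 0x400.
#'
#' @param reads Data frame as returned by [read_alignments()].
#' @param path Output file path.
#' @param ref_lengths Named integer vector of reference lengths for the
#'   header; inferred from block ends when omitted.
#' @export
write_alignments <- function(reads, path, ref_lengths = NULL) {
  if (is.null(ref_lengths)) {
    ref_lengths <- vapply(
      split(reads$end, reads$ref_name), max, 0L)
  }
  hdr <- sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                 as.integer(ref_lengths))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    b <- reads$blocks[[i]]
    seg <- sprintf("%dM", b[, 2] - b[, 1])
    if (nrow(b) > 1L) {
      gaps <- sprintf("%dN", b[-1L, 1] - b[-nrow(b), 2])
      cigar <- paste0(paste0(seg[-length(seg)], gaps, collapse = ""),
                      seg[length(seg)])
    } else cigar <- seg
    flag <- 0L
    if (reads$strand[i] == "-") flag <- flag + 16L
    if (isTRUE(reads$is_duplicate[i])) flag <- flag + 1024L
    paste(reads$query_id[i], flag, reads$ref_name[i],
          reads$start[i] + 1L, 255L, cigar, "*", 0L, 0L, "*", "*",
          sprintf("NH:i:%d", if (isTRUE(reads$is_unique[i])) 1L else 2L),
          sep = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read exon records from a GTF annotation
#'
#' Consumes only rows with feature type `exon` and converts the GTF 1-based
#' inclusive coordinates to the package's 0-based half-open convention.
#' `transcript_id` and `gene_id` are extracted from the attribute column.
#'
#' @param gtf Path to a GTF file, or a character vector of GTF lines.
#' @return Data frame with columns `transcript_id`, `gene_id`, `seqname`,
#'   `start`, `end` (0-based half-open) and `strand`.
#' @export
read_annotation <- function(gtf) {
  lines <- if (length(gtf) == 1L && file.exists(gtf)) readLines(gtf) else gtf
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  recs <- lapply(body_idx, function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("GTF line ", ln, ": fewer than 9 fields")
    if (f[3] != "exon") return(NULL)
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || start < 1L)
      stop("GTF line ", ln, ": invalid start '", f[4], "' (GTF is 1-based)")
    if (is.na(end) || end < start)
      stop("GTF line ", ln, ": end < start")
    if (!f[7] %in% c("+", "-"))
      stop("GTF line ", ln, ": strand must be + or -")
    tid <- gtf_attribute(f[9], "transcript_id")
    if (is.na(tid))
      stop("GTF line ", ln, ": exon row lacks transcript_id")
    gid <- gtf_attribute(f[9], "gene_id")
    data.frame(transcript_id = tid,
               gene_id = if (is.na(gid)) tid else gid,
               seqname = f[1], start = start - 1L, end = end,
               strand = f[7], stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, NA)]
  if (!length(recs))
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      seqname = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

gtf_attribute <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, "[ =]+\"?([^\";]+)\"?"), attr))[[1]]
  if (length(m) < 2L) NA_character_ else m[2]
}

#' Read or write a gene-by-sample count matrix as TSV
#'
#' The on-disk layout is one header row of sample ids preceded by the
#' annotation columns `gene_id`, `biotype`, `length`, then one row per gene.
#'
#' @param path File path.
#' @return For the reader, a [count_matrix()] object.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "biotype", "length") %in% names(df)))
  samples <- setdiff(names(df), c("gene_id", "biotype", "length"))
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$gene_id
  count_matrix(counts, biotype = setNames(df$biotype, df$gene_id),
               length = setNames(df$length, df$gene_id))
}

#' @rdname read_count_matrix
#' @param mat A [count_matrix()] object.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat$counts),
                   biotype = mat$genes$biotype,
                   length = mat$genes$length,
                   mat$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-position track as bedGraph-style TSV
#'
#' Columns are `ref`, `start`, `end`, `value` with 0-based half-open
#' single-base intervals; positions with `NA` value are omitted.
#'
#' @param ref_name Reference sequence name.
#' @param values Per-position numeric vector (position 0 first).
#' @param path Output path.
#' @export
write_track <- function(ref_name, values, path) {
  pos <- which(!is.na(values)) - 1L
  df <- data.frame(ref = ref_name, start = pos, end = pos + 1L,
                   value = values[pos + 1L])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param seqs Character vector of read sequences.
#' @param path Output path.
#' @param ids Read identifiers; defaults to `read_1 ... read_n`.
#' @export
write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read FASTQ sequences
#'
#' @param path FASTQ file path.
#' @return Character vector of sequences named by read id.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

# 0-based position of the biological 5' end of a read: the first base of the
# first block on +, the last base of the last block on -.
five_prime_position <- function(reads) {
  ifelse(reads$strand == "-", reads$end - 1L, reads$start)
}
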