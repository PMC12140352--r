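# Generators for every input the pipeline consumes, each with recorded truth.
# All are deterministic under `seed` (the caller's RNG state is untouched).

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

#' Generate a ground-truth 2'-O-methylation profile
#'
#' Places `n_sites` methylated positions on a reference of `ref_length`
#' bases, pairwise at least `min_spacing` bases apart and at least
#' `min_spacing` bases away from either reference end (so every site has a
#' complete flanking window for scoring). Methylated fractions are drawn
#' uniformly in `[fraction_low, fraction_high]`; all other positions have
#' fraction 0.
#'
#' @param ref_length Reference length in bases.
#' @param n_sites Number of methylated sites.
#' @param fraction_low,fraction_high Range of methylated fractions.
#' @param min_spacing Minimum pairwise distance between sites (bases).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `methylation_profile`: list with `ref_length`, `positions`
#'   (0-based, sorted) and `m` (fractions, parallel to `positions`).
#' @export
gen_methylation_profile <- function(ref_length, n_sites, fraction_low = 0.2,
                                    fraction_high = 1.0, min_spacing = 20,
                                    seed = 1) {
  stopifnot(fraction_low >= 0, fraction_high <= 1,
            fraction_low <= fraction_high, min_spacing >= 1)
  if (n_sites * min_spacing > ref_length)
    stop("infeasible spacing: n_sites * min_spacing exceeds ref_length")
  if (n_sites == 0L) {
    return(structure(list(ref_length = as.integer(ref_length),
                          positions = integer(0), m = numeric(0)),
                     class = "methylation_profile"))
  }
  lo <- min_spacing
  hi <- ref_length - 1L - min_spacing
  # map to a gap-free space so pairwise spacing holds by construction
  span <- hi - lo - (n_sites - 1L) * min_spacing
  if (span < 0)
    stop("infeasible spacing: sites do not fit inside the reference interior")
  with_seed_(seed, {
    u <- sort(sample.int(span + 1L, n_sites, replace = FALSE) - 1L)
    positions <- as.integer(lo + u + (seq_len(n_sites) - 1L) * min_spacing)
    m <- runif(n_sites, fraction_low, fraction_high)
  })
  structure(list(ref_length = as.integer(ref_length),
                 positions = positions, m = m),
            class = "methylation_profile")
}

# Dense per-base methylation vector, 1-based index j <-> 0-based base j-1.
profile_vector <- function(profile) {
  v <- numeric(profile$ref_length)
  v[profile$positions + 1L] <- profile$m
  v
}

#' Simulate 5'-end count tracks under the protection model (Poisson mode)
#'
#' Alkaline hydrolysis cleaves the phosphodiester bond 3' of each base
#' unless the ribose is 2'-O-methylated; a cleavage at the bond after base
#' `i` creates a read 5' end at position `i + 1`. Counts are drawn
#' independently as `n_j ~ Poisson(depth * (1 - m_{j-1}))`, with
#' `n_0 ~ Poisson(depth)` (the reference 5' terminus is always a start).
#'
#' @param profile A `methylation_profile`.
#' @param depth Expected read starts per unprotected position.
#' @param seed Integer seed.
#' @param ref_name Reference name stored in the track.
#' @return An `end_count_track`: list with `ref_name`, `n` (integer counts,
#'   position 0 first) and `ref_length`.
#' @export
simulate_end_counts <- function(profile, depth, seed = 1,
                                ref_name = "rDNA") {
  stopifnot(depth > 0)
  m <- profile_vector(profile)
  L <- profile$ref_length
  lambda <- c(depth, depth * (1 - m[seq_len(L - 1L)]))
  n <- with_seed_(seed, rpois(L, lambda))
  end_count_track(n, ref_name = ref_name)
}

#' Simulate alkaline-hydrolysis fragmentation into FASTQ-style reads
#'
#' Full mechanistic mode: molecules of the reference sequence are hydrolysed
#' bond by bond (bond after base `i` cleaved with probability
#' `cleavage_prob * (1 - m_i)`), fragments between consecutive cleavage
#' points are size-selected to `[size_min, size_max]`, and each retained
#' fragment is emitted with `polyA_len` templated A's appended (emulating
#' the poly-adenylation step of small-RNA library construction). Molecules
#' are drawn until `n_fragments` fragments have been retained.
#'
#' @param reference_seq Reference sequence (single character string).
#' @param profile A `methylation_profile` on that reference.
#' @param n_fragments Number of retained fragments to emit.
#' @param cleavage_prob Per-bond cleavage probability for unmethylated
#'   bases; must be strictly inside (0, 1).
#' @param size_min,size_max Retained fragment size window (before poly-A).
#' @param polyA_len Number of A's appended to each fragment.
#' @param seed Integer seed.
#' @return List with `seq` (character vector of reads), `start` (true
#'   0-based 5' start of each fragment) and `length` (fragment length
#'   before poly-A).
#' @export
simulate_hydrolysis_reads <- function(reference_seq, profile, n_fragments,
                                      cleavage_prob = 0.02, size_min = 20,
                                      size_max = 60, polyA_len = 10,
                                      seed = 1) {
  if (cleavage_prob <= 0 || cleavage_prob >= 1)
    stop("cleavage_prob must be strictly between 0 and 1")
  L <- nchar(reference_seq)
  stopifnot(size_min <= size_max, size_max <= L,
            profile$ref_length == L)
  m <- profile_vector(profile)
  p_cut <- cleavage_prob * (1 - m[seq_len(L - 1L)])  # bond after base j-1
  acc <- list(); n_acc <- 0L
  with_seed_(seed, {
    while (n_acc < n_fragments) {
      batch <- 200L
      u <- matrix(runif(batch * (L - 1L)), nrow = batch)
      for (b in seq_len(batch)) {
        cuts <- which(u[b, ] < p_cut)          # 0-based start positions
        fs <- c(0L, cuts)
        fl <- diff(c(0L, cuts, L))
        ok <- fl >= size_min & fl <= size_max
        if (any(ok)) {
          acc[[length(acc) + 1L]] <- cbind(fs[ok], fl[ok])
          n_acc <- n_acc + sum(ok)
        }
        if (n_acc >= n_fragments) break
      }
    }
  })
  frag <- do.call(rbind, acc)
  starts <- frag[seq_len(n_fragments), 1]
  lens <- frag[seq_len(n_fragments), 2]
  seqs <- paste0(substring(reference_seq, starts + 1L, starts + lens),
                 strrep("A", polyA_len))
  list(seq = seqs, start = starts, length = lens)
}

#' Generate a random nucleotide reference sequence
#'
#' @param length Sequence length in bases.
#' @param seed Integer seed.
#' @return A character string over A/C/G/T.
#' @export
random_reference <- function(length, seed = 1) {
  with_seed_(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
}

#' Describe a simulated single-embryo cohort
#'
#' Captures the experimental design the cohort simulator realizes:
#' developmental stages, group sizes, gene panel sizes per biotype, ERCC
#' spike-in rows, and the genotype effect (per-biotype down-regulation in
#' null samples plus a zeroed target gene and deleted-region counts).
#' Defaults describe a two-stage intercross cohort in which null embryos
#' lose most mRNA, rRNA and snoRNA abundance while spike-ins stay constant
#' per embryo.
#'
#' @param stages Stage labels.
#' @param n_null,n_control Samples per genotype per stage.
#' @param n_genes Named vector of gene counts per biotype
#'   (`mRNA`, `rRNA`, `snoRNA`).
#' @param n_ercc Number of ERCC spike-in rows (> 0).
#' @param downreg Named vector of per-biotype down-regulation factors in
#'   (0, 1] applied to null samples.
#' @param target_gene Identifier of the knockout target gene, zeroed in
#'   null samples.
#' @param spike_mean Mean spike-in count per ERCC gene per sample (scaled
#'   only by capture efficiency; models a fixed spike volume per embryo).
#' @param capture_sd Standard deviation (log scale) of the per-sample
#'   capture efficiency.
#' @param region_lambda Mean deleted-region read count in control samples.
#' @param seed Integer seed.
#' @export
cohort_design <- function(stages = c("E2.5", "E3.5"), n_null = 10,
                          n_control = 10,
                          n_genes = c(mRNA = 200, rRNA = 5, snoRNA = 50),
                          n_ercc = 50,
                          downreg = c(mRNA = 0.3, rRNA = 0.5, snoRNA = 0.4),
                          target_gene = "target_gene", spike_mean = 200,
                          capture_sd = 0.25, region_lambda = 30, seed = 1) {
  stopifnot(all(downreg > 0), all(downreg <= 1),
            all(n_genes >= 0), n_null >= 0, n_control >= 0)
  if (n_ercc == 0) stop("n_ercc must be > 0: normalization impossible")
  structure(list(stages = stages, n_null = n_null, n_control = n_control,
                 n_genes = n_genes, n_ercc = n_ercc, downreg = downreg,
                 target_gene = target_gene, spike_mean = spike_mean,
                 capture_sd = capture_sd, region_lambda = region_lambda,
                 seed = seed),
            class = "cohort_design")
}

#' Simulate an ERCC-spiked single-embryo count matrix with known truth
#'
#' Per-gene baseline means are drawn once per cohort (log-normal); each
#' sample's endogenous counts are Poisson around
#' `mean * capture_efficiency * downreg` (down-regulation applied to null
#' samples only), while ERCC rows scale with capture efficiency alone —
#' the spike amount is constant per sample. The target gene is zeroed in
#' nulls, and a per-sample deleted-region read count is 0 in nulls and
#' Poisson(`region_lambda`) in controls.
#'
#' @param design A [cohort_design()].
#' @return List with `counts` (a [count_matrix()]), `meta` (data frame:
#'   `sample_id`, `stage`, `genotype`, `region_count`) and `truth`
#'   (gene means, capture efficiencies, applied factors).
#' @export
simulate_embryo_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  biotypes <- rep(names(design$n_genes), design$n_genes)
  gene_ids <- unlist(lapply(names(design$n_genes), function(b)
    sprintf("%s_%04d", b, seq_len(design$n_genes[[b]]))), use.names = FALSE)
  # first mRNA row doubles as the knockout target
  if (design$n_genes[["mRNA"]] >= 1L)
    gene_ids[match("mRNA", biotypes)] <- design$target_gene
  ercc_ids <- sprintf("ERCC-%05d", seq_len(design$n_ercc))
  all_ids <- c(gene_ids, ercc_ids)
  all_bio <- c(biotypes, rep("ERCC", design$n_ercc))

  n_per_stage <- design$n_null + design$n_control
  n_samples <- n_per_stage * length(design$stages)
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    stage = rep(design$stages, each = n_per_stage),
    genotype = rep(rep(c("null", "control"),
                       c(design$n_null, design$n_control)),
                   length(design$stages)),
    stringsAsFactors = FALSE)

  with_seed_(design$seed, {
    gene_mean <- rlnorm(length(gene_ids), meanlog = log(50), sdlog = 1)
    ercc_mean <- rlnorm(design$n_ercc, meanlog = log(design$spike_mean),
                        sdlog = 0.5)
    gene_len <- round(rlnorm(length(all_ids), meanlog = log(1500),
                             sdlog = 0.4))
    eff <- rlnorm(n_samples, meanlog = 0, sdlog = design$capture_sd)
    counts <- matrix(0L, nrow = length(all_ids), ncol = n_samples,
                     dimnames = list(all_ids, meta$sample_id))
    region_count <- integer(n_samples)
    for (s in seq_len(n_samples)) {
      fac <- rep(1, length(gene_ids))
      if (meta$genotype[s] == "null")
        fac <- design$downreg[biotypes]
      lam <- gene_mean * eff[s] * fac
      counts[seq_along(gene_ids), s] <- rpois(length(gene_ids), lam)
      counts[gene_ids == design$target_gene & meta$genotype[s] == "null",
             s] <- 0L
      counts[length(gene_ids) + seq_len(design$n_ercc), s] <-
        rpois(design$n_ercc, ercc_mean * eff[s])
      region_count[s] <- if (meta$genotype[s] == "null") 0L else
        rpois(1L, design$region_lambda)
    }
  })
  meta$region_count <- region_count
  mat <- count_matrix(counts,
                      biotype = setNames(all_bio, all_ids),
                      length = setNames(pmax(gene_len, 100), all_ids))
  list(counts = mat, meta = meta,
       truth = list(gene_mean = setNames(gene_mean, gene_ids),
                    ercc_mean = setNames(ercc_mean, ercc_ids),
                    capture_eff = setNames(eff, meta$sample_id),
                    downreg = design$downreg,
                    target_gene = design$target_gene))
}

#' Simulate toy alignments with controlled intronic overlap
#'
#' Emits `n_exonic` single-block reads fully contained in exons and
#' `n_intronic` single-block reads whose maximum contiguous intronic
#' overlap is exactly `intron_overlap_len` bases, together with per-read
#' truth labels under the more-than-`min_more_than`-contiguous-bases rule.
#'
#' @param model A `gene_model` from [build_gene_model()].
#' @param n_exonic,n_intronic Read counts per class.
#' @param intron_overlap_len Exact contiguous intronic overlap of each
#'   intronic read (bases, >= 1).
#' @param seed Integer seed.
#' @param min_more_than Rule threshold used for the truth label: a read is
#'   labeled effective when its overlap exceeds this many bases.
#' @return List with `reads` (aligned-read data frame) and `truth` (data
#'   frame: `query_id`, `class` in `exonic`/`intronic`, `effective`).
#' @export
simulate_toy_alignments <- function(model, n_exonic, n_intronic,
                                    intron_overlap_len = 10, seed = 1,
                                    min_more_than = 3) {
  introns <- do.call(rbind, model$introns)
  if (n_intronic > 0) {
    if (is.null(introns) || nrow(introns) == 0L)
      stop("gene model has no introns")
    stopifnot(intron_overlap_len >= 1)
    if (all(introns[, 2] - introns[, 1] < intron_overlap_len))
      stop("requested overlap longer than any intron")
  }
  exons <- do.call(rbind, model$exons)
  mk_read <- function(start, end, id) {
    list(query_id = id, ref_name = model$seqname, start = start, end = end,
         strand = "+", is_unique = TRUE, is_duplicate = FALSE,
         blocks = cbind(start = start, end = end))
  }
  with_seed_(seed, {
    recs <- list()
    for (i in seq_len(n_exonic)) {
      e <- exons[sample.int(nrow(exons), 1L), ]
      w <- min(e[2] - e[1], sample(10:30, 1L))
      s <- e[1] + sample.int(e[2] - e[1] - w + 1L, 1L) - 1L
      recs[[length(recs) + 1L]] <- mk_read(s, s + w,
                                           sprintf("ex_%04d", i))
    }
    ok_introns <- which(introns[, 2] - introns[, 1] >= intron_overlap_len)
    for (i in seq_len(n_intronic)) {
      it <- introns[ok_introns[sample.int(length(ok_introns), 1L)], ]
      left_ext <- sample(1:10, 1L)  # exonic anchor upstream of the intron
      s <- it[1] - left_ext
      e <- it[1] + intron_overlap_len
      recs[[length(recs) + 1L]] <- mk_read(as.integer(s), as.integer(e),
                                           sprintf("in_%04d", i))
    }
  })
  reads <- data.frame(
    query_id = vapply(recs, `[[`, "", "query_id"),
    ref_name = vapply(recs, `[[`, "", "ref_name"),
    start = vapply(recs, function(r) as.integer(r$start), 0L),
    end = vapply(recs, function(r) as.integer(r$end), 0L),
    strand = vapply(recs, `[[`, "", "strand"),
    is_unique = TRUE, is_duplicate = FALSE, stringsAsFactors = FALSE)
  reads$blocks <- lapply(recs, `[[`, "blocks")
  truth <- data.frame(
    query_id = reads$query_id,
    class = rep(c("exonic", "intronic"), c(n_exonic, n_intronic)),
    effective = rep(c(FALSE, intron_overlap_len > min_more_than),
                    c(n_exonic, n_intronic)),
    stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}
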