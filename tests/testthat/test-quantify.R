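toy_matrix <- function(counts, biotype, length = NULL) {
  if (is.null(length))
    length <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  count_matrix(counts, biotype, length)
}

test_that("ERCC scale factors are spike totals over their median", {
  counts <- rbind(g1 = c(a = 5, b = 7),
                  `ERCC-1` = c(600, 1200), `ERCC-2` = c(400, 800))
  mat <- toy_matrix(counts, c(g1 = "mRNA", `ERCC-1` = "ERCC",
                              `ERCC-2` = "ERCC"))
  f <- ercc_scale_factors(mat)  # totals 1000, 2000; median 1500
  expect_equal(unname(f), c(2 / 3, 4 / 3))
  # equal spike totals give unit factors
  counts2 <- rbind(g1 = c(a = 5, b = 7), `ERCC-1` = c(100, 100))
  f2 <- ercc_scale_factors(toy_matrix(counts2, c(g1 = "mRNA",
                                                 `ERCC-1` = "ERCC")))
  expect_equal(unname(f2), c(1, 1))
  counts3 <- rbind(g1 = c(a = 5, b = 7), `ERCC-1` = c(100, 0))
  expect_error(ercc_scale_factors(toy_matrix(counts3,
                                             c(g1 = "mRNA",
                                               `ERCC-1` = "ERCC"))), "b")
})

test_that("normalized totals are linear and column-scale invariant", {
  withr::with_seed(71, {
    counts <- matrix(rpois(6 * 5, 50), nrow = 6,
                     dimnames = list(c(paste0("g", 1:4), "E1", "E2"),
                                     paste0("s", 1:5)))
  })
  bio <- stats::setNames(c(rep("mRNA", 4), "ERCC", "ERCC"),
                         rownames(counts))
  mat <- toy_matrix(counts, bio)
  f <- ercc_scale_factors(mat)
  tot <- total_rna_abundance(mat, f)
  # the sample with the top spike total: scaling it never moves the median
  sm <- names(which.max(colSums(counts[c("E1", "E2"), ])))
  # doubling one sample's endogenous counts (spikes fixed) doubles it
  c2 <- counts; c2[1:4, sm] <- 2 * c2[1:4, sm]
  tot2 <- total_rna_abundance(m2 <- toy_matrix(c2, bio),
                              ercc_scale_factors(m2))
  expect_equal(unname(tot2[sm]), unname(2 * tot[sm]))
  expect_equal(tot2[setdiff(names(tot2), sm)],
               tot[setdiff(names(tot), sm)])
  # doubling the whole column (endogenous + spikes) leaves it unchanged
  # while the other samples pin the median spike total
  c3 <- counts; c3[, sm] <- 2 * c3[, sm]
  tot3 <- total_rna_abundance(m3 <- toy_matrix(c3, bio),
                              ercc_scale_factors(m3))
  expect_equal(tot3, tot)
})

test_that("TPM matches the closed form and sums to one million", {
  counts <- matrix(c(10, 20), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  mat <- toy_matrix(counts, c(g1 = "mRNA", g2 = "mRNA"),
                    c(g1 = 1000, g2 = 2000))
  tpm <- compute_tpm(mat)
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))
  # single gene takes the whole million
  m1 <- toy_matrix(matrix(7, 1, 1, dimnames = list("g1", "s1")),
                   c(g1 = "mRNA"))
  expect_equal(unname(compute_tpm(m1)[1, 1]), 1e6)
  # random matrices: per-sample endogenous sums hit 1e6 to 1e-6 relative
  design <- cohort_design(stages = "E2.5", n_null = 3, n_control = 3,
                          seed = 72)
  sim <- simulate_embryo_cohort(design)
  tpm2 <- compute_tpm(sim$counts)
  endo <- sim$counts$genes$biotype != "ERCC"
  expect_true(all(abs(colSums(tpm2[endo, ]) - 1e6) < 1))
  zero <- toy_matrix(matrix(0, 1, 1, dimnames = list("g1", "s1")),
                     c(g1 = "mRNA"))
  expect_error(compute_tpm(zero), "all-zero")
})

test_that("class abundance sums the biotype and rejects unknown labels", {
  counts <- rbind(r1 = c(a = 5), r2 = c(7), E1 = c(100))
  mat <- toy_matrix(counts, c(r1 = "rRNA", r2 = "rRNA", E1 = "ERCC"))
  f <- ercc_scale_factors(mat)
  expect_equal(unname(class_abundance(mat, f, "rRNA")), 12)
  per_gene <- class_abundance(mat, f, "rRNA", per_gene = TRUE)
  expect_equal(dim(per_gene), c(2, 1))
  expect_error(class_abundance(mat, f, "tRNA"), "absent")
})

test_that("simulated down-regulation is recovered after normalization", {
  design <- cohort_design(stages = "E3.0", n_null = 8, n_control = 8,
                          downreg = c(mRNA = 0.6, rRNA = 0.5,
                                      snoRNA = 0.4),
                          seed = 73)
  sim <- simulate_embryo_cohort(design)
  f <- ercc_scale_factors(sim$counts)
  nulls <- sim$meta$sample_id[sim$meta$genotype == "null"]
  ctrls <- sim$meta$sample_id[sim$meta$genotype == "control"]
  sno <- class_abundance(sim$counts, f, "snoRNA")
  expect_lt(abs(mean(sno[nulls]) / mean(sno[ctrls]) - 0.4), 0.1)
})

test_that("rDNA feature assignment follows majority overlap with ties out", {
  features <- data.frame(name = c("18S", "5.8S", "28S"),
                         start = c(50, 2000, 2300),
                         end = c(1900, 2160, 7000))
  inside <- make_reads(100, 150)
  expect_equal(unname(quantify_rdna(inside, features)),
               c(1L, 0L, 0L, 0L))
  # 25 bases in each of two features: tie, unassigned
  tie <- make_reads(1875, 2025)
  counts <- quantify_rdna(tie, features)
  expect_equal(unname(counts["unassigned"]), 1L)
  # non-unique reads excluded under unique_only
  multi <- make_reads(100, 150, unique = FALSE)
  expect_equal(sum(quantify_rdna(multi, features)), 0)
  expect_equal(sum(quantify_rdna(multi, features,
                                 unique_only = FALSE)), 1)
  overlapping <- data.frame(name = c("a", "b"), start = c(0, 50),
                            end = c(100, 150))
  expect_error(quantify_rdna(inside, overlapping), "overlapping")
})

test_that("rDNA counting equals the per-base brute-force oracle", {
  features <- data.frame(name = c("18S", "5.8S", "28S"),
                         start = c(50, 1950, 2300),
                         end = c(1900, 2110, 4000))
  withr::with_seed(74, {
    n <- 400
    starts <- sample(0:3900, n, replace = TRUE)
    widths <- sample(20:120, n, replace = TRUE)
    reads <- make_reads(starts, pmin(starts + widths, 4000))
    # give a third of the reads a spliced second block
    idx <- sample(n, n %/% 3)
    for (i in idx) {
      gap <- sample(30:300, 1)
      w2 <- sample(10:80, 1)
      b <- reads$blocks[[i]]
      s2 <- min(b[1, 2] + gap, 3990)
      reads$blocks[[i]] <- cbind(start = c(b[1, 1], s2),
                                 end = c(b[1, 2], min(s2 + w2, 4000)))
      reads$end[i] <- reads$blocks[[i]][2, 2]
    }
  })
  expect_equal(quantify_rdna(reads, features, unique_only = FALSE),
               oracle_rdna_counts(reads, features))
})

test_that("log2 fold changes use spike-normalized group means", {
  counts <- rbind(g1 = c(a = 10, b = 10, c = 5, d = 5),
                  E1 = c(100, 100, 100, 100))
  mat <- toy_matrix(counts, c(g1 = "mRNA", E1 = "ERCC"))
  f <- ercc_scale_factors(mat)
  lfc <- log2_fold_change(mat, f, c("a", "b"), c("c", "d"),
                          pseudocount = 0)
  expect_equal(unname(lfc["g1"]), 1)
  counts0 <- rbind(g1 = c(a = 0, b = 0, c = 3, d = 3),
                   E1 = c(100, 100, 100, 100))
  mat0 <- toy_matrix(counts0, c(g1 = "mRNA", E1 = "ERCC"))
  lfc0 <- log2_fold_change(mat0, ercc_scale_factors(mat0),
                           c("a", "b"), c("c", "d"), pseudocount = 1)
  expect_equal(unname(lfc0["g1"]), -2)
  expect_error(log2_fold_change(mat, f, "a", "c", pseudocount = -1),
               ">= 0")
  expect_error(log2_fold_change(mat, f, character(0), "c"), "non-empty")
})
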