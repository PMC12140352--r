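# Sample-level inference: genotype calls from deleted-region read counts
# or target-gene abundance, genotype-by-stage tables, Mendelian chi-square
# tests.

#' Call genotypes from deleted-region counts or target-gene TPM
#'
#' In `region` mode, a sample is `null` when its deleted-region read count
#' is at most `max_null`, `control` when at least `min_control`, and
#' `ambiguous` between the two thresholds. In `tpm` mode the values are
#' split on `log(value + 1)` by a deterministic two-centroid assignment
#' (centroids initialized at the minimum and maximum, Lloyd iteration to
#' convergence); the cluster with the lower center is `null`, and samples
#' within `margin` (a fraction of the inter-center distance) of the
#' midpoint are `ambiguous`.
#'
#' @param values Non-negative numeric vector of evidence values, named by
#'   sample where available.
#' @param mode `"region"` or `"tpm"`.
#' @param max_null Region mode: highest count still called null.
#' @param min_control Region mode: lowest count called control.
#' @param margin TPM mode: half-width of the ambiguous band around the
#'   cluster midpoint, as a fraction of the distance between centers.
#' @return Data frame `sample_id`, `evidence`, `value`, `label`.
#' @export
call_genotype <- function(values, mode = c("region", "tpm"), max_null = 2,
                          min_control = 10, margin = 0.1) {
  mode <- match.arg(mode)
  stopifnot(all(values >= 0))
  ids <- if (is.null(names(values))) paste0("S", seq_along(values)) else
    names(values)
  if (mode == "region") {
    if (max_null >= min_control)
      stop("max_null must be below min_control")
    label <- ifelse(values <= max_null, "null",
                    ifelse(values >= min_control, "control", "ambiguous"))
  } else {
    x <- log(values + 1)
    if (diff(range(x)) == 0) {
      label <- rep("ambiguous", length(x))
    } else {
      centers <- range(x)
      for (iter in 1:100) {
        assign <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
        new_centers <- c(mean(x[assign == 1L]), mean(x[assign == 2L]))
        if (anyNA(new_centers) || all(new_centers == centers)) break
        centers <- new_centers
      }
      mid <- mean(centers)
      band <- margin * abs(diff(centers))
      label <- ifelse(abs(x - mid) < band, "ambiguous",
                      ifelse(x < mid, "null", "control"))
    }
  }
  data.frame(sample_id = ids, evidence = mode, value = as.numeric(values),
             label = label, stringsAsFactors = FALSE)
}

#' Genotype counts and null fraction per developmental stage
#'
#' Ambiguous calls are excluded (a warning reports how many); stages with
#' no unambiguous samples get an `NA` row.
#'
#' @param calls Data frame from [call_genotype()].
#' @param stages Stage label per sample, parallel to `calls`.
#' @return Data frame `stage`, `n_null`, `n_control`, `fraction_null`.
#' @export
genotype_stage_ratio <- function(calls, stages) {
  stopifnot(nrow(calls) == length(stages))
  amb <- calls$label == "ambiguous"
  if (any(amb))
    warning(sum(amb), " ambiguous call(s) excluded")
  keep <- !amb
  out <- lapply(unique(stages), function(st) {
    sel <- keep & stages == st
    n_null <- sum(calls$label[sel] == "null")
    n_ctrl <- sum(calls$label[sel] == "control")
    data.frame(stage = st, n_null = n_null, n_control = n_ctrl,
               fraction_null = if (n_null + n_ctrl > 0)
                 n_null / (n_null + n_ctrl) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Chi-square test of observed genotype counts against a Mendelian ratio
#'
#' Expected counts are `N * ratio_k / sum(ratio)`; the statistic is
#' `sum((obs - exp)^2 / exp)` on `length(observed) - 1` degrees of
#' freedom, with the p-value from the upper chi-square tail.
#'
#' @param observed Non-negative counts per genotype class.
#' @param expected_ratio Positive expected ratio, same length (e.g.
#'   `c(1, 2, 1)` for an intercross).
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
mendelian_chi_square <- function(observed, expected_ratio = c(1, 2, 1)) {
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (length(observed) != length(expected_ratio))
    stop("observed and expected_ratio differ in length")
  if (any(expected_ratio <= 0))
    stop("expected_ratio entries must be positive")
  expected <- sum(observed) * expected_ratio / sum(expected_ratio)
  if (any(expected == 0)) stop("expected count of zero")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}
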