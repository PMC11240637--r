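## Per-population diversity statistics: random match probability, haplotype
## diversity, nucleotide diversity, and the survey-level summary table.

#' Random match probability
#'
#' RMP = sum of squared haplotype frequencies: the probability that two
#' individuals drawn at random from the population carry the same
#' haplotype, i.e. the forensic weight of an mtDNA match.
#'
#' @param counts Non-negative integer haplotype counts (at least one > 0).
#' @return A fraction in `[1/k, 1]`.
#' @examples
#' rmp(c(25, 5, 1))  # 651/961
#' @export
rmp <- function(counts) {
  counts <- validate_counts(counts)
  n <- sum(counts)
  sum((counts / n)^2)
}

#' Haplotype diversity
#'
#' The probability that two randomly drawn individuals carry different
#' haplotypes. The unbiased estimator multiplies by `n/(n-1)` to correct
#' for drawing without replacement.
#'
#' @param counts Non-negative integer haplotype counts.
#' @param unbiased Apply the `n/(n-1)` small-sample correction (default).
#' @return `Hd` in `[0, 1]` (the unbiased form can reach 1 exactly).
#' @examples
#' haplotype_diversity(c(66, 108, 1, 1, 9, 7))  # 0.5648
#' @export
haplotype_diversity <- function(counts, unbiased = TRUE) {
  counts <- validate_counts(counts)
  n <- sum(counts)
  h <- 1 - sum((counts / n)^2)
  if (unbiased) {
    if (n < 2) stop("unbiased Hd requires n >= 2", call. = FALSE)
    h <- n / (n - 1) * h
  }
  h
}

#' Haplotype diversity from a published match probability
#'
#' Applies the unbiased correction directly to a reported sum of squared
#' frequencies: `Hd = (n/(n-1)) * (1 - RMP)`. Useful for auditing printed
#' summary tables where only (n, RMP) are given, and for detecting
#' internally inconsistent rows.
#'
#' @param n Sample size (>= 2).
#' @param match_probability Sum of squared haplotype frequencies.
#' @return `Hd`.
#' @examples
#' hd_from_match_probability(34, 0.585)  # 0.4276
#' @export
hd_from_match_probability <- function(n, match_probability) {
  n <- check_count(n, "n", min = 2L)
  if (!is.finite(match_probability) || match_probability < 0 || match_probability > 1)
    stop("'match_probability' must be in [0, 1]", call. = FALSE)
  n / (n - 1) * (1 - match_probability)
}

#' Audit a printed (n, Hd, RMP) table row for internal consistency
#'
#' Checks whether a reported haplotype diversity agrees with the value
#' implied by the reported match probability under the unbiased estimator.
#' Both printed entries carry rounding error, so the consistency band is
#' half a printed unit on each, with the RMP's half-unit propagated through
#' the `n/(n-1)` factor.
#'
#' @param n Sample size.
#' @param hd,rmp Reported values.
#' @param digits Printed precision (default 3).
#' @return Logical.
#' @export
check_hd_rmp <- function(n, hd, rmp, digits = 3) {
  implied <- hd_from_match_probability(n, rmp)
  band <- (n / (n - 1) + 1) * 10^(-digits) / 2
  abs(implied - hd) <= band
}

#' Nucleotide diversity per site
#'
#' The average number of nucleotide differences between two randomly drawn
#' sequences, per base position of the evaluated alignment length `L`:
#' `pi = c * sum_{i<j} 2 p_i p_j d_ij / L`, with `c = n/(n-1)` for the
#' unbiased form.
#'
#' @param counts Named haplotype counts.
#' @param diffs Symmetric pairwise-difference matrix covering all haplotypes
#'   present (e.g. from [registry_diff_matrix()]), or a single number when
#'   exactly two haplotypes are supplied.
#' @param L Evaluated alignment length in bases (default 450, the
#'   combined-analysis control-region sub-window).
#' @param unbiased Apply the `n/(n-1)` correction (default).
#' @return `pi` per site.
#' @examples
#' nucleotide_diversity(c(24, 10), diffs = 1, L = 450)  # 0.00095
#' @export
nucleotide_diversity <- function(counts, diffs, L = 450, unbiased = TRUE) {
  counts <- validate_counts(counts)
  L <- check_count(L, "L")
  n <- sum(counts)
  k <- length(counts)
  if (is.matrix(diffs)) {
    if (!is.null(names(counts))) {
      if (!all(names(counts) %in% rownames(diffs)))
        stop("'diffs' is missing a haplotype pair present in 'counts'",
             call. = FALSE)
      diffs <- diffs[names(counts), names(counts), drop = FALSE]
    } else if (!all(dim(diffs) == k)) {
      stop("'diffs' dimensions do not match 'counts'", call. = FALSE)
    }
  } else {
    if (k > 2 || length(diffs) != 1L)
      stop("scalar 'diffs' is only allowed for two haplotypes", call. = FALSE)
    diffs <- matrix(c(0, diffs, diffs, 0), 2, 2)[seq_len(k), seq_len(k), drop = FALSE]
  }
  p <- counts / n
  pi_sum <- 0
  if (k >= 2) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        pi_sum <- pi_sum + 2 * p[i] * p[j] * diffs[i, j]
      }
    }
  }
  unname((if (unbiased) n / (n - 1) else 1) * pi_sum / L)
}

#' Overall random match probability across regions
#'
#' Two aggregation conventions are supported and should be reported side by
#' side: `mean_of_regions`, the unweighted arithmetic mean of the regional
#' RMPs (the convention behind the published country-wide figure), and
#' `pooled`, the sum of squared frequencies of the pooled counts.
#'
#' @param regional_rmps Numeric vector of regional RMP values
#'   (`mean_of_regions` mode).
#' @param pooled_counts Pooled haplotype counts (`pooled` mode).
#' @param mode Aggregation convention.
#' @return A fraction.
#' @examples
#' overall_rmp(c(0.585, 0.484, 0.487, 0.617, 0.677, 0.429))  # 0.5465
#' @export
overall_rmp <- function(regional_rmps = NULL, pooled_counts = NULL,
                        mode = c("mean_of_regions", "pooled")) {
  mode <- match.arg(mode)
  if (mode == "mean_of_regions") {
    if (is.null(regional_rmps) || length(regional_rmps) == 0)
      stop("'regional_rmps' must be a non-empty numeric vector", call. = FALSE)
    mean(regional_rmps)
  } else {
    if (is.null(pooled_counts))
      stop("'pooled_counts' required in pooled mode", call. = FALSE)
    rmp(pooled_counts)
  }
}

#' Per-region and overall diversity summary table
#'
#' Computes, for each region and for the pooled data, the sample size `n`,
#' number of segregating sites `S`, haplotype count `k`, unbiased haplotype
#' diversity `Hd`, unbiased per-site nucleotide diversity `pi` and the
#' random match probability `RMP`. `S` and `k` are measured from the data,
#' never taken from configuration. The overall `RMP` follows the
#' mean-of-regions convention; the pooled variant is attached as
#' `attr(, "rmp_overall_pooled")`.
#'
#' @param positioned A `positioned_seqs` list of the mapped samples.
#' @param assignments Assignment data.frame from [assign_haplotypes()].
#' @param metadata Metadata data.frame (`sample_id`, `region`).
#' @param registry The `haplotype_registry` (supplies the inter-haplotype
#'   difference matrix for `pi`).
#' @param L Alignment length for `pi` (default 450).
#' @return A data.frame with one row per region plus an `"Overall"` row.
#' @export
stats_table <- function(positioned, assignments, metadata, registry, L = 450) {
  tab <- haplotype_frequencies(assignments, metadata)
  regions <- rownames(tab)
  if (any(rowSums(tab) == 0))
    stop("region with no assigned samples", call. = FALSE)
  diffs <- registry_diff_matrix(registry)
  ids <- vapply(positioned, function(r) as.character(r$id), character(1))

  one_row <- function(region) {
    counts <- tab[region, tab[region, ] > 0]
    members <- metadata$sample_id[metadata$region == region]
    sub <- positioned[ids %in% members]
    S <- if (length(sub) >= 2) length(call_segregating_sites(sub)) else 0L
    n_region <- sum(counts)
    data.frame(
      region = region,
      n = n_region,
      S = S,
      k = length(counts),
      ## the unbiased estimators are undefined for a single individual
      Hd = if (n_region >= 2) haplotype_diversity(counts) else NA_real_,
      pi = if (n_region >= 2) nucleotide_diversity(counts, diffs, L = L) else NA_real_,
      RMP = rmp(counts),
      stringsAsFactors = FALSE
    )
  }
  per_region <- do.call(rbind, lapply(regions, one_row))

  pooled <- colSums(tab)
  pooled <- pooled[pooled > 0]
  overall <- data.frame(
    region = "Overall",
    n = sum(pooled),
    S = length(call_segregating_sites(positioned)),
    k = length(pooled),
    Hd = haplotype_diversity(pooled),
    pi = nucleotide_diversity(pooled, diffs, L = L),
    RMP = overall_rmp(per_region$RMP),
    stringsAsFactors = FALSE
  )
  out <- rbind(per_region, overall)
  rownames(out) <- NULL
  attr(out, "rmp_overall_pooled") <- rmp(pooled)
  attr(out, "L") <- L
  out
}

validate_counts <- function(counts) {
  counts <- unlist(counts)
  if (length(counts) == 0)
    stop("'counts' must be non-empty", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("'counts' must sum to at least 1", call. = FALSE)
  counts
}
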