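## Pairwise population differentiation: Hudson-style Fst from sequence
## differences, Nei Gst from haplotype frequencies (with the Nei-Chesser
## small-sample correction), and permutation significance.

#' Hudson-style Fst between two populations
#'
#' `Fst = 1 - Hw/Hb`, where `Hw` is the unweighted mean of the two
#' within-population mean pairwise difference counts and `Hb` is the mean
#' pairwise difference count across all between-population pairs
#' (Hudson-Slatkin-Maddison estimator). `Hb = 0` yields 0 by convention.
#' The estimator can be slightly negative for near-identical populations;
#' negative values are reported as computed, never clamped.
#'
#' @param counts_a,counts_b Named haplotype counts of the two populations.
#' @param diffs Symmetric pairwise-difference matrix whose dimnames cover
#'   all haplotypes present.
#' @return `Fst` (<= 1).
#' @examples
#' d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' hudson_fst(c(A = 5), c(B = 5), d)  # 1
#' @export
hudson_fst <- function(counts_a, counts_b, diffs) {
  ca <- validate_counts(counts_a)
  cb <- validate_counts(counts_b)
  haps <- union(names(ca), names(cb))
  if (is.null(names(ca)) || is.null(names(cb)))
    stop("counts must be named by haplotype", call. = FALSE)
  if (!all(haps %in% rownames(diffs)))
    stop("'diffs' is missing a haplotype present in the populations",
         call. = FALSE)
  d <- diffs[haps, haps, drop = FALSE]
  va <- stats::setNames(rep(0, length(haps)), haps)
  vb <- va
  va[names(ca)] <- ca
  vb[names(cb)] <- cb

  hw <- mean(c(mean_within(va, d), mean_within(vb, d)))
  hb <- as.numeric(t(va) %*% d %*% vb) / (sum(va) * sum(vb))
  if (hb == 0) return(0)
  1 - hw / hb
}

## mean pairwise difference count among the n(n-1)/2 within-population
## pairs; 0 for a single individual (no pairs)
mean_within <- function(v, d) {
  n <- sum(v)
  if (n < 2) return(0)
  as.numeric(t(v) %*% d %*% v) / (n * (n - 1))
}

#' Nei Gst across populations
#'
#' The haplotype-frequency analogue of Fst: `Gst = (Ht - Hs)/Ht`, with `Hs`
#' the mean within-population gene diversity and `Ht` the gene diversity of
#' the mean frequencies. The corrected form applies the Nei-Chesser
#' small-sample estimators (haploid data): `Hs~ = n~/(n~-1) * Hs` and
#' `Ht~ = Ht + Hs~/(n~ s)`, with `n~` the harmonic mean sample size and `s`
#' the number of populations — this is the variant that "also considers the
#' population sizes".
#'
#' @param pop_table Region x haplotype count matrix (e.g. a `pop_table`
#'   from [haplotype_frequencies()]), >= 2 rows.
#' @param corrected Apply the Nei-Chesser correction (default `TRUE`).
#' @return `Gst`; 0 (with a warning) when `Ht = 0`, i.e. all populations
#'   monomorphic for the same haplotype.
#' @examples
#' m <- rbind(a = c(5, 5), b = c(10, 0))
#' nei_gst(m, corrected = FALSE)  # 1/3
#' @export
nei_gst <- function(pop_table, corrected = TRUE) {
  m <- as.matrix(unclass(pop_table))
  if (nrow(m) < 2)
    stop("at least two populations are required", call. = FALSE)
  sizes <- rowSums(m)
  if (any(sizes == 0))
    stop("population of size 0", call. = FALSE)
  p <- sweep(m, 1, sizes, "/")
  s <- nrow(m)

  hs <- mean(1 - rowSums(p^2))
  pbar <- colMeans(p)
  ht <- 1 - sum(pbar^2)

  if (corrected) {
    n_h <- s / sum(1 / sizes) # harmonic mean sample size
    if (n_h <= 1)
      stop("corrected Gst requires harmonic mean sample size > 1", call. = FALSE)
    hs <- n_h / (n_h - 1) * hs
    ht <- ht + hs / (n_h * s)
  }
  if (ht == 0) {
    warning("Ht = 0: all populations monomorphic for the same haplotype; Gst defined as 0")
    return(0)
  }
  (ht - hs) / ht
}

#' Permutation test for pairwise differentiation
#'
#' Permutes individual haplotype labels across the pooled pair, recomputes
#' the statistic, and returns the add-one p-value
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)` (never exactly 0).
#' Reproducible for a fixed seed.
#'
#' @param labels_a,labels_b Character vectors of individual haplotype
#'   labels for the two populations.
#' @param statistic `"fst"` (needs `diffs`) or `"gst"`.
#' @param diffs Pairwise-difference matrix (Fst only).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer RNG seed.
#' @param corrected Passed to [nei_gst()] when `statistic = "gst"`.
#' @return List of class `perm_test`: `p_value`, `observed`, `n_perm`,
#'   `seed`, `statistic`.
#' @export
permutation_test <- function(labels_a, labels_b,
                             statistic = c("fst", "gst"), diffs = NULL,
                             n_perm = 10000L, seed = 1L, corrected = TRUE) {
  statistic <- match.arg(statistic)
  n_perm <- check_count(n_perm, "n_perm")
  na <- length(labels_a)
  nb <- length(labels_b)
  if (na == 0 || nb == 0)
    stop("both populations must be non-empty", call. = FALSE)
  pooled <- c(labels_a, labels_b)
  if (length(unique(pooled)) < 2)
    stop("degenerate pair: all pooled individuals carry the same haplotype",
         call. = FALSE)

  stat_fun <- function(a, b) {
    if (statistic == "fst") {
      hudson_fst(label_counts(a), label_counts(b), diffs)
    } else {
      haps <- sort(unique(c(a, b)))
      tab <- rbind(
        a = as.integer(table(factor(a, levels = haps))),
        b = as.integer(table(factor(b, levels = haps)))
      )
      colnames(tab) <- haps
      nei_gst(tab, corrected = corrected)
    }
  }
  observed <- stat_fun(labels_a, labels_b)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      perm <- sample(pooled)
      stat_fun(perm[seq_len(na)], perm[na + seq_len(nb)])
    }, numeric(1)) >= observed - 1e-12)
  })
  structure(
    list(
      p_value = (1 + exceed) / (1 + n_perm),
      observed = observed,
      n_perm = n_perm,
      seed = as.integer(seed),
      statistic = statistic
    ),
    class = "perm_test"
  )
}

label_counts <- function(labels) {
  tab <- table(labels)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> %s = %.4f, p = %.4g (%d permutations, seed %d)\n",
    toupper(x$statistic), x$observed, x$p_value, x$n_perm, x$seed
  ))
  invisible(x)
}

#' All-pairs differentiation matrix
#'
#' Computes Hudson Fst and Nei Gst (corrected) for every pair of regions,
#' with permutation p-values, and annotates pairs at or above the
#' conventional `Fst >= 0.15` threshold for significant genetic difference
#' between subpopulations.
#'
#' @param pop_table Region x haplotype count matrix.
#' @param diffs Pairwise-difference matrix over the haplotypes present.
#' @param n_perm Permutations per pair (default 10000; set 0 to skip
#'   permutation p-values).
#' @param seed Integer RNG seed (each pair derives its own sub-seed).
#' @param fst_threshold Annotation threshold (default 0.15).
#' @return An object of class `differentiation_matrix`: list with
#'   `regions`, symmetric matrices `fst`, `gst`, `p_fst`, `p_gst`,
#'   logical `significant` (`fst >= fst_threshold`), `n_permutations`,
#'   `seed`.
#' @export
differentiation_matrix <- function(pop_table, diffs, n_perm = 10000L,
                                   seed = 1L, fst_threshold = 0.15) {
  m <- as.matrix(unclass(pop_table))
  regions <- rownames(m)
  if (length(regions) < 2)
    stop("at least two populations are required", call. = FALSE)
  nr <- length(regions)
  fst <- gst <- p_fst <- p_gst <-
    matrix(NA_real_, nr, nr, dimnames = list(regions, regions))

  pair_idx <- 0L
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      pair_idx <- pair_idx + 1L
      ca <- m[i, m[i, ] > 0]
      cb <- m[j, m[j, ] > 0]
      fst[i, j] <- fst[j, i] <- hudson_fst(ca, cb, diffs)
      gst[i, j] <- gst[j, i] <- nei_gst(m[c(i, j), , drop = FALSE])
      if (n_perm > 0) {
        la <- rep(names(ca), ca)
        lb <- rep(names(cb), cb)
        degenerate <- length(unique(c(la, lb))) < 2
        if (!degenerate) {
          sub_seed <- as.integer(seed) + pair_idx
          p_fst[i, j] <- p_fst[j, i] <- permutation_test(
            la, lb, "fst", diffs, n_perm = n_perm, seed = sub_seed
          )$p_value
          p_gst[i, j] <- p_gst[j, i] <- permutation_test(
            la, lb, "gst", n_perm = n_perm, seed = sub_seed
          )$p_value
        }
      }
    }
  }
  structure(
    list(
      regions = regions,
      fst = fst,
      gst = gst,
      p_fst = p_fst,
      p_gst = p_gst,
      significant = fst >= fst_threshold,
      fst_threshold = fst_threshold,
      n_permutations = as.integer(n_perm),
      seed = as.integer(seed)
    ),
    class = "differentiation_matrix"
  )
}

#' @export
print.differentiation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<differentiation_matrix> %d regions; Fst below diagonal, Gst above; %d permutations\n",
    length(x$regions), x$n_permutations
  ))
  comb <- x$gst
  comb[lower.tri(comb)] <- x$fst[lower.tri(x$fst)]
  diag(comb) <- NA
  print(round(comb, digits))
  sig <- which(x$significant & upper.tri(x$significant), arr.ind = TRUE)
  if (nrow(sig) > 0) {
    cat(sprintf("Pairs with Fst >= %.2f (significant genetic difference):\n",
                x$fst_threshold))
    for (r in seq_len(nrow(sig)))
      cat(sprintf("  %s-%s: Fst = %.3f\n",
                  x$regions[sig[r, 1]], x$regions[sig[r, 2]],
                  x$fst[sig[r, 1], sig[r, 2]]))
  }
  invisible(x)
}
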