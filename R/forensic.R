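## Forensic comparison of an evidence sequence against a reference sample
## or a haplotype database, using the two-discrepancy exclusion rule: >= 2
## nucleotide discrepancies exclude, exactly 1 is inconclusive, 0 is a
## match (whose weight is the haplotype's random match probability).

#' Compare an evidence sequence with a reference sample
#'
#' Both sequences are placed on the reference window; discrepancies are
#' counted only over jointly covered positions where both bases are
#' unambiguous. The verdict follows the forensic convention: `match` at 0
#' discrepancies, `inconclusive` at exactly 1, `exclusion` at 2 or more.
#' Zero overlapping coverage is an error, never a "match". Symmetric in
#' its two sequence arguments.
#'
#' @param evidence,reference_sample Character strings, or positioned
#'   records (lists with `seq`, `start`, `end`).
#' @param reference A `ref_sequence`.
#' @param window Analysis window (default the full reference extent).
#' @param registry Optional `haplotype_registry`: when supplied together
#'   with `pop_table`, the evidence is haplotyped and the match weight
#'   (regional and overall RMP of the matched haplotype) is attached.
#' @param pop_table Optional region x haplotype count matrix.
#' @return An object of class `match_result`: `verdict`, `discrepancies`,
#'   `compared_positions`, `overlap` (coordinates), `notes`, and (when a
#'   database is supplied) `matched_haplotype` and `match_weight`.
#' @export
compare_sequences <- function(evidence, reference_sample, reference,
                              window = NULL, registry = NULL,
                              pop_table = NULL) {
  ev <- as_positioned(evidence, reference, window, "evidence")
  rs <- as_positioned(reference_sample, reference, window, "reference_sample")

  lo <- max(ev$start, rs$start)
  hi <- min(ev$end, rs$end)
  if (lo > hi)
    stop("no overlapping coverage between evidence and reference sample; comparison impossible",
         call. = FALSE)

  ec <- seq_chars(ev$seq)[(lo - ev$start + 1L):(hi - ev$start + 1L)]
  rc <- seq_chars(rs$seq)[(lo - rs$start + 1L):(hi - rs$start + 1L)]
  both_unamb <- is_unambiguous(ec) & is_unambiguous(rc)
  discrepancies <- sum(ec[both_unamb] != rc[both_unamb])
  compared <- sum(both_unamb)

  notes <- character(0)
  skipped <- sum(!both_unamb)
  if (skipped > 0)
    notes <- c(notes, sprintf(
      "%d position(s) skipped as missing/ambiguous in at least one sequence",
      skipped
    ))
  win <- if (is.null(window)) {
    c(reference$origin, reference$origin + nchar(reference$sequence) - 1L)
  } else {
    as_window_vec(window)
  }
  if (lo > win[1] || hi < win[2])
    notes <- c(notes, sprintf(
      "partial coverage: compared interval %d..%d of window %d..%d",
      lo, hi, win[1], win[2]
    ))

  verdict <- if (discrepancies >= 2) "exclusion"
             else if (discrepancies == 1) "inconclusive"
             else "match"

  res <- list(
    verdict = verdict,
    discrepancies = as.integer(discrepancies),
    compared_positions = as.integer(compared),
    overlap = c(start = lo, end = hi),
    matched_haplotype = NULL,
    match_weight = NULL,
    notes = notes
  )

  if (!is.null(registry) && !is.null(pop_table) && verdict == "match") {
    asn <- assign_haplotypes(
      structure(list(list(id = "evidence", seq = ev$seq,
                          start = ev$start, end = ev$end)),
                class = "positioned_seqs"),
      registry, reference, allow_new = FALSE
    )$assignments
    hap <- if (!is.na(asn$haplotype[1])) asn$haplotype[1] else
      strsplit(asn$consistent_with[1], ",", fixed = TRUE)[[1]]
    res$matched_haplotype <- hap
    res$match_weight <- match_weight(hap, pop_table)
    if (is.na(asn$haplotype[1]))
      res$notes <- c(res$notes,
        "evidence has partial variable-site coverage; weight is the summed frequency of its consistency set")
  }
  structure(res, class = "match_result")
}

as_positioned <- function(x, reference, window, what) {
  if (is.character(x)) {
    map_to_reference(x, reference, window, id = what)
  } else if (is.list(x) && all(c("seq", "start", "end") %in% names(x))) {
    x
  } else {
    stop(sprintf("'%s' must be a sequence string or a positioned record", what),
         call. = FALSE)
  }
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %s: %d discrepancy(ies) over %d compared position(s) [%d..%d]\n",
    toupper(x$verdict), x$discrepancies, x$compared_positions,
    x$overlap[["start"]], x$overlap[["end"]]
  ))
  if (!is.null(x$matched_haplotype))
    cat("  haplotype:", paste(x$matched_haplotype, collapse = ","), "\n")
  if (!is.null(x$match_weight)) {
    ov <- x$match_weight$overall
    cat(sprintf("  match weight (overall): frequency %.4f, conservative %.4f\n",
                ov$frequency, ov$conservative))
  }
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}

#' Forensic weight of a haplotype match
#'
#' Reports the haplotype's sample frequency per region and overall,
#' together with a conservative frequency estimate: the add-one estimator
#' `(x+1)/(n+1)` (default) or a one-sided 95% upper Clopper-Pearson
#' confidence bound. For a consistency set (partial evidence), frequencies
#' of the member haplotypes are summed, giving an upper bound on the match
#' probability. The plain sample frequency remains the headline figure;
#' under-sampling then errs conservatively (it overestimates rare
#' haplotype frequencies, which cannot incriminate a false suspect).
#'
#' @param haplotype Haplotype name, or character vector of names (a
#'   consistency set).
#' @param pop_table Region x haplotype count matrix.
#' @param conservative `"add_one"` or `"upper_ci"`.
#' @param conf Confidence level for `"upper_ci"` (default 0.95).
#' @return An object of class `match_weight`: list with `haplotype`,
#'   `regional` (data.frame: region, x, n, frequency, conservative) and
#'   `overall` (same fields, pooled).
#' @examples
#' tab <- matrix(c(66, 108), 1, 2, dimnames = list("HU", c("Hun1", "Hun2")))
#' match_weight("Hun2", tab)$overall$frequency  # 0.6207 on this one-region table
#' @export
match_weight <- function(haplotype, pop_table,
                         conservative = c("add_one", "upper_ci"),
                         conf = 0.95) {
  conservative <- match.arg(conservative)
  m <- as.matrix(unclass(pop_table))
  if (length(m) == 0 || sum(m) == 0)
    stop("empty population table", call. = FALSE)
  known <- intersect(haplotype, colnames(m))

  cons_est <- function(x, n) {
    if (conservative == "add_one") (x + 1) / (n + 1)
    else stats::qbeta(conf, x + 1, pmax(n - x, 0))
  }
  row_weight <- function(x, n) {
    data.frame(
      x = x, n = n,
      frequency = if (n > 0) x / n else NA_real_,
      conservative = if (n > 0) pmin(cons_est(x, n), 1) else NA_real_
    )
  }

  regional <- do.call(rbind, lapply(rownames(m), function(region) {
    x <- sum(m[region, known])
    cbind(region = region, row_weight(x, sum(m[region, ])))
  }))
  overall <- cbind(region = "Overall",
                  row_weight(sum(m[, known]), sum(m)))
  structure(
    list(
      haplotype = haplotype,
      estimator = conservative,
      regional = regional,
      overall = overall
    ),
    class = "match_weight"
  )
}

#' @export
print.match_weight <- function(x, ...) {
  cat(sprintf("<match_weight> haplotype %s (conservative estimator: %s)\n",
              paste(x$haplotype, collapse = ","), x$estimator))
  print(rbind(x$regional, x$overall), row.names = FALSE)
  invisible(x)
}
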