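## Haplotyping: amplicon arithmetic, reference placement, segregating-site
## calling and haplotype collapsing.

#' Parse a primer name into its 5' position
#'
#' Primer names encode the 1-based mitogenome position of the primer's 5'
#' base, e.g. `"F15,386"` or `"R16,330"`; thousands separators are ignored.
#'
#' @param name Primer name.
#' @return Integer position.
#' @export
parse_primer_position <- function(name) {
  m <- regmatches(name, regexec("^[FfRr]?([0-9][0-9,]*)$", trimws(name)))[[1]]
  if (length(m) != 2L)
    stop(sprintf("cannot parse primer name '%s'", name), call. = FALSE)
  as.integer(gsub(",", "", m[2], fixed = TRUE))
}

#' Amplicon window spanned by a primer pair
#'
#' The amplicon is the inclusive interval between the forward and reverse
#' primers' 5' positions on the forward strand (the reverse primer's 5'
#' base, on the reverse strand, marks the amplicon's last forward-strand
#' position), so its length is `reverse - forward + 1`.
#'
#' @param forward,reverse Primer names (see [parse_primer_position()]) or
#'   bare positions.
#' @return An object of class `alignment_window`: list with `start`, `end`,
#'   `L`.
#' @examples
#' amplicon_span("F15,386", "R16,330")$L  # 945
#' @export
amplicon_span <- function(forward, reverse) {
  fp <- if (is.numeric(forward)) as.integer(forward) else parse_primer_position(forward)
  rp <- if (is.numeric(reverse)) as.integer(reverse) else parse_primer_position(reverse)
  if (rp <= fp)
    stop("reverse primer position must exceed forward primer position",
         call. = FALSE)
  structure(
    list(start = fp, end = rp, L = rp - fp + 1L),
    class = "alignment_window"
  )
}

#' @export
print.alignment_window <- function(x, ...) {
  cat(sprintf("<alignment_window> %d..%d (L = %d bp)\n", x$start, x$end, x$L))
  invisible(x)
}

#' Place a sample sequence on the reference window
#'
#' Colinear, gap-free placement by sliding-offset search: the offset
#' minimising mismatches over the sample's unambiguous bases wins (smallest
#' offset on ties). Sequences requiring an internal gap (any `-` character)
#' are rejected — the substitution-only model is a hard contract, not a
#' heuristic. IUPAC ambiguity codes and `N` are carried through and treated
#' as missing data downstream.
#'
#' @param seq Sample sequence (character string).
#' @param reference A `ref_sequence`.
#' @param window An `alignment_window` or integer `c(start, end)`; defaults
#'   to the full reference extent.
#' @param max_mismatch_frac Placements whose best mismatch fraction exceeds
#'   this are rejected as unmappable (default 0.1).
#' @param id Optional sample identifier recorded in the result.
#' @return A positioned record: list with `id`, `seq`, `start`, `end`,
#'   `mismatches`, `compared`.
#' @export
map_to_reference <- function(seq, reference, window = NULL,
                             max_mismatch_frac = 0.1, id = NULL) {
  if (is.null(window))
    window <- c(reference$origin, reference$origin + nchar(reference$sequence) - 1L)
  win <- as_window_vec(window)

  s <- toupper(seq)
  gap <- regexpr("-", s, fixed = TRUE)
  if (gap > 0)
    stop(sprintf(
      "internal gap (indel) required at sequence position %d: indels are not supported",
      gap
    ), call. = FALSE)

  sv <- seq_chars(s)
  n <- length(sv)
  L <- win[2] - win[1] + 1L
  if (n > L)
    stop("sample is longer than the analysis window", call. = FALSE)
  rv <- seq_chars(substring(
    reference$sequence,
    win[1] - reference$origin + 1L,
    win[2] - reference$origin + 1L
  ))

  unamb <- is_unambiguous(sv)
  compared <- sum(unamb)
  best_off <- 0L
  best_mm <- Inf
  for (off in 0:(L - n)) {
    mm <- sum(sv[unamb] != rv[off + which(unamb)])
    if (mm < best_mm) {
      best_mm <- mm
      best_off <- off
      if (mm == 0L) break
    }
  }
  frac <- if (compared > 0) best_mm / compared else 0
  if (frac > max_mismatch_frac)
    stop(sprintf(
      "sequence unmappable: best placement has mismatch fraction %.3f (> %.3f)",
      frac, max_mismatch_frac
    ), call. = FALSE)

  list(
    id = id,
    seq = s,
    start = win[1] + best_off,
    end = win[1] + best_off + n - 1L,
    mismatches = as.integer(best_mm),
    compared = as.integer(compared)
  )
}

#' Place a set of sample sequences on the reference window
#'
#' @param sequences Named character vector.
#' @inheritParams map_to_reference
#' @return A `positioned_seqs` list (one record per sequence, named).
#' @export
map_sequences <- function(sequences, reference, window = NULL,
                          max_mismatch_frac = 0.1) {
  recs <- lapply(names(sequences), function(id) {
    map_to_reference(sequences[[id]], reference, window,
                     max_mismatch_frac, id = id)
  })
  names(recs) <- names(sequences)
  structure(recs, class = "positioned_seqs")
}

as_window_vec <- function(window) {
  if (inherits(window, "alignment_window")) c(window$start, window$end)
  else as.integer(window[1:2])
}

## character matrix of positioned samples over their joint coordinate range;
## NA outside each sample's coverage
positioned_matrix <- function(positioned) {
  starts <- vapply(positioned, `[[`, numeric(1), "start")
  ends <- vapply(positioned, `[[`, numeric(1), "end")
  lo <- min(starts)
  hi <- max(ends)
  mat <- matrix(NA_character_, length(positioned), hi - lo + 1L,
    dimnames = list(
      vapply(positioned, function(r) r$id %||% "", character(1)),
      NULL
    )
  )
  for (i in seq_along(positioned)) {
    r <- positioned[[i]]
    mat[i, (r$start - lo + 1L):(r$end - lo + 1L)] <- seq_chars(r$seq)
  }
  attr(mat, "offset") <- lo
  mat
}

#' Call segregating sites
#'
#' A position is segregating iff at least two distinct unambiguous bases
#' (A/C/G/T) are observed among the samples covering it; ambiguity codes
#' contribute no evidence at that site.
#'
#' @param positioned A `positioned_seqs` list (from [map_sequences()] or
#'   [fragment_samples()]).
#' @return Sorted integer vector of 1-based mitogenome positions.
#' @examples
#' ref <- generate_reference(20, origin = 101, seed = 1)
#' s <- c(a = ref$sequence, b = ref$sequence)
#' call_segregating_sites(map_sequences(s, ref))  # integer(0)
#' @export
call_segregating_sites <- function(positioned) {
  if (length(positioned) == 0)
    stop("no sequences supplied", call. = FALSE)
  mat <- positioned_matrix(positioned)
  seg <- vapply(seq_len(ncol(mat)), function(j) {
    obs <- mat[, j]
    obs <- obs[!is.na(obs) & obs %in% DNA_BASES]
    length(unique(obs)) >= 2L
  }, logical(1))
  which(seg) + attr(mat, "offset") - 1L
}

#' Collapse positioned samples into named haplotypes
#'
#' Samples covering every registered variable site unambiguously are
#' assigned a haplotype name: an existing one if the sample agrees with a
#' registered allele vector at every covered position, or — when
#' `allow_new` — a newly registered sequential name built from the sample's
#' substitutions relative to the reference. Samples with partial coverage
#' are not assigned; they receive a consistency set: all registered
#' haplotypes agreeing with them at every covered unambiguous position.
#' Discovery order for simultaneous novelties is sorted sample-id order, so
#' the result is independent of input order.
#'
#' @param positioned A `positioned_seqs` list.
#' @param registry A `haplotype_registry`.
#' @param reference The `ref_sequence` the registry is defined against.
#' @param allow_new Register unmatched full-coverage allele vectors as new
#'   haplotypes (default `FALSE`: such samples are an error).
#' @return List with `assignments` (data.frame: `sample_id`, `haplotype`
#'   (NA when only constrained), `consistent_with` (comma-separated set),
#'   `covered_start`, `covered_end`, `missing_sites`) sorted by sample id,
#'   and `registry` (possibly grown; never shrunk or renamed).
#' @export
assign_haplotypes <- function(positioned, registry, reference,
                              allow_new = FALSE) {
  stopifnot(inherits(registry, "haplotype_registry"))
  ord <- order(vapply(positioned, function(r) as.character(r$id), character(1)))
  positioned <- positioned[ord]

  win <- registry$window
  hap_chars <- lapply(names(registry$haplotypes), function(h) {
    seq_chars(haplotype_sequence(registry, h, reference))
  })
  names(hap_chars) <- names(registry$haplotypes)

  rows <- vector("list", length(positioned))
  for (i in seq_along(positioned)) {
    r <- positioned[[i]]
    sv <- seq_chars(r$seq)
    unamb <- is_unambiguous(sv)
    cov_pos <- r$start:r$end
    sites <- registry_sites(registry)

    ## registered haplotypes agreeing at every covered unambiguous position
    idx <- cov_pos - win[1] + 1L
    consistent <- names(hap_chars)[vapply(hap_chars, function(hc) {
      all(sv[unamb] == hc[idx[unamb]])
    }, logical(1))]

    missing_sites <- sites[!(sites %in% cov_pos[unamb])]
    full_cov <- length(missing_sites) == 0L

    hap <- NA_character_
    if (full_cov) {
      if (length(consistent) >= 1L) {
        hap <- consistent[1]
      } else if (allow_new) {
        ## new haplotype: substitutions vs reference over covered positions
        rv <- seq_chars(substring(
          reference$sequence,
          r$start - reference$origin + 1L,
          r$end - reference$origin + 1L
        ))
        diff <- which(unamb & sv != rv)
        alleles <- stats::setNames(sv[diff], as.character(cov_pos[diff]))
        new_name <- next_haplotype_name(registry)
        registry$haplotypes[[new_name]] <- alleles[order(as.integer(names(alleles)))]
        check_registry_distinct(registry)
        hap_chars[[new_name]] <- seq_chars(haplotype_sequence(registry, new_name, reference))
        hap <- new_name
        consistent <- new_name
      } else {
        stop(sprintf(
          "sample '%s' matches no registered haplotype and allow_new = FALSE",
          r$id
        ), call. = FALSE)
      }
    }

    rows[[i]] <- data.frame(
      sample_id = as.character(r$id),
      haplotype = hap,
      consistent_with = paste(consistent, collapse = ","),
      covered_start = r$start,
      covered_end = r$end,
      missing_sites = paste(missing_sites, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  list(
    assignments = do.call(rbind, rows),
    registry = registry
  )
}

## next sequential name: prefix + (max existing index + 1)
next_haplotype_name <- function(registry) {
  nm <- names(registry$haplotypes)
  idx <- suppressWarnings(as.integer(sub(
    paste0("^", registry$prefix), "", nm
  )))
  nxt <- if (length(idx) == 0 || all(is.na(idx))) 1L else max(idx, na.rm = TRUE) + 1L
  paste0(registry$prefix, nxt)
}

#' Tabulate haplotype counts per region
#'
#' @param assignments Assignment data.frame from [assign_haplotypes()].
#' @param metadata Metadata data.frame with `sample_id` and `region`.
#' @return An integer matrix (regions x haplotypes) of class `pop_table`;
#'   samples that only received a consistency set are excluded and listed
#'   in `attr(, "excluded")`.
#' @export
haplotype_frequencies <- function(assignments, metadata) {
  missing_md <- setdiff(assignments$sample_id, metadata$sample_id)
  if (length(missing_md) > 0)
    stop(sprintf(
      "no region label for sample(s): %s",
      paste(utils::head(missing_md, 5), collapse = ", ")
    ), call. = FALSE)

  assigned <- assignments[!is.na(assignments$haplotype), , drop = FALSE]
  excluded <- assignments$sample_id[is.na(assignments$haplotype)]
  region <- metadata$region[match(assigned$sample_id, metadata$sample_id)]

  regions <- unique(metadata$region)
  haps <- sort(unique(assigned$haplotype))
  tab <- matrix(0L, length(regions), length(haps),
                dimnames = list(regions, haps))
  if (nrow(assigned) > 0) {
    t0 <- table(factor(region, levels = regions),
                factor(assigned$haplotype, levels = haps))
    tab[] <- as.integer(t0)
  }
  structure(tab, class = c("pop_table", "matrix"), excluded = excluded)
}
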