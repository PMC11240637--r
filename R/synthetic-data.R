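## Synthetic mtDNA control-region fixtures
##
## The generator reconstructs the composition of the Hungarian fallow deer
## (Dama dama) control-region survey: 192 animals across six regions, six
## haplotypes (Hun1..Hun6) defined by six substitution-only variable sites,
## all inside a 450-bp sub-window of a 945-bp amplicon.

## amplicon coordinates (1-based, mitogenome convention): the full window is
## the inclusive span between the two primer 5' positions; the 450-bp
## sub-window is the shorter control-region section previously surveyed, and
## is the default denominator length L for nucleotide diversity.
CR_FULL_WINDOW <- c(15386L, 16330L)
CR_SUB_WINDOW <- c(15601L, 16050L)

## fixed variable-site positions, all inside the 450-bp sub-window
CR_SITE_POSITIONS <- c(15620L, 15710L, 15785L, 15860L, 15925L, 16040L)

## haplotype definitions as sets of variable sites carrying the alternate
## base (indices into CR_SITE_POSITIONS); Hun1 is the reference haplotype.
## This is a documented constant of the fixture: it realises the published
## per-region segregating-site counts (NW 1, NM 2, NE 2, SW 3, SM 2, SE 4;
## 6 overall) and d(Hun1,Hun2)=1, but makes no claim about the real
## nucleotide states, which were never printed.
CR_HAPLOTYPE_SITES <- list(
  Hun1 = integer(0),
  Hun2 = 1L,
  Hun3 = c(1L, 2L),
  Hun4 = 3L,
  Hun5 = c(4L, 5L),
  Hun6 = 6L
)

## per-region haplotype compositions for the three fixture variants.
## "regional" realises each Table-style per-region (n, k, RMP) individually:
## the compositions are the unique solutions of derive_counts_from_stats()
## against the published regional RMP entries (SW fixed by its Hd instead;
## its printed RMP is internally inconsistent with its printed Hd).
## "global_192" keeps the region sizes but realises the published global
## counts {66,108,1,1,9,7} exactly. "new_collection_138" is the newly
## collected subset (the published set minus the 54 previously sequenced
## animals), carrying exactly four haplotypes.
CR_COMPOSITIONS <- list(
  regional = list(
    NW = c(Hun1 = 10L, Hun2 = 24L),
    NM = c(Hun1 = 18L, Hun2 = 23L, Hun4 = 1L),
    NE = c(Hun1 = 17L, Hun2 = 23L, Hun3 = 1L),
    SW = c(Hun1 = 19L, Hun2 = 13L, Hun5 = 5L),
    SM = c(Hun1 = 1L, Hun2 = 25L, Hun6 = 5L),
    SE = c(Hun2 = 4L, Hun5 = 2L, Hun6 = 1L)
  ),
  global_192 = list(
    NW = c(Hun1 = 11L, Hun2 = 23L),
    NM = c(Hun1 = 18L, Hun2 = 23L, Hun4 = 1L),
    NE = c(Hun1 = 17L, Hun2 = 23L, Hun3 = 1L),
    SW = c(Hun1 = 19L, Hun2 = 11L, Hun5 = 7L),
    SM = c(Hun1 = 1L, Hun2 = 24L, Hun6 = 6L),
    SE = c(Hun2 = 4L, Hun5 = 2L, Hun6 = 1L)
  ),
  new_collection_138 = list(
    NW = c(Hun1 = 10L, Hun2 = 24L),
    NM = c(Hun1 = 18L, Hun2 = 23L, Hun4 = 1L),
    SW = c(Hun1 = 17L, Hun2 = 13L),
    SM = c(Hun1 = 1L, Hun2 = 25L, Hun6 = 5L),
    SE = c(Hun2 = 1L)
  )
)

#' Generate a synthetic reference sequence
#'
#' Produces a random A/C/G/T sequence anchored at a 1-based mitogenome
#' coordinate, standing in for a control-region reference. Deterministic for
#' a fixed seed.
#'
#' @param length Number of bases (positive integer).
#' @param origin 1-based mitogenome coordinate of the first base.
#' @param seed Integer RNG seed.
#' @return An object of class `ref_sequence`: a list with elements `id`,
#'   `sequence` (uppercase string) and `origin`.
#' @examples
#' ref <- generate_reference(945, origin = 15386, seed = 1)
#' nchar(ref$sequence)
#' @export
generate_reference <- function(length, origin = 1L, seed = 1L) {
  length <- check_count(length, "length")
  origin <- check_count(origin, "origin")
  bases <- with_seed(seed, sample(DNA_BASES, length, replace = TRUE))
  structure(
    list(
      id = sprintf("synthetic_ref_%d_%d", origin, origin + length - 1L),
      sequence = paste(bases, collapse = ""),
      origin = origin
    ),
    class = "ref_sequence"
  )
}

#' @export
print.ref_sequence <- function(x, ...) {
  cat(sprintf(
    "<ref_sequence> %s: %d bp, coordinates %d..%d\n",
    x$id, nchar(x$sequence), x$origin, x$origin + nchar(x$sequence) - 1L
  ))
  invisible(x)
}

## base of the reference at 1-based mitogenome position(s)
ref_base_at <- function(reference, pos) {
  idx <- pos - reference$origin + 1L
  if (any(idx < 1L | idx > nchar(reference$sequence)))
    stop("position outside the reference sequence", call. = FALSE)
  substring(reference$sequence, idx, idx)
}

## deterministic alternate base (transition-like cycle), always != input
alt_base <- function(base) {
  unname(c(A = "G", C = "T", G = "A", T = "C")[base])
}

#' Recover integer haplotype compositions from summary statistics
#'
#' Exhaustively enumerates the compositions of `n` individuals into `k`
#' haplotype classes (order-insensitive, all parts positive) and returns
#' those whose sum of squared frequencies matches a target random match
#' probability within a tolerance. This inverts the published (n, k, RMP)
#' table entries back to the integer counts that produced them.
#'
#' @param n Sample size.
#' @param k Number of haplotypes (1 <= k <= n).
#' @param target_rmp Target sum of squared frequencies, in (0, 1].
#' @param tolerance Maximum absolute residual |achieved - target| accepted.
#' @return A list of solutions sorted by residual; each is a list with
#'   `counts` (non-increasing integer vector), `achieved_sum_sq` and
#'   `residual`. Empty list if no composition is within tolerance.
#' @examples
#' derive_counts_from_stats(7, 3, 0.429)[[1]]$counts  # 4 2 1
#' @export
derive_counts_from_stats <- function(n, k, target_rmp, tolerance = 5e-4) {
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (k > n) stop("'k' must not exceed 'n'", call. = FALSE)
  if (!is.finite(target_rmp) || target_rmp <= 0 || target_rmp > 1)
    stop("'target_rmp' must be in (0, 1]", call. = FALSE)
  if (!is.finite(tolerance) || tolerance < 0)
    stop("'tolerance' must be >= 0", call. = FALSE)

  sols <- list()
  ## non-increasing compositions of n into k positive parts
  recurse <- function(remaining, parts_left, max_part, acc) {
    if (parts_left == 1L) {
      if (remaining <= max_part) {
        counts <- c(acc, remaining)
        ssq <- sum((counts / n)^2)
        res <- abs(ssq - target_rmp)
        if (res <= tolerance)
          sols[[length(sols) + 1L]] <<- list(
            counts = as.integer(counts),
            achieved_sum_sq = ssq,
            residual = res
          )
      }
      return(invisible(NULL))
    }
    ## each remaining part >= 1, so the current part is at most
    ## remaining - (parts_left - 1)
    hi <- min(max_part, remaining - (parts_left - 1L))
    lo <- ceiling(remaining / parts_left)
    if (hi < lo) return(invisible(NULL))
    for (p in hi:lo)
      recurse(remaining - p, parts_left - 1L, p, c(acc, p))
  }
  recurse(n, k, n, integer(0))
  sols[order(vapply(sols, `[[`, numeric(1), "residual"))]
}

#' Build a synthetic fallow deer control-region fixture
#'
#' Realises one of three sample compositions of the Hungarian fallow deer
#' control-region survey as concrete sequence data: a synthetic reference,
#' a haplotype registry (Hun1..Hun6 allele maps), full-amplicon sample
#' sequences and sample metadata. Counts are exact (no multinomial
#' sampling); the seed affects only the reference bases and the order in
#' which haplotypes are dealt to samples within a region.
#'
#' @param variant `"regional"` (per-region compositions individually
#'   matching the published regional statistics, 192 samples),
#'   `"global_192"` (the published global counts 66/108/1/1/9/7), or
#'   `"new_collection_138"` (the newly collected subset, 138 samples, four
#'   haplotypes).
#' @param seed Integer RNG seed.
#' @return A list of class `cr_fixture`: `reference` (`ref_sequence`),
#'   `registry` (`haplotype_registry`), `sequences` (named character vector
#'   of full-window sample sequences), `metadata` (data.frame with columns
#'   `sample_id`, `region`, `source`) and `composition` (the region ->
#'   haplotype -> count list realised).
#' @examples
#' fx <- fallow_deer_fixture("regional", seed = 1)
#' table(fx$metadata$region)
#' @export
fallow_deer_fixture <- function(variant = c("regional", "global_192",
                                            "new_collection_138"),
                                seed = 1L) {
  variant <- match.arg(variant)
  composition <- CR_COMPOSITIONS[[variant]]

  win <- CR_FULL_WINDOW
  ref <- generate_reference(win[2] - win[1] + 1L, origin = win[1], seed = seed)

  registry <- build_fixture_registry(ref)
  hap_seqs <- vapply(
    names(registry$haplotypes),
    function(h) haplotype_sequence(registry, h, ref),
    character(1)
  )

  ids <- character(0)
  regions <- character(0)
  seqs <- character(0)
  with_seed(seed + 1L, {
    for (region in names(composition)) {
      counts <- composition[[region]]
      haps <- rep(names(counts), counts)
      haps <- sample(haps) # deal order only; counts stay exact
      id <- sprintf("%s_%03d", region, seq_along(haps))
      ids <- c(ids, id)
      regions <- c(regions, rep(region, length(haps)))
      seqs <- c(seqs, unname(hap_seqs[haps]))
    }
  })
  names(seqs) <- ids

  structure(
    list(
      reference = ref,
      registry = registry,
      sequences = seqs,
      metadata = data.frame(
        sample_id = ids,
        region = regions,
        source = "synthetic",
        stringsAsFactors = FALSE
      ),
      composition = composition,
      variant = variant,
      seed = as.integer(seed)
    ),
    class = "cr_fixture"
  )
}

## registry of the six fixture haplotypes against a concrete reference
build_fixture_registry <- function(reference) {
  haps <- lapply(CR_HAPLOTYPE_SITES, function(idx) {
    if (length(idx) == 0) return(character(0))
    pos <- CR_SITE_POSITIONS[idx]
    alleles <- alt_base(ref_base_at(reference, pos))
    names(alleles) <- as.character(pos)
    alleles
  })
  haplotype_registry(haps, prefix = "Hun", window = CR_FULL_WINDOW)
}

#' Fragment sample sequences into partial reads
#'
#' Replaces each full-window sequence by a contiguous sub-sequence, emulating
#' the degraded trace material typical of forensic casework. Fragment length
#' and placement are drawn uniformly; deterministic for a fixed seed.
#'
#' @param sequences Named character vector of full-window sequences.
#' @param min_len,max_len Fragment length bounds (bases).
#' @param window Integer vector `c(start, end)`, the mitogenome coordinates
#'   the input sequences span.
#' @param seed Integer RNG seed.
#' @return A `positioned_seqs` list; each record has `id`, `seq`, `start`,
#'   `end` with the coverage interval in mitogenome coordinates.
#' @export
fragment_samples <- function(sequences, min_len, max_len,
                             window = CR_FULL_WINDOW, seed = 1L) {
  min_len <- check_count(min_len, "min_len")
  max_len <- check_count(max_len, "max_len")
  if (min_len > max_len)
    stop("'min_len' must not exceed 'max_len'", call. = FALSE)
  L <- window[2] - window[1] + 1L
  if (max_len > L)
    stop("fragment lengths must not exceed the window length", call. = FALSE)
  if (any(nchar(sequences) != L))
    stop("all sequences must span the full window", call. = FALSE)

  recs <- with_seed(seed, lapply(seq_along(sequences), function(i) {
    len <- if (min_len == max_len) min_len else
      sample(min_len:max_len, 1L)
    off <- if (len == L) 0L else sample(0:(L - len), 1L)
    list(
      id = names(sequences)[i],
      seq = substring(sequences[[i]], off + 1L, off + len),
      start = window[1] + off,
      end = window[1] + off + len - 1L
    )
  }))
  names(recs) <- names(sequences)
  structure(recs, class = "positioned_seqs")
}

#' Write a fixture to disk as standard files
#'
#' Writes the sample sequences as wrapped multi-FASTA, the metadata as TSV
#' (`sample_id`, `region`, `source`), the haplotype registry as JSON, and
#' the reference as FASTA whose header records the coordinate origin.
#'
#' @param fixture A `cr_fixture` from [fallow_deer_fixture()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "cr_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    samples = file.path(dir, "samples.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    registry = file.path(dir, "registry.json"),
    reference = file.path(dir, "reference.fasta")
  )
  write_fasta(fixture$sequences, paths[["samples"]])
  utils::write.table(fixture$metadata, paths[["metadata"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_registry(fixture$registry, paths[["registry"]])
  write_reference(fixture$reference, paths[["reference"]])
  invisible(paths)
}
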