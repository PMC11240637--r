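#' Haplotype registry
#'
#' A registry holds named haplotype definitions as allele maps: for each
#' haplotype, the 1-based mitogenome positions at which it differs from the
#' reference and the base carried there. The reference haplotype has an
#' empty map. Names follow a sequential convention (`Hun1`, `Hun2`, ...).
#'
#' @param haplotypes Named list; each element a named character vector
#'   mapping position (as name) to base. May be empty for the reference
#'   haplotype.
#' @param prefix Naming prefix used when registering new haplotypes.
#' @param window Integer `c(start, end)`: the analysis window all positions
#'   must fall in.
#' @return An object of class `haplotype_registry`.
#' @examples
#' haplotype_registry(list(Hun1 = character(0), Hun2 = c(`15620` = "T")),
#'                    window = c(15386, 16330))
#' @export
haplotype_registry <- function(haplotypes = list(), prefix = "Hun",
                               window = CR_FULL_WINDOW) {
  stopifnot(is.list(haplotypes))
  if (length(haplotypes) > 0 &&
      (is.null(names(haplotypes)) || anyDuplicated(names(haplotypes))))
    stop("haplotype names must be present and unique", call. = FALSE)
  haplotypes <- lapply(haplotypes, function(al) {
    al <- unlist(al)
    if (length(al) == 0) return(character(0))
    if (is.null(names(al)) || any(is.na(suppressWarnings(as.integer(names(al))))))
      stop("allele maps must be named by integer positions", call. = FALSE)
    if (!all(al %in% DNA_BASES))
      stop("allele bases must be A/C/G/T", call. = FALSE)
    pos <- as.integer(names(al))
    if (any(pos < window[1] | pos > window[2]))
      stop("allele positions must lie inside the analysis window", call. = FALSE)
    al[order(pos)]
  })
  reg <- structure(
    list(
      prefix = prefix,
      window = as.integer(window),
      haplotypes = haplotypes
    ),
    class = "haplotype_registry"
  )
  check_registry_distinct(reg)
  reg
}

## allele vectors must be pairwise distinct over the union of variable sites
check_registry_distinct <- function(registry) {
  keys <- vapply(
    registry$haplotypes,
    function(al) paste(names(al), al, sep = ":", collapse = ";"),
    character(1)
  )
  if (anyDuplicated(keys))
    stop("haplotype allele vectors must be pairwise distinct", call. = FALSE)
  invisible(registry)
}

#' @export
print.haplotype_registry <- function(x, ...) {
  cat(sprintf(
    "<haplotype_registry> %d haplotypes (prefix '%s'), window %d..%d\n",
    length(x$haplotypes), x$prefix, x$window[1], x$window[2]
  ))
  for (h in names(x$haplotypes)) {
    al <- x$haplotypes[[h]]
    cat(sprintf(
      "  %s: %s\n", h,
      if (length(al) == 0) "(reference)" else
        paste(names(al), al, sep = ">", collapse = ", ")
    ))
  }
  invisible(x)
}

## sorted union of all variable-site positions known to the registry
registry_sites <- function(registry) {
  sort(unique(as.integer(unlist(lapply(registry$haplotypes, names)))))
}

#' Full sequence of a registered haplotype
#'
#' Materialises a haplotype as a full-window sequence: the reference with
#' the haplotype's substitutions applied.
#'
#' @param registry A `haplotype_registry`.
#' @param name Haplotype name.
#' @param reference A `ref_sequence` covering the registry window.
#' @return A character string.
#' @export
haplotype_sequence <- function(registry, name, reference) {
  if (!name %in% names(registry$haplotypes))
    stop(sprintf("unknown haplotype '%s'", name), call. = FALSE)
  win <- registry$window
  chars <- seq_chars(substring(
    reference$sequence,
    win[1] - reference$origin + 1L,
    win[2] - reference$origin + 1L
  ))
  al <- registry$haplotypes[[name]]
  if (length(al) > 0)
    chars[as.integer(names(al)) - win[1] + 1L] <- unname(al)
  paste(chars, collapse = "")
}

#' Pairwise difference matrix between registered haplotypes
#'
#' Counts, for each haplotype pair, the number of variable sites at which
#' their alleles differ (substitutions only). This is the `d_ij` matrix used
#' by nucleotide diversity and by the sequence-based Fst.
#'
#' @param registry A `haplotype_registry`.
#' @return A symmetric integer matrix with zero diagonal, dimnames the
#'   haplotype names.
#' @export
registry_diff_matrix <- function(registry) {
  haps <- registry$haplotypes
  nm <- names(haps)
  sites <- registry_sites(registry)
  ## allele at every union site; NA = reference base (all definitions carry
  ## non-reference alleles, so NA vs non-NA is a difference)
  allele_mat <- vapply(haps, function(al) {
    v <- rep(NA_character_, length(sites))
    if (length(al) > 0)
      v[match(as.integer(names(al)), sites)] <- unname(al)
    v
  }, character(length(sites)))
  d <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1L)) {
      for (j in (i + 1L):length(nm)) {
        a <- allele_mat[, i]
        b <- allele_mat[, j]
        diff <- xor(is.na(a), is.na(b)) | (!is.na(a) & !is.na(b) & a != b)
        d[i, j] <- d[j, i] <- sum(diff)
      }
    }
  }
  d
}

#' Read or write a haplotype registry as JSON
#'
#' The JSON layout is `{prefix, window, haplotypes: {name: {position: base}}}`.
#'
#' @param registry A `haplotype_registry`.
#' @param path File path.
#' @return `write_registry()` returns the path invisibly; `read_registry()`
#'   returns a `haplotype_registry`.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "haplotype_registry"))
  obj <- list(
    prefix = registry$prefix,
    window = registry$window,
    haplotypes = lapply(registry$haplotypes, function(al) {
      if (length(al) == 0) structure(list(), names = character(0)) else as.list(al)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  obj <- jsonlite::read_json(path)
  haplotype_registry(
    haplotypes = lapply(obj$haplotypes, function(al) {
      unlist(lapply(al, as.character)) %||% character(0)
    }),
    prefix = obj$prefix,
    window = as.integer(unlist(obj$window))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
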