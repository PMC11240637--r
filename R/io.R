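## FASTA I/O via Biostrings; sequences are handled in-package as named
## character vectors of uppercase strings.

#' Read and write multi-FASTA files
#'
#' Thin wrappers around Biostrings that exchange sequences as named
#' character vectors. Output is wrapped at 70 columns.
#'
#' @param sequences Named character vector of A/C/G/T (and IUPAC ambiguity)
#'   strings.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector; `write_fasta()`
#'   returns the path invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  ## keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(toupper(sequences))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

## reference FASTA: the header carries the coordinate origin so the file is
## self-describing ("<id> origin=<pos>")
write_reference <- function(reference, path) {
  seqs <- stats::setNames(
    reference$sequence,
    sprintf("%s origin=%d", reference$id, reference$origin)
  )
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a reference sequence with coordinate origin
#'
#' Reads a single-record FASTA whose header carries an `origin=<pos>` tag
#' giving the 1-based mitogenome coordinate of the first base; `origin`
#' defaults to 1 when the tag is absent.
#'
#' @param path File path.
#' @return A `ref_sequence`.
#' @export
read_reference <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("reference FASTA must contain exactly one record", call. = FALSE)
  header <- names(set)[1]
  m <- regmatches(header, regexpr("origin=([0-9]+)", header))
  origin <- if (length(m) == 1L) as.integer(sub("origin=", "", m)) else 1L
  structure(
    list(
      id = sub("\\s.*$", "", header),
      sequence = toupper(as.character(set)[[1]]),
      origin = origin
    ),
    class = "ref_sequence"
  )
}

#' Read a sample metadata table
#'
#' Reads the tab-separated metadata accompanying a sample FASTA, with
#' required columns `sample_id` and `region` (a `source` column is
#' conventional but optional).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "region") %in% names(md)))
    stop("metadata must have columns 'sample_id' and 'region'", call. = FALSE)
  md
}
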