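#' Create a sequence set
#'
#' A `sequence_set` is the container used throughout the package for contigs,
#' scaffolds and pseudomolecules: a named character vector of upper-case
#' nucleotide sequences over `{A,C,G,T,N}` plus a `kind` attribute recording
#' what stage of assembly the sequences represent.
#'
#' @param seqs Named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param kind One of `"contig"`, `"scaffold"`, `"pseudomolecule"`.
#'   Contigs may not contain `N` gap characters.
#' @return An object of class `sequence_set` (a named character vector with a
#'   `kind` attribute).
#' @examples
#' ss <- sequence_set(c(s1 = "ACGTACGT", s2 = "ACGTNNNNACGT"), kind = "scaffold")
#' seq_lengths(ss)
#' @export
sequence_set <- function(seqs, kind = c("scaffold", "contig", "pseudomolecule")) {
  kind <- match.arg(kind)
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  check_that(is.character(seqs) && length(seqs) >= 1, "no sequences")
  check_that(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
             "sequence ids must be present and unique")
  seqs <- toupper(seqs)
  check_that(all(nchar(seqs) > 0), "sequences must be non-empty")
  bad <- grepl("[^ACGTN]", seqs)
  check_that(!any(bad), "sequences restricted to A,C,G,T,N")
  if (kind == "contig" && any(grepl("N", seqs, fixed = TRUE)))
    stop("contigs may not contain N gap characters", call. = FALSE)
  structure(seqs, kind = kind, class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set of %d %s(s), total %s bp\n",
              length(x), attr(x, "kind"),
              format(sum(nchar(unclass(x))), big.mark = ",")))
  invisible(x)
}

#' @export
`[.sequence_set` <- function(x, i) {
  structure(unclass(x)[i], kind = attr(x, "kind"), class = "sequence_set")
}

#' Sequence lengths of a set
#' @param seqs A [sequence_set()] or named character vector.
#' @return Named integer vector of lengths in bp.
#' @export
seq_lengths <- function(seqs) {
  nchar(unclass(seqs))
}

#' Kind of a sequence set
#' @param seqs A [sequence_set()].
#' @return The `kind` attribute.
#' @export
seq_kind <- function(seqs) attr(seqs, "kind")

#' Read sequences from a FASTA file
#'
#' Multi-record FASTA; line wrapping is ignored. Only the first whitespace
#' token of each header is used as the id.
#'
#' @param path FASTA file.
#' @param kind Passed to [sequence_set()].
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path, kind = "scaffold") {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  sequence_set(x, kind = kind)
}

#' Write sequences to a FASTA file
#' @param seqs A [sequence_set()] or named character vector.
#' @param path Output file.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unclass(seqs))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
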