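#' Read a FASTA file of DNA sequences
#'
#' Wraps [Biostrings::readDNAStringSet()] with the validation the rest of the
#' toolkit relies on: record ids (first whitespace-delimited token of the
#' header) must be unique and non-empty, every sequence must be non-empty and
#' restricted to the `A/C/G/T/N` alphabet, and sequences are uppercased on
#' read.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id. The full header
#'   line is kept in the `description` metadata column.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_("FASTA file does not exist: %s", path)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop_("FASTA record with empty id in %s", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_("duplicate FASTA id(s): %s", paste(dup, collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stop_("empty sequence for FASTA record(s): %s",
          paste(ids[Biostrings::width(x) == 0L], collapse = ", "))
  x <- Biostrings::DNAStringSet(toupper(x))
  bad <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)[, "other", drop = TRUE] -
    Biostrings::letterFrequency(x, "N")[, 1L]
  if (any(bad > 0))
    stop_("non-ACGTN letters in record(s): %s", paste(ids[bad > 0], collapse = ", "))
  names(x) <- ids
  S4Vectors::mcols(x)$description <- headers
  x
}

#' Write DNA sequences to FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_("all sequences must be named to be written to FASTA")
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read a 4-line FASTQ file
#'
#' @param path Path to a FASTQ file.
#' @return A [Biostrings::DNAStringSet] named by read id (qualities are not
#'   retained; no downstream stage consumes base qualities).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_("FASTQ file does not exist: %s", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(x))
}

#' Write DNA sequences to 4-line FASTQ with placeholder qualities
#'
#' Qualities are written as a constant Q30 (`?`) placeholder: no stage of the
#' toolkit consumes base qualities.
#'
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop_("all reads must be named to be written to FASTQ")
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(seqs),
                                        function(w) strrep("?", w), ""))
  x <- Biostrings::QualityScaledDNAStringSet(seqs, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
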