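#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and any IUPAC ambiguity code other than `N`
#' (and any other non-`ACGT` character) is converted to `N`; the number of
#' converted characters is reported with a message and attached as the
#' `"ambiguity_conversions"` attribute. Record ids are the header up to
#' the first whitespace; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file (plain text, wrapped or unwrapped).
#' @param quiet Suppress the ambiguity-conversion message.
#' @return A named [Biostrings::DNAStringSet]; descriptions are stored in
#'   `mcols(x)$description`.
#' @export
read_fasta <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    out <- Biostrings::DNAStringSet()
    attr(out, "ambiguity_conversions") <- 0L
    return(out)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning("no records in FASTA file: ", path)
    out <- Biostrings::DNAStringSet()
    attr(out, "ambiguity_conversions") <- 0L
    return(out)
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence in ", path)
  n_amb <- sum(vapply(seqs, function(s) {
    nchar(s) - nchar(gsub("[^ACGTN]", "", s))
  }, numeric(1)))
  if (n_amb > 0) seqs <- gsub("[^ACGTN]", "N", seqs)
  if (!quiet && n_amb > 0) {
    message(sprintf("read_fasta: converted %d ambiguity character(s) to N", n_amb))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  attr(out, "ambiguity_conversions") <- as.integer(n_amb)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

as_dna_character <- function(x) {
  if (is.character(x)) return(x)
  stats::setNames(as.character(x), names(x))
}
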