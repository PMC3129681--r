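#' Decompose scaffolds into contigs at N-gap runs
#'
#' A scaffold is split at every run of `N` of length at least
#' `gap_threshold`; shorter N-runs are retained inside contigs. Contig
#' coordinates are 0-based half-open in scaffold space, so concatenating
#' contigs and gap runs in order reconstructs each scaffold exactly.
#'
#' @param records A named [Biostrings::DNAStringSet] (or named character
#'   vector) of scaffold sequences, e.g. from [read_fasta()].
#' @param gap_threshold Minimum N-run length (bp) that splits a scaffold.
#' @return An object of class `asm_assembly` with elements `scaffolds`
#'   (DNAStringSet), `gap_threshold`, `contigs` (data.frame with
#'   `contig_id`, `scaffold_id`, `start`, `end`, `length`) and
#'   `contig_seqs` (DNAStringSet keyed by `contig_id`).
#' @export
decompose_scaffolds <- function(records, gap_threshold = 10L) {
  stopifnot(gap_threshold >= 1L)
  seqs <- as_dna_character(records)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("scaffolds must have unique names")
  }
  rows <- vector("list", length(seqs))
  nraw <- charToRaw("N")
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    isn <- charToRaw(s) == nraw
    rl <- rle(as.vector(isn))
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    gap <- rl$values & rl$lengths >= gap_threshold
    # contigs are the maximal stretches between qualifying gaps
    brk <- c(0L, rbind(starts[gap] - 1L, ends[gap]), nchar(s))
    cs <- brk[seq(1L, length(brk), by = 2L)]
    ce <- brk[seq(2L, length(brk), by = 2L)]
    keep <- ce > cs
    cs <- cs[keep]; ce <- ce[keep]
    if (length(cs) == 0L) { rows[[i]] <- NULL; next }
    rows[[i]] <- data.frame(
      scaffold_id = names(seqs)[i],
      start = cs, end = ce,
      stringsAsFactors = FALSE
    )
  }
  contigs <- do.call(rbind, rows)
  if (is.null(contigs)) {
    contigs <- data.frame(scaffold_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  }
  contigs$length <- contigs$end - contigs$start
  contigs$contig_id <- sprintf("%s:%d-%d", contigs$scaffold_id,
                               contigs$start, contigs$end)
  contigs <- contigs[, c("contig_id", "scaffold_id", "start", "end", "length")]
  contig_seqs <- if (nrow(contigs) > 0L) {
    Biostrings::DNAStringSet(stats::setNames(
      substring(seqs[contigs$scaffold_id], contigs$start + 1L, contigs$end),
      contigs$contig_id))
  } else {
    Biostrings::DNAStringSet()
  }
  structure(list(scaffolds = Biostrings::DNAStringSet(seqs),
                 gap_threshold = as.integer(gap_threshold),
                 contigs = contigs,
                 contig_seqs = contig_seqs),
            class = "asm_assembly")
}

#' Rebuild scaffold sequences from a decomposed assembly
#'
#' Reconstructs each scaffold by interleaving contig sequences with the
#' N-gap runs implied by the contig coordinates. Used as the exactness
#' check of the decomposition.
#'
#' @param assembly An `asm_assembly`.
#' @return A named character vector of scaffold sequences.
#' @export
reconstruct_scaffolds <- function(assembly) {
  stopifnot(inherits(assembly, "asm_assembly"))
  seqs <- as_dna_character(assembly$scaffolds)
  ctg <- as_dna_character(assembly$contig_seqs)
  out <- character(length(seqs))
  names(out) <- names(seqs)
  for (nm in names(seqs)) {
    tab <- assembly$contigs[assembly$contigs$scaffold_id == nm, , drop = FALSE]
    if (nrow(tab) == 0L) { out[nm] <- strrep("N", nchar(seqs[[nm]])); next }
    tab <- tab[order(tab$start), , drop = FALSE]
    pieces <- character(0)
    pos <- 0L
    for (j in seq_len(nrow(tab))) {
      if (tab$start[j] > pos) pieces <- c(pieces, strrep("N", tab$start[j] - pos))
      pieces <- c(pieces, ctg[[tab$contig_id[j]]])
      pos <- tab$end[j]
    }
    total <- nchar(seqs[[nm]])
    if (pos < total) pieces <- c(pieces, strrep("N", total - pos))
    out[nm] <- paste0(pieces, collapse = "")
  }
  out
}

#' @export
print.asm_assembly <- function(x, ...) {
  cat(sprintf(
    "asm_assembly: %d scaffold(s), %d contig(s) (gap threshold %d bp)\n",
    length(x$scaffolds), nrow(x$contigs), x$gap_threshold))
  cat(sprintf("  scaffold bases: %s; contig bases: %s\n",
              format(sum(Biostrings::width(x$scaffolds)), big.mark = ","),
              format(sum(x$contigs$length), big.mark = ",")))
  invisible(x)
}
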