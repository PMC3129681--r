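#' Transcript base coverage from chunked assembly alignments
#'
#' Queries are assembly chunks (see [chunk_contigs()]), targets are
#' unspliced transcript sequences. Only the single best alignment per
#' chunk is kept; alignments not exceeding `min_identity` identity over
#' at least `min_align_length` aligned bases are dropped. Covered bases
#' per transcript are the union of retained aligned transcript
#' intervals; the pooled percentage is `100 * sum(covered) / sum(length)`.
#'
#' @param alignments `alignment_list` of chunks vs transcripts.
#' @param transcripts Named transcript sequences.
#' @param min_identity Exclusive identity cutoff (retain identity
#'   strictly greater).
#' @param min_align_length Minimum aligned bases.
#' @return A list with `pooled_percent` and `per_transcript` (data.frame
#'   `transcript_id`, `length`, `covered_bases`, `fraction`).
#' @export
transcript_base_coverage <- function(alignments, transcripts,
                                     min_identity = 0.95,
                                     min_align_length = 100L) {
  tx <- as_dna_character(transcripts)
  if (is.null(names(tx))) stop("transcripts must be named")
  kept <- list()
  if (length(alignments) > 0L) {
    qids <- vapply(alignments, `[[`, character(1), "query_id")
    for (qid in unique(qids)) {
      a <- best_alignment(alignments[qids == qid])
      if (is.null(a)) next
      if (alignment_identity(a) <= min_identity) next
      if (sum(a$blocks[, "len"]) < min_align_length) next
      kept[[length(kept) + 1L]] <- a
    }
  }
  cov <- stats::setNames(numeric(length(tx)), names(tx))
  if (length(kept) > 0L) {
    tids <- vapply(kept, `[[`, character(1), "target_id")
    for (tid in unique(tids)) {
      alns <- kept[tids == tid]
      iv <- IRanges::reduce(IRanges::IRanges(
        start = unlist(lapply(alns, function(a) a$blocks[, "tstart"])) + 1L,
        width = unlist(lapply(alns, function(a) a$blocks[, "len"]))))
      cov[tid] <- sum(IRanges::width(iv))
    }
  }
  lens <- nchar(tx)
  per <- data.frame(transcript_id = names(tx), length = unname(lens),
                    covered_bases = unname(cov),
                    fraction = unname(cov / lens), stringsAsFactors = FALSE)
  list(pooled_percent = 100 * sum(cov) / sum(lens), per_transcript = per)
}

#' cDNA completeness at length-fraction cutoffs
#'
#' A cDNA counts as covered at cutoff c when its best alignment to the
#' assembly meets `min_identity` and its aligned query bases are at
#' least `c` times the cDNA length. Counts are monotone non-increasing
#' in the cutoff.
#'
#' @param alignments `alignment_list` of full cDNAs vs assembly scaffolds.
#' @param cdnas Named cDNA sequences.
#' @param min_identity Identity threshold (inclusive).
#' @param length_cutoffs Length-fraction thresholds, e.g. `c(0.9, 0.5, 0.2)`.
#' @return A data.frame of class `completeness_curve`: `cutoff`, `count`,
#'   `fraction` (of all cDNAs).
#' @export
cdna_completeness <- function(alignments, cdnas, min_identity = 0.90,
                              length_cutoffs = c(0.9, 0.5, 0.2)) {
  cd <- as_dna_character(cdnas)
  if (is.null(names(cd))) stop("cDNAs must be named")
  aligned_frac <- stats::setNames(numeric(length(cd)), names(cd))
  if (length(alignments) > 0L) {
    qids <- vapply(alignments, `[[`, character(1), "query_id")
    for (qid in intersect(unique(qids), names(cd))) {
      a <- best_alignment(alignments[qids == qid])
      if (is.null(a) || alignment_identity(a) < min_identity) next
      aligned_frac[qid] <- sum(a$blocks[, "len"]) / nchar(cd[[qid]])
    }
  }
  cutoffs <- sort(length_cutoffs, decreasing = TRUE)
  counts <- vapply(cutoffs, function(cc) sum(aligned_frac >= cc), integer(1))
  structure(data.frame(cutoff = cutoffs, count = counts,
                       fraction = counts / length(cd)),
            class = c("completeness_curve", "data.frame"))
}

#' Scaffold fragmentation across a gene locus
#'
#' Counts the distinct assembly scaffolds whose aligned reference span
#' intersects the locus interval.
#'
#' @param locus A list or one-row data.frame with `chrom`, `start`,
#'   `end` (0-based half-open reference coordinates).
#' @param alignments `alignment_list` of assembly scaffolds vs the
#'   annotated reference; target ids are chromosome names.
#' @param reference Optional named reference sequences (or lengths) used
#'   to validate the locus coordinates.
#' @return Integer count of scaffolds overlapping the locus.
#' @export
gene_fragmentation <- function(locus, alignments, reference = NULL) {
  stopifnot(!is.null(locus$chrom), locus$start >= 0, locus$end > locus$start)
  if (!is.null(reference)) {
    lens <- if (is.numeric(reference)) reference else
      nchar(as_dna_character(reference))
    if (!locus$chrom %in% names(lens)) {
      stop("locus chromosome not in reference: ", locus$chrom)
    }
    if (locus$end > lens[[locus$chrom]]) {
      stop("locus extends past the end of ", locus$chrom)
    }
  }
  if (length(alignments) == 0L) return(0L)
  tids <- vapply(alignments, `[[`, character(1), "target_id")
  ts <- vapply(alignments, `[[`, numeric(1), "tstart")
  te <- vapply(alignments, `[[`, numeric(1), "tend")
  qids <- vapply(alignments, `[[`, character(1), "query_id")
  hit <- tids == locus$chrom & ts < locus$end & te > locus$start
  length(unique(qids[hit]))
}
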