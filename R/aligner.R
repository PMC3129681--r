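#' Aligner parameter set
#'
#' Defaults are tuned to behave like classical nucleotide aligners on
#' genomic DNA of 90% identity or better: short exact seeds, co-linear
#' seed chaining, then banded affine-gap dynamic programming over each
#' chained region with ungapped X-drop extension of the ends. A gap of
#' length L costs `gap_open + L * gap_extend`.
#'
#' @param k Seed length (8-31).
#' @param min_chain_seeds Minimum co-linear seeds to attempt an alignment.
#' @param band_width Diagonal band width (bp) for the gapped DP; when
#'   `band_width` is at least the query length the exact unbanded fit DP
#'   is used for small targets, so scores equal the unrestricted optimum.
#' @param match,mismatch,gap_open,gap_extend Scoring integers.
#' @param min_identity Minimum alignment identity to report, in (0, 1].
#' @param min_align_length Minimum aligned columns (bp) to report.
#' @param max_hits Seeds occurring more often than this in the index are
#'   skipped (repeat masking).
#' @param xdrop Score drop at which ungapped end extension stops.
#' @param chain_gap Maximum query gap (bp) bridged within one chain.
#' @param max_chains Cap on chained regions evaluated per query/strand
#'   (largest chains first).
#' @param split_drop Score drop that splits a window alignment at an
#'   internal valley, so chains bridging non-homologous sequence do not
#'   report the bridge as aligned.
#' @return A list of class `aligner_params`.
#' @export
aligner_params <- function(k = 12L, min_chain_seeds = 2L, band_width = 64L,
                           match = 1L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, min_identity = 0.90,
                           min_align_length = 100L, max_hits = 64L,
                           xdrop = 20L, chain_gap = 500L, max_chains = 100L,
                           split_drop = 100L) {
  stopifnot(k >= 8L, k <= 31L, min_identity > 0, min_identity <= 1,
            band_width >= 1L, min_chain_seeds >= 1L)
  structure(list(k = as.integer(k),
                 min_chain_seeds = as.integer(min_chain_seeds),
                 band_width = as.integer(band_width),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_identity = min_identity,
                 min_align_length = as.integer(min_align_length),
                 max_hits = as.integer(max_hits), xdrop = as.integer(xdrop),
                 chain_gap = as.integer(chain_gap),
                 max_chains = as.integer(max_chains),
                 split_drop = as.integer(split_drop)),
            class = "aligner_params")
}

#' Build a k-mer index over target sequences
#'
#' Every k-mer position of every target is stored (both strands are
#' handled at query time by reverse-complementing the query); k-mers
#' containing `N` are excluded.
#'
#' @param targets Named [Biostrings::DNAStringSet] or character vector.
#' @param k Seed length.
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(targets, k = 12L) {
  seqs <- as_dna_character(targets)
  if (length(seqs) == 0L) stop("targets must be non-empty")
  if (is.null(names(seqs))) stop("targets must be named")
  ptr <- cpp_build_index(unname(seqs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), target_ids = names(seqs),
                 target_lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("kmer_index: k=%d over %d target(s), %.0f k-mers\n",
              info$k, info$n_targets, info$n_kmers))
  invisible(x)
}

#' Look up the positions of one k-mer in an index
#'
#' @param index A `kmer_index`.
#' @param kmer A string of length `k`.
#' @return data.frame with `target_id` and 0-based `position`.
#' @export
index_lookup <- function(index, kmer) {
  m <- cpp_index_lookup(index$ptr, kmer)
  data.frame(target_id = index$target_ids[m[, 1] + 1L], position = m[, 2],
             stringsAsFactors = FALSE)
}

#' Align queries against an indexed target set
#'
#' Seeds each query on both strands, chains co-linear seeds, aligns each
#' chained region by banded dynamic programming with affine gaps, and
#' left-shifts gaps through homopolymers so equivalent optimal alignments
#' give identical discrepancy coordinates. Alignments failing the
#' identity or length thresholds in `params` are dropped; survivors are
#' sorted by score (descending) within each query.
#'
#' @param queries Named [Biostrings::DNAStringSet] or character vector.
#' @param index A `kmer_index` built with `params$k`.
#' @param params An [aligner_params()] list.
#' @return An `alignment_list`: a flat list of `pairwise_alignment`
#'   records (see [alignment_table()] for a tabular view).
#' @export
align_pairwise <- function(queries, index, params = aligner_params()) {
  stopifnot(inherits(index, "kmer_index"))
  if (params$k != index$k) stop("params$k does not match index k")
  seqs <- as_dna_character(queries)
  if (length(seqs) == 0L) return(new_alignment_list(list()))
  if (is.null(names(seqs))) stop("queries must be named")
  short <- nchar(seqs) < index$k
  if (any(short)) {
    warning(sprintf("%d quer%s shorter than k=%d skipped", sum(short),
                    if (sum(short) == 1L) "y" else "ies", index$k))
  }
  raw <- cpp_align_batch(unname(seqs), index$ptr, unclass(params))
  out <- list()
  for (qi in seq_along(seqs)) {
    for (a in raw[[qi]]) {
      out[[length(out) + 1L]] <- new_pairwise_alignment(
        query_id = names(seqs)[qi],
        target_id = index$target_ids[a$tid],
        strand = a$strand,
        qstart = a$qstart, qend = a$qend,
        tstart = a$tstart, tend = a$tend,
        qsize = nchar(seqs[[qi]]),
        tsize = unname(index$target_lengths[a$tid]),
        blocks = a$blocks,
        matches = a$matches, mismatches = a$mismatches,
        query_gap_bases = a$query_gap_bases,
        target_gap_bases = a$target_gap_bases,
        score = a$score,
        detail = list(mm_tpos = a$mm_tpos, del_runs = a$del_runs,
                      ins_runs = a$ins_runs))
    }
  }
  new_alignment_list(out)
}

new_pairwise_alignment <- function(query_id, target_id, strand, qstart, qend,
                                   tstart, tend, qsize, tsize, blocks,
                                   matches, mismatches, query_gap_bases,
                                   target_gap_bases, score, detail = NULL) {
  colnames(blocks) <- c("qstart", "tstart", "len")
  structure(list(query_id = query_id, target_id = target_id, strand = strand,
                 qstart = qstart, qend = qend, tstart = tstart, tend = tend,
                 qsize = qsize, tsize = tsize, blocks = blocks,
                 matches = matches, mismatches = mismatches,
                 query_gap_bases = query_gap_bases,
                 target_gap_bases = target_gap_bases,
                 score = score, detail = detail),
            class = "pairwise_alignment")
}

new_alignment_list <- function(x) structure(x, class = "alignment_list")

#' @export
`[.alignment_list` <- function(x, i) new_alignment_list(unclass(x)[i])

#' @export
c.alignment_list <- function(...) {
  new_alignment_list(do.call(c, lapply(list(...), unclass)))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "%s:%d-%d (%s) -> %s:%d-%d  id=%.4f score=%g (%dM %dX %dD %dI)\n",
    x$query_id, x$qstart, x$qend, x$strand, x$target_id, x$tstart, x$tend,
    alignment_identity(x), x$score, x$matches, x$mismatches,
    x$query_gap_bases, x$target_gap_bases))
  invisible(x)
}

#' @export
print.alignment_list <- function(x, ...) {
  cat(sprintf("alignment_list with %d alignment(s)\n", length(x)))
  for (a in utils::head(x, 10)) print(a)
  if (length(x) > 10) cat(sprintf("  ... and %d more\n", length(x) - 10))
  invisible(x)
}

#' Identity of a pairwise alignment
#'
#' `matches / (matches + mismatches + query_gap_bases + target_gap_bases)`.
#'
#' @param aln A `pairwise_alignment`.
#' @return Proportion in `[0, 1]`.
#' @export
alignment_identity <- function(aln) {
  denom <- aln$matches + aln$mismatches + aln$query_gap_bases +
    aln$target_gap_bases
  if (denom == 0) return(0)
  aln$matches / denom
}

#' Pick the single best alignment
#'
#' Highest score; ties broken by more matches, then lexicographically
#' smallest target id, then smallest target start, so the choice is
#' deterministic.
#'
#' @param alignments An `alignment_list` (or plain list of alignments).
#' @return A `pairwise_alignment`, or `NULL` for an empty input.
#' @export
best_alignment <- function(alignments) {
  if (length(alignments) == 0L) return(NULL)
  score <- vapply(alignments, `[[`, numeric(1), "score")
  matches <- vapply(alignments, `[[`, numeric(1), "matches")
  tid <- vapply(alignments, `[[`, character(1), "target_id")
  tstart <- vapply(alignments, `[[`, numeric(1), "tstart")
  ord <- order(-score, -matches, tid, tstart, method = "radix")
  alignments[[ord[1L]]]
}

#' Tabular summary of an alignment list
#'
#' @param alignments An `alignment_list`.
#' @return A data.frame with one row per alignment.
#' @export
alignment_table <- function(alignments) {
  if (length(alignments) == 0L) {
    return(data.frame(query_id = character(), target_id = character(),
                      strand = character(), qstart = integer(),
                      qend = integer(), tstart = integer(), tend = integer(),
                      matches = integer(), mismatches = integer(),
                      query_gap_bases = integer(),
                      target_gap_bases = integer(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    query_id = vapply(alignments, `[[`, character(1), "query_id"),
    target_id = vapply(alignments, `[[`, character(1), "target_id"),
    strand = vapply(alignments, `[[`, character(1), "strand"),
    qstart = vapply(alignments, `[[`, numeric(1), "qstart"),
    qend = vapply(alignments, `[[`, numeric(1), "qend"),
    tstart = vapply(alignments, `[[`, numeric(1), "tstart"),
    tend = vapply(alignments, `[[`, numeric(1), "tend"),
    matches = vapply(alignments, `[[`, numeric(1), "matches"),
    mismatches = vapply(alignments, `[[`, numeric(1), "mismatches"),
    query_gap_bases = vapply(alignments, `[[`, numeric(1), "query_gap_bases"),
    target_gap_bases = vapply(alignments, `[[`, numeric(1), "target_gap_bases"),
    identity = vapply(alignments, alignment_identity, numeric(1)),
    score = vapply(alignments, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
}

#' Reverse-complement a nucleotide string
#'
#' @param x A character string over `{A,C,G,T,N}`.
#' @return The reverse complement.
#' @export
revcomp <- function(x) cpp_revcomp(x)
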