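#' Break assembly contigs into non-overlapping chunks
#'
#' Contigs are tiled with `chunk_size` bp segments; a sub-chunk tail is
#' absorbed into the final segment (searched "as a piece of the
#' penultimate segment"), so segment lengths lie in
#' `[chunk_size, 2 * chunk_size)`. Contigs shorter than `chunk_size`
#' yield one segment covering the whole contig.
#'
#' @param assembly An `asm_assembly`.
#' @param chunk_size Segment size in bp (>= 100).
#' @return A data.frame of class `chunk_segments`: `segment_id`,
#'   `contig_id`, `start`, `end` (0-based half-open contig coordinates)
#'   and a `sequences` attribute ([Biostrings::DNAStringSet] keyed by
#'   `segment_id`).
#' @export
chunk_contigs <- function(assembly, chunk_size = 1000L) {
  stopifnot(inherits(assembly, "asm_assembly"), chunk_size >= 100L)
  ctab <- assembly$contigs
  segs <- vector("list", nrow(ctab))
  for (i in seq_len(nrow(ctab))) {
    m <- ctab$length[i]
    n_full <- m %/% chunk_size
    if (n_full <= 1L) {
      starts <- 0L
      ends <- m
    } else {
      starts <- (seq_len(n_full) - 1L) * chunk_size
      ends <- c(starts[-1L], m)  # final segment absorbs the tail
    }
    segs[[i]] <- data.frame(contig_id = ctab$contig_id[i],
                            start = as.integer(starts), end = as.integer(ends),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out$segment_id <- sprintf("%s|%d-%d", out$contig_id, out$start, out$end)
  out <- out[, c("segment_id", "contig_id", "start", "end")]
  ctg <- as_dna_character(assembly$contig_seqs)
  seqs <- Biostrings::DNAStringSet(stats::setNames(
    substring(ctg[out$contig_id], out$start + 1L, out$end), out$segment_id))
  attr(out, "sequences") <- seqs
  class(out) <- c("chunk_segments", "data.frame")
  out
}

#' Sequences of chunk segments
#' @param segments A `chunk_segments` data.frame.
#' @return The [Biostrings::DNAStringSet] of segment sequences.
#' @export
chunk_sequences <- function(segments) attr(segments, "sequences")

#' Identify putative novel segments absent from a reference
#'
#' For each chunk segment, the union of its reference-aligned
#' sub-intervals (alignments at or above `min_identity`) is subtracted;
#' remaining runs strictly longer than `min_novel_length` become
#' putative novel segments with their GC content.
#'
#' @param segments A `chunk_segments` data.frame.
#' @param alignments `alignment_list` of segments vs the reference.
#' @param min_identity Identity threshold for an alignment to mask.
#' @param min_novel_length Minimum unmapped run length, exclusive
#'   (runs of exactly this length are discarded).
#' @return A data.frame of class `novel_segments`: `novel_id`,
#'   `segment_id`, `contig_id`, `start`, `end` (contig coordinates),
#'   `length`, `gc`, `status` (all `putative_novel`), `matched_source`,
#'   plus a `sequences` attribute.
#' @export
find_unmapped_segments <- function(segments, alignments, min_identity = 0.90,
                                   min_novel_length = 50L) {
  stopifnot(inherits(segments, "chunk_segments"))
  seqs <- as_dna_character(chunk_sequences(segments))
  qids <- vapply(alignments, `[[`, character(1), "query_id")
  ident <- vapply(alignments, alignment_identity, numeric(1))
  keep <- ident >= min_identity
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    sid <- segments$segment_id[i]
    seg_len <- segments$end[i] - segments$start[i]
    hit <- which(keep & qids == sid)
    if (length(hit) > 0L) {
      iv <- IRanges::reduce(IRanges::IRanges(
        start = vapply(alignments[hit], `[[`, numeric(1), "qstart") + 1L,
        end = vapply(alignments[hit], `[[`, numeric(1), "qend")))
      unmapped <- IRanges::setdiff(IRanges::IRanges(1L, seg_len), iv)
    } else {
      unmapped <- IRanges::IRanges(1L, seg_len)
    }
    unmapped <- unmapped[IRanges::width(unmapped) > min_novel_length]
    if (length(unmapped) == 0L) next
    for (j in seq_along(unmapped)) {
      s <- IRanges::start(unmapped)[j] - 1L  # back to 0-based
      e <- IRanges::end(unmapped)[j]
      seq <- substr(seqs[[sid]], s + 1L, e)
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = sid, contig_id = segments$contig_id[i],
        start = segments$start[i] + s, end = segments$start[i] + e,
        length = e - s, gc = gc_content(seq), status = "putative_novel",
        matched_source = NA_character_, sequence = seq,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(segment_id = character(), contig_id = character(),
               start = integer(), end = integer(), length = integer(),
               gc = numeric(), status = character(),
               matched_source = character(), sequence = character(),
               stringsAsFactors = FALSE)
  out$novel_id <- if (nrow(out) > 0L)
    sprintf("%s|novel%d", out$segment_id, seq_len(nrow(out))) else character(0)
  seqs_out <- Biostrings::DNAStringSet(stats::setNames(out$sequence, out$novel_id))
  out$sequence <- NULL
  out <- out[, c("novel_id", "segment_id", "contig_id", "start", "end",
                 "length", "gc", "status", "matched_source")]
  attr(out, "sequences") <- seqs_out
  class(out) <- c("novel_segments", "data.frame")
  out
}

#' Sequences of novel segments
#' @param novel A `novel_segments` data.frame.
#' @return The [Biostrings::DNAStringSet] of novel segment sequences.
#' @export
novel_sequences <- function(novel) attr(novel, "sequences")

#' Screen novel segments against a sequence database
#'
#' Segments aligning to any database sequence at `min_identity` over at
#' least `min_length` aligned bases are relabelled (`contaminant` by
#' default; use `label = "annotated_known"` to screen against known
#' BAC/cDNA sets). The per-source attribution is recorded in
#' `matched_source`.
#'
#' @param novel A `novel_segments` data.frame.
#' @param db Named sequences of the screening database.
#' @param min_identity Identity threshold (default the conventional 98%).
#' @param min_length Aligned-length threshold in bp (default 200).
#' @param label Status assigned to matching segments.
#' @param params Aligner parameters for the screen.
#' @return The `novel_segments` data.frame with updated `status` and a
#'   `screen_summary` attribute (list with `n_relabelled`,
#'   `fraction_bases_relabelled`, `per_source` base counts).
#' @export
screen_contamination <- function(novel, db, min_identity = 0.98,
                                 min_length = 200L, label = "contaminant",
                                 params = NULL) {
  stopifnot(inherits(novel, "novel_segments"))
  db_seqs <- as_dna_character(db)
  if (length(db_seqs) == 0L) stop("screening database is empty")
  if (is.null(params)) {
    params <- aligner_params(min_identity = min_identity,
                             min_align_length = as.integer(min_length))
  }
  seqs <- novel_sequences(novel)
  hits <- character(nrow(novel))
  if (nrow(novel) > 0L) {
    idx <- build_index(db_seqs, k = params$k)
    alns <- suppressWarnings(align_pairwise(seqs, idx, params))
    if (length(alns) > 0L) {
      tab <- alignment_table(alns)
      ok <- tab$identity >= min_identity &
        (tab$matches + tab$mismatches) >= min_length
      tab <- tab[ok, , drop = FALSE]
      if (nrow(tab) > 0L) {
        best <- tab[order(-tab$score), , drop = FALSE]
        best <- best[!duplicated(best$query_id), , drop = FALSE]
        m <- match(novel$novel_id, best$query_id)
        hits <- ifelse(is.na(m), "", best$target_id[m])
      }
    }
  }
  relabel <- hits != "" & novel$status == "putative_novel"
  novel$status[relabel] <- label
  novel$matched_source[relabel] <- hits[relabel]
  per_source <- if (any(relabel)) {
    tapply(novel$length[relabel], novel$matched_source[relabel], sum)
  } else {
    numeric(0)
  }
  attr(novel, "screen_summary") <- list(
    label = label,
    n_relabelled = sum(relabel),
    fraction_bases_relabelled =
      if (sum(novel$length) > 0) sum(novel$length[relabel]) / sum(novel$length)
      else 0,
    per_source = per_source)
  novel
}

#' Novel sequence shared between two assemblies
#'
#' Shared bases counted from each direction: the total bases of set A
#' segments having an alignment to any set B segment at `min_identity`,
#' and symmetrically. The single "shared" figure uses the intersection
#' convention (the smaller of the two directional totals).
#'
#' @param set_a,set_b `novel_segments` data.frames (screened; only
#'   `putative_novel` rows are compared).
#' @param min_identity Identity threshold.
#' @param params Aligner parameters.
#' @return A list: `shared_ab`, `shared_ba`, `shared`, `exclusive_a`,
#'   `exclusive_b`, `total_a`, `total_b` (all in bases).
#' @export
shared_novel <- function(set_a, set_b, min_identity = 0.90, params = NULL) {
  stopifnot(inherits(set_a, "novel_segments"), inherits(set_b, "novel_segments"))
  if (is.null(params)) {
    params <- aligner_params(min_identity = min_identity,
                             min_align_length = 50L)
  }
  a <- set_a[set_a$status == "putative_novel", , drop = FALSE]
  b <- set_b[set_b$status == "putative_novel", , drop = FALSE]
  seq_a <- novel_sequences(set_a)[a$novel_id]
  seq_b <- novel_sequences(set_b)[b$novel_id]
  one_way <- function(qs, qdf, ts) {
    if (nrow(qdf) == 0L || length(ts) == 0L) return(0)
    idx <- build_index(ts, k = params$k)
    alns <- suppressWarnings(align_pairwise(qs, idx, params))
    if (length(alns) == 0L) return(0)
    tab <- alignment_table(alns)
    tab <- tab[tab$identity >= min_identity, , drop = FALSE]
    hit_ids <- unique(tab$query_id)
    sum(qdf$length[qdf$novel_id %in% hit_ids])
  }
  total_a <- sum(a$length); total_b <- sum(b$length)
  shared_ab <- one_way(seq_a, a, seq_b)
  shared_ba <- one_way(seq_b, b, seq_a)
  list(shared_ab = shared_ab, shared_ba = shared_ba,
       shared = min(shared_ab, shared_ba),
       exclusive_a = total_a - shared_ab, exclusive_b = total_b - shared_ba,
       total_a = total_a, total_b = total_b)
}

#' GC content of sequences, pooled, as a percentage
#'
#' `100 * (G + C) / (A + C + G + T)`; N and other letters are excluded
#' from the denominator.
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet].
#' @return Percentage in `[0, 100]`.
#' @export
gc_content <- function(sequences) {
  x <- Biostrings::DNAStringSet(as_dna_character(sequences))
  freq <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  tot <- sum(freq)
  if (tot == 0) stop("no unambiguous bases; GC content undefined")
  100 * sum(freq[, c("C", "G")]) / tot
}
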