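#' Detect split-contig mis-assemblies
#'
#' A contig whose uniquely-aligned segments of at least `size_cutoff`
#' aligned bases land on two or more distinct chromosomes is one
#' mis-assembly event. A segment is "unique" when its score is at least
#' `unique_ratio` times the best score of any other alignment of the
#' same contig overlapping at least half of its query interval.
#' Segments on one chromosome that are more than `intra_distance` apart,
#' or in an order inconsistent with the contig, are reported as
#' intrachromosomal events but excluded from the cross-chromosome count
#' unless `include_intrachromosomal = TRUE`.
#'
#' @param alignments Contig-vs-reference `alignment_list`; target ids are
#'   chromosome names.
#' @param size_cutoff Minimum aligned segment length (bp) to consider.
#' @param unique_ratio Score ratio defining alignment uniqueness.
#' @param intra_distance Separation (bp) above which same-chromosome
#'   placements count as an intrachromosomal event.
#' @param include_intrachromosomal Also return intrachromosomal events.
#' @return A list of class `misassembly_events`; each event has
#'   `contig_id`, `type` ("interchromosomal" or "intrachromosomal"),
#'   `placements` (data.frame) and `min_segment_length`.
#' @export
detect_split_contigs <- function(alignments, size_cutoff = 10000L,
                                 unique_ratio = 1.1,
                                 intra_distance = 1e6,
                                 include_intrachromosomal = FALSE) {
  qids <- vapply(alignments, `[[`, character(1), "query_id")
  events <- list()
  for (qid in unique(qids)) {
    alns <- alignments[qids == qid]
    n <- length(alns)
    score <- vapply(alns, `[[`, numeric(1), "score")
    qs <- vapply(alns, `[[`, numeric(1), "qstart")
    qe <- vapply(alns, `[[`, numeric(1), "qend")
    alen <- vapply(alns, function(a) sum(a$blocks[, "len"]), numeric(1))
    # uniqueness: best against overlapping competitors
    unique_ok <- vapply(seq_len(n), function(i) {
      ov <- pmin(qe[i], qe) - pmax(qs[i], qs)
      comp <- which(seq_len(n) != i & ov >= 0.5 * (qe[i] - qs[i]))
      if (length(comp) == 0L) return(TRUE)
      score[i] >= unique_ratio * max(score[comp])
    }, logical(1))
    keep <- which(unique_ok & alen >= size_cutoff)
    if (length(keep) < 2L) next
    sel <- alns[keep]
    placements <- data.frame(
      chromosome = vapply(sel, `[[`, character(1), "target_id"),
      tstart = vapply(sel, `[[`, numeric(1), "tstart"),
      tend = vapply(sel, `[[`, numeric(1), "tend"),
      qstart = vapply(sel, `[[`, numeric(1), "qstart"),
      qend = vapply(sel, `[[`, numeric(1), "qend"),
      strand = vapply(sel, `[[`, character(1), "strand"),
      aligned_length = alen[keep],
      identity = vapply(sel, alignment_identity, numeric(1)),
      stringsAsFactors = FALSE)
    placements <- placements[order(placements$qstart), , drop = FALSE]
    chroms <- unique(placements$chromosome)
    if (length(chroms) >= 2L) {
      events[[length(events) + 1L]] <- structure(
        list(contig_id = qid, type = "interchromosomal",
             placements = placements,
             min_segment_length = min(placements$aligned_length)),
        class = "misassembly_event")
    } else {
      # same chromosome: distant or disordered placements
      p <- placements
      gap_too_far <- any(abs(diff(p$tstart)) > intra_distance)
      disordered <- is.unsorted(p$tstart) && is.unsorted(rev(p$tstart))
      if (gap_too_far || disordered) {
        events[[length(events) + 1L]] <- structure(
          list(contig_id = qid, type = "intrachromosomal",
               placements = placements,
               min_segment_length = min(placements$aligned_length)),
          class = "misassembly_event")
      }
    }
  }
  types <- vapply(events, `[[`, character(1), "type")
  if (!include_intrachromosomal) events <- events[types == "interchromosomal"]
  structure(events, class = "misassembly_events")
}

#' @export
print.misassembly_events <- function(x, ...) {
  cat(sprintf("misassembly_events: %d event(s)\n", length(x)))
  for (e in x) {
    cat(sprintf("  %s [%s]: %s (min segment %g bp)\n", e$contig_id, e$type,
                paste(unique(e$placements$chromosome), collapse = " | "),
                e$min_segment_length))
  }
  invisible(x)
}

#' Normalize a mis-assembly event count to mean scaffold length
#'
#' Returns `N * scale_constant / mean_scaffold_length`: a rate per
#' `scale_constant` bp of scaffold. When comparing assemblies, taking
#' `scale_constant` as the smallest mean scaffold length among them
#' leaves that assembly's raw count unchanged. Note the exact
#' normalisation constant is a package choice; only the proportionality
#' to N and inverse proportionality to L are fixed by the definition.
#'
#' @param n Integer event count.
#' @param mean_scaffold_length Mean scaffold length L (bp) of the
#'   assembly being normalised.
#' @param scale_constant Scale constant C (bp).
#' @return Normalised event count (numeric).
#' @export
normalize_event_count <- function(n, mean_scaffold_length, scale_constant) {
  stopifnot(mean_scaffold_length > 0, scale_constant > 0, n >= 0)
  n * scale_constant / mean_scaffold_length
}

#' Classify a read pair from its two end alignments
#'
#' A pair is `proper` when both ends map to the same scaffold on
#' opposite strands with the leftmost end on `+` and an outer distance
#' within `insert_mean * (1 +/- insert_tolerance)`. Otherwise the first
#' failing label applies, in the order `both_unmapped`,
#' `one_end_unmapped`, `cross_scaffold`, `discordant_orientation`,
#' `discordant_distance`.
#'
#' @param end1,end2 `pairwise_alignment` of each end (its best
#'   alignment), or `NULL` if unmapped.
#' @param insert_mean Expected outer insert size (bp).
#' @param insert_tolerance Relative tolerance, in (0, 1).
#' @return A single classification string.
#' @export
classify_pair <- function(end1, end2, insert_mean, insert_tolerance = 0.3) {
  stopifnot(insert_mean > 0, insert_tolerance > 0, insert_tolerance < 1)
  if (is.null(end1) && is.null(end2)) return("both_unmapped")
  if (is.null(end1) || is.null(end2)) return("one_end_unmapped")
  if (end1$target_id != end2$target_id) return("cross_scaffold")
  if (end1$strand == end2$strand) return("discordant_orientation")
  left <- if (end1$tstart <= end2$tstart) end1 else end2
  if (left$strand != "+") return("discordant_orientation")
  outer <- max(end1$tend, end2$tend) - min(end1$tstart, end2$tstart)
  lo <- insert_mean * (1 - insert_tolerance)
  hi <- insert_mean * (1 + insert_tolerance)
  if (outer < lo || outer > hi) return("discordant_distance")
  "proper"
}

#' Summarise pair classifications
#'
#' @param classes Character vector of [classify_pair()] labels.
#' @return A list with `counts` (named integer vector over all labels)
#'   and `proper_fraction`.
#' @export
concordance_summary <- function(classes) {
  if (length(classes) == 0L) stop("no pairs to summarise")
  labels <- c("proper", "discordant_orientation", "discordant_distance",
              "one_end_unmapped", "both_unmapped", "cross_scaffold")
  bad <- setdiff(unique(classes), labels)
  if (length(bad) > 0L) stop("unknown pair class: ", paste(bad, collapse = ", "))
  counts <- table(factor(classes, levels = labels))
  list(counts = stats::setNames(as.integer(counts), labels),
       proper_fraction = unname(counts["proper"] / length(classes)))
}
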