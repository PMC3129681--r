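#' Tally per-base discrepancies against trusted reference sequences
#'
#' Alignments must have trusted sequences as targets and assembly contigs
#' as queries. Where several alignments cover the same trusted base, the
#' best-scoring alignment owns that base (per-base attribution), so
#' repeat-induced multi-alignments never double-count discrepancies.
#' Substitutions are mismatched columns; deletion bases are trusted bases
#' absent from the assembly (target-side gap bases); insertion bases are
#' assembly bases absent from the trusted sequence, attributed to the
#' alignment owning the trusted position where they occur.
#'
#' Alignments produced by [align_pairwise()] carry the per-event detail
#' needed here; for alignments read from PSL (which stores counts, not
#' positions), pass the query sequences as `assembly` so detail can be
#' recomputed.
#'
#' @param alignments An `alignment_list` (queries = contigs,
#'   targets = trusted sequences).
#' @param trusted Named [Biostrings::DNAStringSet] of trusted sequences.
#' @param assembly Optional named sequences for the queries, used to
#'   recompute event positions for alignments lacking detail.
#' @return A list of class `discrepancy_tally` with `substitutions`,
#'   `deletion_bases`, `insertion_bases`, `aligned_reference_bases`,
#'   `covered_reference_bases`, `total_reference_bases`.
#' @export
tally_discrepancies <- function(alignments, trusted, assembly = NULL) {
  trusted_seqs <- as_dna_character(trusted)
  if (is.null(names(trusted_seqs))) stop("trusted sequences must be named")
  tids <- vapply(alignments, `[[`, character(1), "target_id")
  unknown <- setdiff(unique(tids), names(trusted_seqs))
  if (length(unknown) > 0L) {
    stop("alignment references unknown trusted id(s): ",
         paste(unknown, collapse = ", "))
  }
  alignments <- lapply(alignments, function(a) {
    if (is.null(a$detail)) a <- add_alignment_detail(a, assembly, trusted_seqs)
    a
  })

  subs <- 0; del <- 0; ins <- 0; aligned <- 0; covered <- 0
  del_ev <- 0; ins_ev <- 0
  for (tid in unique(tids)) {
    alns <- alignments[tids == tid]
    score <- vapply(alns, `[[`, numeric(1), "score")
    matches <- vapply(alns, `[[`, numeric(1), "matches")
    qid <- vapply(alns, `[[`, character(1), "query_id")
    tstart <- vapply(alns, `[[`, numeric(1), "tstart")
    ord <- order(-score, -matches, qid, tstart, method = "radix")
    # per-base ownership over this trusted sequence (1-based)
    owned <- logical(nchar(trusted_seqs[[tid]]))
    for (a in alns[ord]) {
      span <- (a$tstart + 1L):a$tend
      free <- !owned[span]
      if (!any(free)) next
      owned[span[free]] <- TRUE
      aligned <- aligned + sum(free)
      d <- a$detail
      if (length(d$mm_tpos) > 0L) {
        subs <- subs + sum(free[d$mm_tpos + 1L - a$tstart])
      }
      if (nrow(d$del_runs) > 0L) {
        for (ri in seq_len(nrow(d$del_runs))) {
          off <- (d$del_runs[ri, 1L] - a$tstart) + seq_len(d$del_runs[ri, 2L])
          n_free <- sum(free[off])
          del <- del + n_free
          if (n_free > 0L) del_ev <- del_ev + 1L
        }
      }
      if (nrow(d$ins_runs) > 0L) {
        anchor <- pmin(d$ins_runs[, 1L], a$tend - 1L) - a$tstart + 1L
        hit <- free[anchor]
        ins <- ins + sum(d$ins_runs[hit, 3L])
        ins_ev <- ins_ev + sum(hit)
      }
    }
    covered <- covered + sum(owned)
  }
  structure(list(substitutions = subs, deletion_bases = del,
                 insertion_bases = ins, deletion_events = del_ev,
                 insertion_events = ins_ev,
                 aligned_reference_bases = aligned,
                 covered_reference_bases = covered,
                 total_reference_bases = sum(nchar(trusted_seqs))),
            class = "discrepancy_tally")
}

#' Recompute per-event alignment detail from sequences
#'
#' Fills the mismatch positions and gap runs that PSL files do not carry,
#' by comparing the aligned blocks of query and target sequences.
#'
#' @param aln A `pairwise_alignment` without detail.
#' @param queries,targets Named sequence sets covering the alignment's
#'   query and target ids.
#' @return The alignment with a `detail` element.
#' @export
add_alignment_detail <- function(aln, queries, targets) {
  if (is.null(queries)) {
    stop("alignment lacks per-event detail; supply the query sequences")
  }
  queries <- as_dna_character(queries)
  targets <- as_dna_character(targets)
  q <- queries[[aln$query_id]]
  if (aln$strand == "-") q <- cpp_revcomp(q)
  t <- targets[[aln$target_id]]
  mm <- integer(0)
  b <- aln$blocks
  for (i in seq_len(nrow(b))) {
    qs <- b[i, "qstart"]; ts <- b[i, "tstart"]; len <- b[i, "len"]
    qb <- charToRaw(substr(q, qs + 1L, qs + len))
    tb <- charToRaw(substr(t, ts + 1L, ts + len))
    bad <- which(qb != tb | qb == charToRaw("N"))
    if (length(bad) > 0L) mm <- c(mm, ts + bad - 1L)
  }
  del <- matrix(integer(0), ncol = 2L)
  ins <- matrix(integer(0), ncol = 3L)
  nb <- nrow(b)
  if (nb > 1L) {
    for (i in seq_len(nb - 1L)) {
      qgap <- b[i + 1L, "qstart"] - (b[i, "qstart"] + b[i, "len"])
      tgap <- b[i + 1L, "tstart"] - (b[i, "tstart"] + b[i, "len"])
      if (tgap > 0L) del <- rbind(del, c(b[i, "tstart"] + b[i, "len"], tgap))
      if (qgap > 0L) {
        ins <- rbind(ins, c(b[i + 1L, "tstart"],
                            b[i, "qstart"] + b[i, "len"], qgap))
      }
    }
  }
  aln$detail <- list(mm_tpos = mm, del_runs = del, ins_runs = ins)
  aln
}

#' Discrepancy rates as percentages of aligned trusted bases
#'
#' Each rate is `100 * events / aligned_reference_bases`. Indel events
#' are counted in bases by default (a 2 bp gap contributes 2); set
#' `per_event = TRUE` to count gap openings instead, in which case the
#' tally must have been built from detailed alignments.
#'
#' @param tally A `discrepancy_tally`.
#' @param per_event Count indels per gap opening instead of per base.
#' @return Named numeric vector: `substitution_rate`, `deletion_rate`,
#'   `insertion_rate` (percent).
#' @export
discrepancy_rates <- function(tally, per_event = FALSE) {
  stopifnot(inherits(tally, "discrepancy_tally"))
  if (tally$aligned_reference_bases <= 0) {
    stop("no aligned reference bases; rates undefined")
  }
  ab <- tally$aligned_reference_bases
  del <- if (per_event) tally$deletion_events else tally$deletion_bases
  ins <- if (per_event) tally$insertion_events else tally$insertion_bases
  c(substitution_rate = 100 * tally$substitutions / ab,
    deletion_rate = 100 * del / ab,
    insertion_rate = 100 * ins / ab)
}

#' Coverage of the trusted reference set
#'
#' @param tally A `discrepancy_tally`.
#' @return Percentage of trusted bases covered by at least one alignment.
#' @export
reference_coverage <- function(tally) {
  stopifnot(inherits(tally, "discrepancy_tally"))
  if (tally$total_reference_bases <= 0) stop("empty trusted set")
  100 * tally$covered_reference_bases / tally$total_reference_bases
}

#' Combine discrepancy tallies
#'
#' Pooling per-clone tallies equals tallying pooled alignments, provided
#' the clones are distinct sequences.
#'
#' @param ... `discrepancy_tally` objects (or one list of them).
#' @return A pooled `discrepancy_tally`.
#' @export
pool_tallies <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "discrepancy_tally")) xs <- xs[[1L]]
  out <- Reduce(function(a, b) Map(`+`, a, b), lapply(xs, unclass))
  structure(out, class = "discrepancy_tally")
}

#' @export
print.discrepancy_tally <- function(x, ...) {
  cat(sprintf(
    "discrepancy_tally: %g sub, %g del bp, %g ins bp over %g aligned bp (%.2f%% of %g covered)\n",
    x$substitutions, x$deletion_bases, x$insertion_bases,
    x$aligned_reference_bases,
    100 * x$covered_reference_bases / max(1, x$total_reference_bases),
    x$total_reference_bases))
  invisible(x)
}
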