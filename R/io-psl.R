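#' Read a PSL (BLAT) alignment file
#'
#' Accepts the 21-column PSL layout with or without the `psLayout`
#' header. Coordinates are kept in the 0-based half-open convention PSL
#' already uses; for minus-strand alignments `qstart`/`qend` are reported
#' on the plus strand while block query starts remain strand-local,
#' mirroring the PSL convention. PSL carries no alignment score, so one
#' is recomputed from the match/mismatch/gap counts under `scoring`.
#'
#' @param path Path to a PSL file.
#' @param scoring An [aligner_params()] whose `match`, `mismatch`,
#'   `gap_open` and `gap_extend` are used to assign scores.
#' @return An `alignment_list`.
#' @export
read_psl <- function(path, scoring = aligner_params()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!grepl("^\\d", line)) next  # header / separator lines
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L) {
      stop(sprintf("malformed PSL line %d: expected 21 fields, got %d",
                   ln, length(f)))
    }
    num <- suppressWarnings(as.integer(f[c(1:8, 11:13, 15:18)]))
    if (anyNA(num)) stop(sprintf("malformed PSL line %d: non-numeric field", ln))
    parse_csv <- function(x) as.integer(strsplit(sub(",$", "", x), ",")[[1]])
    sizes <- parse_csv(f[19])
    qstarts <- parse_csv(f[20])
    tstarts <- parse_csv(f[21])
    bc <- as.integer(f[18])
    if (length(sizes) != bc || length(qstarts) != bc || length(tstarts) != bc) {
      stop(sprintf("malformed PSL line %d: block lists disagree with blockCount", ln))
    }
    blocks <- cbind(qstart = qstarts, tstart = tstarts, len = sizes)
    matches <- as.integer(f[1]); mismatches <- as.integer(f[2])
    qgap <- as.integer(f[8])   # tBaseInsert: target bases absent from query
    tgap <- as.integer(f[6])   # qBaseInsert: query bases absent from target
    n_gap_runs <- as.integer(f[5]) + as.integer(f[7])
    score <- matches * scoring$match + mismatches * scoring$mismatch +
      n_gap_runs * scoring$gap_open + (qgap + tgap) * scoring$gap_extend
    out[[length(out) + 1L]] <- new_pairwise_alignment(
      query_id = f[10], target_id = f[14], strand = f[9],
      qstart = as.integer(f[12]), qend = as.integer(f[13]),
      tstart = as.integer(f[16]), tend = as.integer(f[17]),
      qsize = as.integer(f[11]), tsize = as.integer(f[15]),
      blocks = blocks, matches = matches, mismatches = mismatches,
      query_gap_bases = qgap, target_gap_bases = tgap, score = score)
  }
  new_alignment_list(out)
}

#' Write alignments as PSL
#'
#' @param alignments An `alignment_list`.
#' @param path Output path.
#' @param header Write the `psLayout` header block.
#' @return `path`, invisibly.
#' @export
write_psl <- function(alignments, path, header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(c("psLayout version 3", "", paste(rep("-", 159), collapse = "")),
               con)
  }
  for (a in alignments) {
    b <- a$blocks
    nb <- nrow(b)
    q_ins_n <- 0L; t_ins_n <- 0L
    if (nb > 1L) {
      dq <- b[-1L, "qstart"] - (b[-nb, "qstart"] + b[-nb, "len"])
      dt <- b[-1L, "tstart"] - (b[-nb, "tstart"] + b[-nb, "len"])
      q_ins_n <- sum(dq > 0L)
      t_ins_n <- sum(dt > 0L)
    }
    fields <- c(a$matches, a$mismatches, 0L, 0L,
                q_ins_n, a$target_gap_bases, t_ins_n, a$query_gap_bases,
                a$strand, a$query_id, a$qsize, a$qstart, a$qend,
                a$target_id, a$tsize, a$tstart, a$tend, nb,
                paste0(paste(b[, "len"], collapse = ","), ","),
                paste0(paste(b[, "qstart"], collapse = ","), ","),
                paste0(paste(b[, "tstart"], collapse = ","), ","))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Plus-strand query interval of an alignment
#'
#' @param aln A `pairwise_alignment`.
#' @return Integer vector `c(start, end)`, 0-based half-open, on the
#'   original (plus) strand of the query.
#' @export
query_interval <- function(aln) c(aln$qstart, aln$qend)

#' Strand-local aligned query span from the block list
#' @noRd
aligned_query_bases <- function(aln) sum(aln$blocks[, "len"])
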