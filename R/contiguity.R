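#' N-statistic of a set of sequence lengths
#'
#' The N50 (at `fraction = 0.5`) is the largest length L such that
#' sequences of length at least L together contain at least half of all
#' bases; other fractions give N90 and friends. Ties at the crossing
#' keep the larger L.
#'
#' @param lengths Integer vector of sequence lengths (all >= 1).
#' @param fraction Proportion in (0, 1).
#' @return The N-statistic, an integer length in bp.
#' @export
n_statistic <- function(lengths, fraction = 0.5) {
  if (length(lengths) == 0L) stop("empty length collection")
  stopifnot(all(lengths >= 1), fraction > 0, fraction < 1)
  ls <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(ls)
  idx <- which(cum >= fraction * cum[length(cum)])[1L]
  as.integer(ls[idx])
}

#' Contiguity statistics of an assembly
#'
#' Contigs of length `min_length` or shorter are excluded from all contig
#' statistics ("total assembled bases in contigs greater than
#' `min_length`"); scaffold statistics are unfiltered. Scaffold lengths
#' include internal N gaps, since gaps are part of the scaffold span.
#'
#' @param assembly An `asm_assembly` from [decompose_scaffolds()].
#' @param min_length Contig length cutoff in bp (strictly greater-than).
#' @param fractions N-statistic fractions to report (0.5 gives N50).
#' @return A list of class `assembly_stats`: counts, total bases, N50s
#'   (and any extra `fractions`), plus `mean_scaffold_length`, the
#'   normalisation quantity for mis-assembly counts.
#' @export
assembly_stats <- function(assembly, min_length = 100L, fractions = 0.5) {
  stopifnot(inherits(assembly, "asm_assembly"))
  clen <- assembly$contigs$length
  clen <- clen[clen > min_length]
  if (length(clen) == 0L) {
    stop("no contigs longer than min_length = ", min_length)
  }
  slen <- Biostrings::width(assembly$scaffolds)
  nx_c <- vapply(fractions, function(f) n_statistic(clen, f), integer(1))
  nx_s <- vapply(fractions, function(f) n_statistic(slen, f), integer(1))
  names(nx_c) <- names(nx_s) <- sprintf("N%d", round(fractions * 100))
  structure(list(
    total_contig_bases = sum(as.numeric(clen)),
    total_scaffold_bases = sum(as.numeric(slen)),
    contig_count = length(clen),
    scaffold_count = length(slen),
    n50_contig = unname(nx_c["N50"]),
    n50_scaffold = unname(nx_s["N50"]),
    nx_contig = nx_c,
    nx_scaffold = nx_s,
    max_contig = max(clen),
    max_scaffold = max(slen),
    mean_scaffold_length = mean(slen),
    min_length = as.integer(min_length)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("assembly_stats (contigs > %d bp)\n", x$min_length))
  cat(sprintf("  contigs:   %6d  (%s bp, N50 %s)\n", x$contig_count,
              format(x$total_contig_bases, big.mark = ","),
              format(x$n50_contig, big.mark = ",")))
  cat(sprintf("  scaffolds: %6d  (%s bp, N50 %s, mean %.0f)\n",
              x$scaffold_count, format(x$total_scaffold_bases, big.mark = ","),
              format(x$n50_scaffold, big.mark = ","), x$mean_scaffold_length))
  invisible(x)
}

#' @export
as.data.frame.assembly_stats <- function(x, ...) {
  data.frame(metric = c("contig_count", "scaffold_count", "total_contig_bases",
                        "total_scaffold_bases", "n50_contig", "n50_scaffold",
                        "mean_scaffold_length"),
             value = c(x$contig_count, x$scaffold_count, x$total_contig_bases,
                       x$total_scaffold_bases, x$n50_contig, x$n50_scaffold,
                       x$mean_scaffold_length),
             stringsAsFactors = FALSE)
}
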