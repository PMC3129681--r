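#' Specification of a synthetic truth genome
#'
#' Defaults emulate a compact vertebrate genome: genome-wide GC near
#' 41.6%, about 10% interspersed repeats organised in families of
#' diverged copies, and one gene locus per ~50 kbp with its unspliced
#' transcript taken from the genomic sequence.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param lengths Chromosome lengths in bp (recycled to `n_chromosomes`).
#' @param gc Genome-wide GC proportion in (0, 1).
#' @param repeat_fraction Fraction of the genome covered by planted
#'   repeat copies, in `[0, 0.5]`.
#' @param repeat_unit_length Length of one repeat unit (bp).
#' @param repeat_copy_divergence Per-base substitution divergence of each
#'   planted copy from its family consensus.
#' @param gene_spacing One gene locus per this many bp.
#' @param transcript_length_range Min/max unspliced transcript length (bp).
#' @param seed Integer seed; the genome is deterministic given the spec.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 4L, lengths = 1250000L, gc = 0.416,
                        repeat_fraction = 0.10, repeat_unit_length = 500L,
                        repeat_copy_divergence = 0.02,
                        gene_spacing = 50000L,
                        transcript_length_range = c(1000L, 8000L),
                        seed = 1L) {
  stopifnot(gc > 0, gc < 1, repeat_fraction >= 0, repeat_fraction <= 0.5,
            n_chromosomes >= 1L, all(lengths >= 10000L))
  lengths <- rep_len(as.integer(lengths), n_chromosomes)
  structure(list(n_chromosomes = as.integer(n_chromosomes), lengths = lengths,
                 gc = gc, repeat_fraction = repeat_fraction,
                 repeat_unit_length = as.integer(repeat_unit_length),
                 repeat_copy_divergence = repeat_copy_divergence,
                 gene_spacing = as.integer(gene_spacing),
                 transcript_length_range = as.integer(transcript_length_range),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

random_seq <- function(n, gc) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

#' Generate a synthetic truth genome with repeats and gene annotations
#'
#' Chromosome sequences are drawn base-by-base at the target GC; repeat
#' families (each a consensus unit copied several times with
#' `repeat_copy_divergence` substitutions per copy) overwrite the
#' background until `repeat_fraction` of the genome is repetitive; gene
#' loci are placed every `gene_spacing` bp and their unspliced
#' transcripts extracted from the genomic sequence.
#'
#' @param spec A [genome_spec()].
#' @return A list of class `truth_genome`: `chromosomes`
#'   ([Biostrings::DNAStringSet]), `genes` (data.frame `gene_id`,
#'   `chrom`, `start`, `end`, 0-based half-open), `transcripts`
#'   (DNAStringSet keyed by gene id), `repeats` (data.frame of planted
#'   copy intervals) and the `spec`.
#' @export
generate_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    chrom_names <- sprintf("chr%d", seq_len(spec$n_chromosomes))
    chroms <- stats::setNames(
      vapply(spec$lengths, random_seq, character(1), gc = spec$gc),
      chrom_names)

    rep_rows <- list()
    if (spec$repeat_fraction > 0) {
      unit <- spec$repeat_unit_length
      total_copies <- floor(sum(spec$lengths) * spec$repeat_fraction / unit)
      copies_per_family <- 10L
      n_families <- max(1L, ceiling(total_copies / copies_per_family))
      chrom_chars <- lapply(chroms, function(s) strsplit(s, "", fixed = TRUE)[[1]])
      for (fam in seq_len(n_families)) {
        consensus <- random_seq(unit, spec$gc)
        n_copies <- min(copies_per_family, total_copies)
        total_copies <- total_copies - n_copies
        if (n_copies <= 0L) break
        for (cp in seq_len(n_copies)) {
          ci <- sample.int(spec$n_chromosomes, 1L, prob = spec$lengths)
          s <- sample.int(spec$lengths[ci] - unit, 1L)
          copy <- diverge_seq(consensus, spec$repeat_copy_divergence)
          chrom_chars[[ci]][(s + 1L):(s + unit)] <-
            strsplit(copy, "", fixed = TRUE)[[1]]
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            family = fam, chrom = chrom_names[ci], start = s, end = s + unit,
            stringsAsFactors = FALSE)
        }
      }
      chroms <- stats::setNames(
        vapply(chrom_chars, paste0, character(1), collapse = ""), chrom_names)
    }
    repeats <- if (length(rep_rows) > 0L) do.call(rbind, rep_rows) else
      data.frame(family = integer(), chrom = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)

    gene_rows <- list()
    for (ci in seq_len(spec$n_chromosomes)) {
      n_genes <- spec$lengths[ci] %/% spec$gene_spacing
      if (n_genes == 0L) next
      lens <- sample(seq(spec$transcript_length_range[1L],
                         spec$transcript_length_range[2L]), n_genes,
                     replace = TRUE)
      # one gene per spacing window, at a random offset that fits
      starts <- (seq_len(n_genes) - 1L) * spec$gene_spacing +
        vapply(lens, function(l) {
          sample.int(max(1L, spec$gene_spacing - l), 1L) - 1L
        }, integer(1))
      ok <- starts + lens <= spec$lengths[ci]
      gene_rows[[ci]] <- data.frame(chrom = chrom_names[ci],
                                    start = starts[ok], end = (starts + lens)[ok],
                                    stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, gene_rows)
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "chrom", "start", "end")]
    transcripts <- Biostrings::DNAStringSet(stats::setNames(
      substring(chroms[genes$chrom], genes$start + 1L, genes$end),
      genes$gene_id))

    structure(list(chromosomes = Biostrings::DNAStringSet(chroms),
                   genes = genes, transcripts = transcripts,
                   repeats = repeats, spec = spec),
              class = "truth_genome")
  })
}

diverge_seq <- function(seq, rate) {
  n <- nchar(seq)
  n_mut <- rbinom(1L, n, rate)
  if (n_mut == 0L) return(seq)
  pos <- sample.int(n, n_mut)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- substitute_bases(ch[pos])
  paste0(ch, collapse = "")
}

# random base different from the original, vectorised
substitute_bases <- function(orig) {
  bases <- c("A", "C", "G", "T")
  alt <- matrix(c("C", "G", "T",
                  "A", "G", "T",
                  "A", "C", "T",
                  "A", "C", "G"), nrow = 4L, byrow = TRUE,
                dimnames = list(bases, NULL))
  alt[cbind(match(orig, bases), sample.int(3L, length(orig), replace = TRUE))]
}

#' @export
print.truth_genome <- function(x, ...) {
  cat(sprintf(
    "truth_genome: %d chromosome(s), %s bp, GC %.1f%%, %d gene(s), %d repeat copies\n",
    length(x$chromosomes),
    format(sum(Biostrings::width(x$chromosomes)), big.mark = ","),
    gc_content(x$chromosomes), nrow(x$genes), nrow(x$repeats)))
  invisible(x)
}
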