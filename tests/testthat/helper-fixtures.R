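# Session-cached synthetic fixtures so expensive objects are built once.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

random_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

small_genome <- function() {
  fixture("small_genome", function() {
    generate_genome(genome_spec(n_chromosomes = 2L, lengths = 300000L,
                                gene_spacing = 50000L, seed = 101L))
  })
}

small_corruption <- function() {
  fixture("small_corruption", function() {
    corrupt_assembly(small_genome(), corruption_spec(
      target_contig_n50 = 15000L, target_scaffold_n50 = 80000L,
      n_misjoins = 2L, contaminant_fraction = 0.03,
      n_novel_inserts = 8L, seed = 101L))
  })
}

small_alignments <- function() {
  fixture("small_alignments", function() {
    idx <- build_index(small_genome()$chromosomes, k = 12L)
    suppressWarnings(align_pairwise(
      small_corruption()$assembly$contig_seqs, idx,
      aligner_params(min_identity = 0.9, min_align_length = 100L)))
  })
}

# hand-built alignment with per-event detail recomputed from sequences
manual_alignment <- function(query_id, target_id, queries, targets, blocks,
                             strand = "+", score = NULL) {
  if (!is.character(queries)) queries <- stats::setNames(as.character(queries), names(queries))
  if (!is.character(targets)) targets <- stats::setNames(as.character(targets), names(targets))
  q <- queries[[query_id]]
  t <- targets[[target_id]]
  nb <- nrow(blocks)
  matches <- 0L; mismatches <- 0L
  for (i in seq_len(nb)) {
    qs <- blocks[i, 1]; ts <- blocks[i, 2]; len <- blocks[i, 3]
    qb <- strsplit(substr(q, qs + 1, qs + len), "")[[1]]
    tb <- strsplit(substr(t, ts + 1, ts + len), "")[[1]]
    matches <- matches + sum(qb == tb)
    mismatches <- mismatches + sum(qb != tb)
  }
  qgap <- 0L; tgap <- 0L
  if (nb > 1L) {
    qgap <- sum(blocks[-1, 2] - (blocks[-nb, 2] + blocks[-nb, 3]))
    tgap <- sum(blocks[-1, 1] - (blocks[-nb, 1] + blocks[-nb, 3]))
  }
  if (is.null(score)) score <- matches - 3 * mismatches - 2 * (qgap + tgap)
  aln <- asmappraise:::new_pairwise_alignment(
    query_id = query_id, target_id = target_id, strand = strand,
    qstart = blocks[1, 1], qend = blocks[nb, 1] + blocks[nb, 3],
    tstart = blocks[1, 2], tend = blocks[nb, 2] + blocks[nb, 3],
    qsize = nchar(q), tsize = nchar(t),
    blocks = blocks, matches = matches, mismatches = mismatches,
    query_gap_bases = qgap, target_gap_bases = tgap, score = score)
  add_alignment_detail(aln, queries, targets)
}

as_alignment_list <- function(...) asmappraise:::new_alignment_list(list(...))
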