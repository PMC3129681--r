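mk_cov_aln <- function(qid, tid, tstart, len, mismatches = 0L, qsize = 1000L,
                       tsize = 5000L, qstart = 0L) {
  asmappraise:::new_pairwise_alignment(
    query_id = qid, target_id = tid, strand = "+",
    qstart = qstart, qend = qstart + len, tstart = tstart, tend = tstart + len,
    qsize = qsize, tsize = tsize,
    blocks = cbind(as.integer(qstart), as.integer(tstart), as.integer(len)),
    matches = len - mismatches, mismatches = as.integer(mismatches),
    query_gap_bases = 0L, target_gap_bases = 0L,
    score = len - 4 * mismatches)
}

test_that("transcript coverage keeps only filtered best alignments", {
  tx <- c(tx1 = random_dna(200, seed = 91))
  # 96% identity over 120 bp -> retained
  good <- mk_cov_aln("chunk1", "tx1", 0, 120, mismatches = 4)
  out <- transcript_base_coverage(as_alignment_list(good), tx)
  expect_equal(out$per_transcript$covered_bases, 120)
  # 94% identity -> dropped (cutoff is strictly greater than 95%)
  bad <- mk_cov_aln("chunk2", "tx1", 0, 120, mismatches = 8)
  out2 <- transcript_base_coverage(as_alignment_list(bad), tx)
  expect_equal(out2$per_transcript$covered_bases, 0)
  # exactly 95% identity is not "greater than 95%"
  edge <- mk_cov_aln("chunk3", "tx1", 0, 120, mismatches = 6)
  out3 <- transcript_base_coverage(as_alignment_list(edge), tx)
  expect_equal(out3$per_transcript$covered_bases, 0)
  # below the length cutoff -> dropped
  short <- mk_cov_aln("chunk4", "tx1", 0, 90)
  expect_equal(transcript_base_coverage(
    as_alignment_list(short), tx)$per_transcript$covered_bases, 0)
})

test_that("covered bases are the union of retained intervals", {
  tx <- c(tx1 = random_dna(300, seed = 92))
  a <- mk_cov_aln("chunk1", "tx1", 0, 120)
  b <- mk_cov_aln("chunk2", "tx1", 60, 140)  # [60, 200)
  out <- transcript_base_coverage(as_alignment_list(a, b), tx)
  expect_equal(out$per_transcript$covered_bases, 200)
  expect_equal(out$pooled_percent, 100 * 200 / 300)
})

test_that("interval union equals a brute-force base set on random cases", {
  set.seed(93)
  for (case in 1:50) {
    tx_len <- sample(500:2000, 1)
    tx <- stats::setNames(random_dna(tx_len), "tx")
    n <- sample(1:12, 1)
    starts <- sample(0:(tx_len - 150), n, replace = TRUE)
    lens <- sample(100:150, n, replace = TRUE)
    lens <- pmin(lens, tx_len - starts)
    alns <- lapply(seq_len(n), function(i) {
      mk_cov_aln(sprintf("c%d", i), "tx", starts[i], lens[i])
    })
    out <- transcript_base_coverage(do.call(as_alignment_list, alns), tx)
    base_set <- logical(tx_len)
    for (i in seq_len(n)) base_set[(starts[i] + 1):(starts[i] + lens[i])] <- TRUE
    expect_equal(out$per_transcript$covered_bases, sum(base_set))
  }
})

test_that("pooled coverage is invariant to batch splitting", {
  g <- small_genome()
  cr <- small_corruption()
  segs <- chunk_contigs(cr$assembly, 1000)
  idx <- build_index(g$transcripts, k = 12)
  pr <- aligner_params(min_identity = 0.95, min_align_length = 100L)
  al <- suppressWarnings(align_pairwise(chunk_sequences(segs), idx, pr))
  full <- transcript_base_coverage(al, g$transcripts)
  qids <- vapply(al, `[[`, character(1), "query_id")
  half <- unique(qids)[seq_len(floor(length(unique(qids)) / 2))]
  a1 <- al[qids %in% half]
  a2 <- al[!qids %in% half]
  merged <- c(a1, a2)
  again <- transcript_base_coverage(merged, g$transcripts)
  expect_equal(full$pooled_percent, again$pooled_percent)
})

test_that("cdna completeness counts are monotone in the length cutoff", {
  cd <- c(cd1 = random_dna(1000, seed = 94), cd2 = random_dna(1000, seed = 95))
  # cd1: 950 aligned query bases at high identity
  a <- mk_cov_aln("cd1", "sc1", 100, 950, qsize = 1000L)
  # cd2: 300 aligned bases
  b <- mk_cov_aln("cd2", "sc1", 2000, 300, qsize = 1000L)
  curve <- cdna_completeness(as_alignment_list(a, b), cd)
  expect_equal(curve$cutoff, c(0.9, 0.5, 0.2))
  expect_equal(curve$count, c(1L, 1L, 2L))
  expect_true(all(diff(curve$count) >= 0))  # monotone when sorted descending
  expect_equal(curve$fraction, curve$count / 2)
})

test_that("fragmented cDNAs gain completeness only at low cutoffs", {
  g <- small_genome()
  # an assembly broken so each transcript is split across >= 2 contigs
  tx <- g$transcripts[Biostrings::width(g$transcripts) >= 2000]
  pieces <- list()
  for (nm in names(tx)) {
    s <- as.character(tx[[nm]])
    mid <- nchar(s) %/% 2
    pieces[[paste0(nm, "_a")]] <- substr(s, 1, mid)
    pieces[[paste0(nm, "_b")]] <- substr(s, mid + 1, nchar(s))
  }
  asm_idx <- build_index(unlist(pieces), k = 12)
  al <- suppressWarnings(align_pairwise(tx, asm_idx,
        aligner_params(min_identity = 0.9, min_align_length = 100L)))
  curve <- cdna_completeness(al, tx)
  c90 <- curve$count[curve$cutoff == 0.9]
  c20 <- curve$count[curve$cutoff == 0.2]
  expect_gt(c20, c90)
  expect_equal(c90, 0L)  # nothing spans 90% when every cDNA is halved
})

test_that("gene fragmentation counts distinct overlapping scaffolds", {
  locus <- list(chrom = "chr1", start = 10000, end = 15000)
  a <- mk_cov_aln("sc1", "chr1", 8000, 9000, tsize = 100000L)
  out <- gene_fragmentation(locus, as_alignment_list(a))
  expect_equal(out, 1L)
  b <- mk_cov_aln("sc2", "chr1", 14000, 3000, tsize = 100000L)
  c2 <- mk_cov_aln("sc3", "chr2", 10000, 9000, tsize = 100000L)
  expect_equal(gene_fragmentation(locus, as_alignment_list(a, b, c2)), 2L)
  none <- list(chrom = "chr1", start = 50000, end = 51000)
  expect_equal(gene_fragmentation(none, as_alignment_list(a, b, c2)), 0L)
  expect_error(gene_fragmentation(list(chrom = "chrX", start = 0, end = 10),
                                  as_alignment_list(a),
                                  reference = c(chr1 = 100000)),
               "not in reference")
})

test_that("a gene planted across assembly breaks spans breaks + 1 scaffolds", {
  g <- small_genome()
  gene <- g$genes[which(g$genes$end - g$genes$start >= 4000)[1], ]
  chrom <- as.character(g$chromosomes[[gene$chrom]])
  # split the locus region at 3 internal points -> 4 scaffolds overlap it
  brk <- round(seq(gene$start, gene$end, length.out = 5))
  fl <- 3000
  parts <- stats::setNames(
    vapply(1:4, function(i) {
      substr(chrom, max(1, brk[i] - ifelse(i == 1, fl, 0)) + 1,
             min(nchar(chrom), brk[i + 1] + ifelse(i == 4, fl, 0)))
    }, character(1)),
    sprintf("scaf%d", 1:4))
  idx <- build_index(g$chromosomes, k = 12)
  al <- suppressWarnings(align_pairwise(parts, idx,
        aligner_params(min_align_length = 100L)))
  best_per <- do.call(as_alignment_list, lapply(split(
    seq_along(al), vapply(al, `[[`, character(1), "query_id")),
    function(ix) best_alignment(al[ix])))
  expect_equal(gene_fragmentation(
    list(chrom = gene$chrom, start = gene$start, end = gene$end), best_per), 4L)
})
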