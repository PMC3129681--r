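test_that("chunking tiles contigs with tail absorption", {
  asm <- decompose_scaffolds(c(
    a = random_dna(2500, seed = 51),
    b = random_dna(1000, seed = 52),
    c = random_dna(999, seed = 53)))
  segs <- chunk_contigs(asm, 1000)
  a_segs <- segs[segs$contig_id == "a:0-2500", ]
  expect_equal(a_segs$start, c(0L, 1000L))
  expect_equal(a_segs$end, c(1000L, 2500L))
  expect_equal(segs[segs$contig_id == "b:0-1000", c("start", "end")],
               data.frame(start = 0L, end = 1000L),
               ignore_attr = TRUE)
  expect_equal(segs[segs$contig_id == "c:0-999", c("start", "end")],
               data.frame(start = 0L, end = 999L),
               ignore_attr = TRUE)
  # all segment lengths in [chunk, 2*chunk) except whole short contigs
  lens <- segs$end - segs$start
  expect_true(all(lens < 2000))
})

test_that("chunk segments concatenate back to their contig", {
  set.seed(54)
  asm <- decompose_scaffolds(stats::setNames(
    vapply(sample(500:5000, 20), random_dna, character(1)),
    sprintf("ctg%02d", 1:20)))
  segs <- chunk_contigs(asm, 1000)
  seqs <- as.character(chunk_sequences(segs))
  for (cid in asm$contigs$contig_id) {
    sub <- segs[segs$contig_id == cid, ]
    sub <- sub[order(sub$start), ]
    expect_equal(paste0(seqs[sub$segment_id], collapse = ""),
                 as.character(asm$contig_seqs[[cid]]))
  }
})

test_that("unmapped runs become novel segments only above the length cutoff", {
  asm <- decompose_scaffolds(c(a = random_dna(1000, seed = 55),
                               b = random_dna(1000, seed = 56),
                               c = random_dna(1000, seed = 57)))
  segs <- chunk_contigs(asm, 1000)
  seqs <- as.character(chunk_sequences(segs))
  ref <- c(ref1 = random_dna(2000, seed = 58))
  mk <- function(sid, qstart, qend) {
    asmappraise:::new_pairwise_alignment(
      query_id = sid, target_id = "ref1", strand = "+",
      qstart = qstart, qend = qend, tstart = 0, tend = qend - qstart,
      qsize = 1000, tsize = 2000,
      blocks = cbind(as.integer(qstart), 0L, as.integer(qend - qstart)),
      matches = qend - qstart, mismatches = 0L, query_gap_bases = 0L,
      target_gap_bases = 0L, score = qend - qstart)
  }
  sid_a <- segs$segment_id[segs$contig_id == "a:0-1000"]
  sid_b <- segs$segment_id[segs$contig_id == "b:0-1000"]
  al <- as_alignment_list(mk(sid_a, 0, 940),   # leaves a 60 bp run
                          mk(sid_b, 0, 950))   # leaves a 50 bp run (dropped)
  nv <- find_unmapped_segments(segs, al, min_identity = 0.9,
                               min_novel_length = 50)
  expect_equal(sort(nv$contig_id),
               sort(c("a:0-1000", "c:0-1000")))
  expect_equal(nv$length[nv$contig_id == "a:0-1000"], 60)
  expect_equal(nv$length[nv$contig_id == "c:0-1000"], 1000)
  # a fully unaligned segment is wholly novel
  expect_equal(sum(nv$length), 1060)
})

test_that("fully aligned segments produce no novel sequence", {
  g <- small_genome()
  chrom1 <- as.character(g$chromosomes[[1]])
  asm <- decompose_scaffolds(c(copy = substr(chrom1, 10001, 60000)))
  segs <- chunk_contigs(asm, 1000)
  idx <- build_index(g$chromosomes, k = 12)
  al <- align_pairwise(chunk_sequences(segs), idx,
                       aligner_params(min_align_length = 50L))
  nv <- find_unmapped_segments(segs, al)
  expect_equal(nrow(nv), 0L)
})

test_that("contamination screening relabels verbatim matches only", {
  contam_src <- c(ecoli = random_dna(5000, gc = 0.45, seed = 61))
  novel_real <- random_dna(800, gc = 0.54, seed = 62)
  asm <- decompose_scaffolds(c(
    x = substr(contam_src[["ecoli"]], 1001, 1500),
    y = novel_real))
  segs <- chunk_contigs(asm, 1000)
  nv <- find_unmapped_segments(segs, as_alignment_list())
  expect_equal(nrow(nv), 2L)
  out <- screen_contamination(nv, contam_src)
  expect_equal(out$status[out$contig_id == "x:0-500"], "contaminant")
  expect_equal(out$matched_source[out$contig_id == "x:0-500"], "ecoli")
  expect_equal(out$status[out$contig_id == "y:0-800"], "putative_novel")
  s <- attr(out, "screen_summary")
  expect_equal(s$n_relabelled, 1L)
  # screening against known sequences uses a different label
  out2 <- screen_contamination(nv, c(known = novel_real),
                               label = "annotated_known")
  expect_equal(out2$status[out2$contig_id == "y:0-800"], "annotated_known")
  expect_error(screen_contamination(nv, Biostrings::DNAStringSet()), "empty")
})

test_that("shared novel bases are symmetric for identical sets and zero for disjoint", {
  seqs <- vapply(1:5, function(i) random_dna(1200, seed = 70 + i),
                 character(1))
  asm_a <- decompose_scaffolds(stats::setNames(seqs, sprintf("a%d", 1:5)))
  nv_a <- find_unmapped_segments(chunk_contigs(asm_a, 1000),
                                 as_alignment_list())
  sh <- shared_novel(nv_a, nv_a)
  expect_equal(sh$shared_ab, sum(nv_a$length))
  expect_equal(sh$shared, sum(nv_a$length))
  expect_equal(sh$exclusive_a, 0)
  other <- vapply(1:5, function(i) random_dna(1200, seed = 80 + i),
                  character(1))
  asm_b <- decompose_scaffolds(stats::setNames(other, sprintf("b%d", 1:5)))
  nv_b <- find_unmapped_segments(chunk_contigs(asm_b, 1000),
                                 as_alignment_list())
  sh2 <- shared_novel(nv_a, nv_b)
  expect_equal(sh2$shared, 0)
  expect_equal(sh2$exclusive_a, sum(nv_a$length))
})

test_that("gc_content counts G+C over unambiguous bases as a percentage", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATNNNGC"), 50)
  expect_error(gc_content("NNNN"), "GC content undefined")
  s <- random_dna(20000, gc = 0.542, seed = 90)
  expect_equal(gc_content(s), gc_content(revcomp(s)))
  expect_lt(abs(gc_content(s) - 54.2), 1.5)
})

test_that("novel bases shrink monotonically as the identity threshold tightens", {
  cr <- small_corruption()
  segs <- chunk_contigs(cr$assembly, 1000)
  idx <- build_index(cr$reference, k = 12)
  al <- suppressWarnings(align_pairwise(chunk_sequences(segs), idx,
        aligner_params(min_identity = 0.80, min_align_length = 50L)))
  totals <- vapply(c(0.98, 0.95, 0.90, 0.85), function(mi) {
    sum(find_unmapped_segments(segs, al, min_identity = mi)$length)
  }, numeric(1))
  # loosening the identity threshold can only mask more, never less
  expect_true(all(diff(totals) <= 0))
})
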