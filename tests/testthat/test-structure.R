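mk_aln <- function(qid, tid, qstart, qend, tstart, score = NULL,
                   strand = "+") {
  len <- qend - qstart
  if (is.null(score)) score <- len
  asmappraise:::new_pairwise_alignment(
    query_id = qid, target_id = tid, strand = strand,
    qstart = qstart, qend = qend, tstart = tstart, tend = tstart + len,
    qsize = qend, tsize = 10^9, blocks = cbind(as.integer(qstart),
                                               as.integer(tstart),
                                               as.integer(len)),
    matches = len, mismatches = 0L, query_gap_bases = 0L,
    target_gap_bases = 0L, score = score)
}

test_that("a contig uniquely split across two chromosomes is one event", {
  al <- as_alignment_list(
    mk_aln("ctg1", "chr1", 0, 12000, 100000),
    mk_aln("ctg1", "chr2", 12000, 23000, 500000))
  ev10 <- detect_split_contigs(al, size_cutoff = 10000)
  expect_length(ev10, 1L)
  expect_equal(ev10[[1]]$contig_id, "ctg1")
  expect_equal(ev10[[1]]$min_segment_length, 11000)
  expect_length(detect_split_contigs(al, size_cutoff = 25000), 0L)
})

test_that("non-unique placements do not trigger events", {
  al <- as_alignment_list(
    mk_aln("ctg1", "chr1", 0, 12000, 100000, score = 12000),
    mk_aln("ctg1", "chr3", 0, 12000, 700000, score = 11500),  # within 1.1x
    mk_aln("ctg1", "chr2", 12000, 23000, 500000))
  ev <- detect_split_contigs(al, size_cutoff = 10000)
  expect_length(ev, 0L)
})

test_that("event counts are monotone non-increasing in the size cutoff", {
  al <- small_alignments()
  counts <- vapply(c(5000, 10000, 25000, 50000), function(cc) {
    length(detect_split_contigs(al, size_cutoff = cc))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  # planted misjoins recovered exactly at the 10 kbp cutoff
  expect_equal(counts[2], nrow(small_corruption()$ledger$misjoins))
})

test_that("distant same-chromosome placements are intrachromosomal events only", {
  al <- as_alignment_list(
    mk_aln("ctg1", "chr1", 0, 12000, 100000),
    mk_aln("ctg1", "chr1", 12000, 24000, 5000000))
  expect_length(detect_split_contigs(al, 10000), 0L)
  ev <- detect_split_contigs(al, 10000, include_intrachromosomal = TRUE)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$type, "intrachromosomal")
})

test_that("normalization scales counts by C / L", {
  expect_equal(normalize_event_count(7, 1000, 1000), 7)
  expect_equal(normalize_event_count(10, 2000, 1000), 5)
  # linear in N, inverse in L
  expect_equal(normalize_event_count(20, 500, 250),
               2 * normalize_event_count(10, 500, 250))
  expect_equal(normalize_event_count(10, 1000, 250),
               normalize_event_count(10, 500, 250) / 2)
  # the assembly with the smallest mean scaffold length keeps its raw count
  expect_lt(normalize_event_count(9, 4000, 1500), 9)
})

test_that("classify_pair applies proper-pair geometry and label precedence", {
  e1 <- mk_aln("r1", "sc1", 0, 100, 1000, strand = "+")
  e2 <- mk_aln("r2", "sc1", 0, 100, 2900, strand = "-")
  expect_equal(classify_pair(e1, e2, insert_mean = 2000,
                             insert_tolerance = 0.3), "proper")
  e2s <- mk_aln("r2", "sc1", 0, 100, 2900, strand = "+")
  expect_equal(classify_pair(e1, e2s, 2000, 0.3), "discordant_orientation")
  expect_equal(classify_pair(e1, NULL, 2000, 0.3), "one_end_unmapped")
  expect_equal(classify_pair(NULL, NULL, 2000, 0.3), "both_unmapped")
  e2c <- mk_aln("r2", "sc2", 0, 100, 2900, strand = "-")
  expect_equal(classify_pair(e1, e2c, 2000, 0.3), "cross_scaffold")
  e2d <- mk_aln("r2", "sc1", 0, 100, 9000, strand = "-")
  expect_equal(classify_pair(e1, e2d, 2000, 0.3), "discordant_distance")
  # leftmost end must be on plus
  f1 <- mk_aln("r1", "sc1", 0, 100, 1000, strand = "-")
  f2 <- mk_aln("r2", "sc1", 0, 100, 2900, strand = "+")
  expect_equal(classify_pair(f1, f2, 2000, 0.3), "discordant_orientation")
})

test_that("concordance_summary counts labels and computes the proper fraction", {
  s <- concordance_summary(c("proper", "proper", "proper",
                             "discordant_orientation"))
  expect_equal(sum(s$counts), 4L)
  expect_equal(s$proper_fraction, 0.75)
  expect_equal(concordance_summary(rep("proper", 5))$proper_fraction, 1)
  expect_error(concordance_summary(character(0)), "no pairs")
  expect_error(concordance_summary("weird"), "unknown")
})

test_that("simulated pairs against a misjoin-free assembly are mostly proper", {
  g <- small_genome()
  cr <- fixture("clean_corruption", function() {
    corrupt_assembly(g, corruption_spec(
      target_contig_n50 = 15000L, target_scaffold_n50 = 80000L, seed = 103L))
  })
  p <- simulate_pairs(g, 1500, insert_mean = 2000, insert_sd = 100,
                      read_length = 100, seed = 103, corruption = cr)
  cls <- pair_concordance(p, cr$assembly, insert_mean = 2000)
  s <- concordance_summary(cls)
  truth_prop <- mean(p$info$truth_class == "proper")
  expect_gte(s$proper_fraction, truth_prop - 0.02)
  expect_gte(s$proper_fraction, 0.95)
})

test_that("pairs spanning a planted misjoin are never proper", {
  g <- small_genome()
  cr <- small_corruption()
  segs <- cr$ledger$contigs
  mj <- segs[segs$type == "misjoin", ]
  expect_gt(nrow(mj), 0)
  # synthesise reads flanking the junction of the first misjoin contig
  first <- mj[mj$contig_id == mj$contig_id[1], ]
  ctg <- as.character(cr$assembly$contig_seqs[[first$contig_id[1]]])
  junction <- first$segment_offset[2]
  r1 <- substr(ctg, junction - 900, junction - 801)
  r2 <- revcomp(substr(ctg, junction + 901, junction + 1000))
  pairs <- list(reads1 = Biostrings::DNAStringSet(c(`p/1` = r1)),
                reads2 = Biostrings::DNAStringSet(c(`p/2` = r2)))
  # map against the truth genome-derived scaffolds of a clean assembly:
  # the two flanks come from different chromosomes, so they cannot be a
  # proper pair on any scaffold built without the misjoin
  clean <- fixture("clean_corruption", function() {
    corrupt_assembly(g, corruption_spec(
      target_contig_n50 = 15000L, target_scaffold_n50 = 80000L, seed = 103L))
  })
  cls <- pair_concordance(pairs, clean$assembly, insert_mean = 2000)
  expect_false(cls == "proper")
})
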