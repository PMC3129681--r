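test_that("generation is deterministic given the spec", {
  s <- genome_spec(n_chromosomes = 1L, lengths = 60000L, seed = 9L)
  g1 <- generate_genome(s)
  g2 <- generate_genome(s)
  expect_identical(as.character(g1$chromosomes), as.character(g2$chromosomes))
  expect_identical(g1$genes, g2$genes)
  cspec <- corruption_spec(target_contig_n50 = 8000L,
                           target_scaffold_n50 = 20000L, seed = 9L)
  c1 <- corrupt_assembly(g1, cspec)
  c2 <- corrupt_assembly(g2, cspec)
  expect_identical(as.character(c1$assembly$scaffolds),
                   as.character(c2$assembly$scaffolds))
  expect_identical(c1$ledger$events, c2$ledger$events)
})

test_that("realized genome GC tracks the specification", {
  g <- generate_genome(genome_spec(n_chromosomes = 1L, lengths = 1000000L,
                                   gc = 0.416, seed = 12L))
  expect_lt(abs(gc_content(g$chromosomes) - 41.6), 0.5)
  g2 <- generate_genome(genome_spec(n_chromosomes = 1L, lengths = 300000L,
                                    gc = 0.60, seed = 13L))
  expect_lt(abs(gc_content(g2$chromosomes) - 60), 0.8)
})

test_that("with no repeats, no unit-length substring recurs excessively", {
  g <- generate_genome(genome_spec(n_chromosomes = 1L, lengths = 200000L,
                                   repeat_fraction = 0, seed = 14L))
  s <- as.character(g$chromosomes[[1]])
  # k-mer census at a short word length: random sequence only
  k <- 15
  set.seed(14)
  starts <- sample(0:(nchar(s) - k), 3000)
  words <- substring(s, starts + 1, starts + k)
  expect_lte(max(table(words)), 3)
})

test_that("planted event counts stay within binomial bounds of the rates", {
  g <- generate_genome(genome_spec(n_chromosomes = 2L, lengths = 500000L,
                                   seed = 15L))
  sp <- corruption_spec(sub_rate = 2e-4, ins_rate = 5e-5, del_rate = 1e-4,
                        homopolymer_del_bias = 1, seed = 15L)
  cr <- corrupt_assembly(g, sp)
  n <- cr$ledger$realized$genome_bases
  for (pair in list(c(cr$ledger$realized$n_substitutions, sp$sub_rate),
                    c(cr$ledger$realized$n_insertions, sp$ins_rate),
                    c(cr$ledger$realized$n_deletions, sp$del_rate))) {
    expected <- n * pair[2]
    expect_lt(abs(pair[1] - expected), 3 * sqrt(expected) + 1)
  }
})

test_that("homopolymer bias raises the deletion count", {
  g <- generate_genome(genome_spec(n_chromosomes = 1L, lengths = 500000L,
                                   seed = 16L))
  unbiased <- corrupt_assembly(g, corruption_spec(
    homopolymer_del_bias = 1, seed = 16L))$ledger$realized$n_deletions
  biased <- corrupt_assembly(g, corruption_spec(
    homopolymer_del_bias = 3, seed = 16L))$ledger$realized$n_deletions
  expect_gt(biased, unbiased)
})

test_that("ledger contigs tile each chromosome exactly", {
  cr <- small_corruption()
  g <- small_genome()
  segs <- cr$ledger$contigs
  segs <- segs[!is.na(segs$chrom), ]
  for (nm in names(g$chromosomes)) {
    on_chrom <- segs[segs$chrom == nm, ]
    on_chrom <- on_chrom[order(on_chrom$truth_start), ]
    expect_equal(on_chrom$truth_start[1], 0)
    expect_equal(utils::tail(on_chrom$truth_end, 1),
                 nchar(as.character(g$chromosomes[[nm]])))
    expect_equal(on_chrom$truth_start[-1],
                 utils::head(on_chrom$truth_end, -1))
  }
})

test_that("ledger events are locatable in the truth genome", {
  cr <- small_corruption()
  g <- small_genome()
  ev <- cr$ledger$events
  subs <- ev[ev$type == "substitution", ][1:20, ]
  for (i in seq_len(nrow(subs))) {
    truth_base <- substr(as.character(g$chromosomes[[subs$chrom[i]]]),
                         subs$truth_pos[i] + 1, subs$truth_pos[i] + 1)
    expect_false(truth_base == subs$base[i])  # replacement differs
  }
})

test_that("null corruption reproduces the genome exactly", {
  g <- generate_genome(genome_spec(n_chromosomes = 1L, lengths = 100000L,
                                   seed = 17L))
  cr <- corrupt_assembly(g, corruption_spec(
    sub_rate = 0, ins_rate = 0, del_rate = 0,
    target_contig_n50 = 20000L, target_scaffold_n50 = 50000L, seed = 17L))
  expect_equal(cr$ledger$realized$n_substitutions, 0)
  # contigs are verbatim substrings of the genome
  chrom <- as.character(g$chromosomes[[1]])
  segs <- cr$ledger$contigs
  for (i in seq_len(nrow(segs))) {
    expect_equal(as.character(cr$assembly$contig_seqs[[segs$contig_id[i]]]),
                 substr(chrom, segs$truth_start[i] + 1, segs$truth_end[i]))
  }
})

test_that("contaminant contigs come from the foreign genome", {
  cr <- small_corruption()
  foreign <- as.character(cr$foreign[[1]])
  for (i in seq_len(nrow(cr$ledger$contaminants))) {
    row <- cr$ledger$contaminants[i, ]
    ctg <- as.character(cr$assembly$contig_seqs[[row$contig_id]])
    expect_equal(ctg, substr(foreign, row$source_start + 1,
                             row$source_start + row$length))
  }
})

test_that("novel inserts sit inside their host contigs at the recorded position", {
  cr <- small_corruption()
  nv <- cr$ledger$novel
  for (i in seq_len(nrow(nv))) {
    ctg <- as.character(cr$assembly$contig_seqs[[nv$contig_id[i]]])
    expect_gte(nchar(ctg), nv$insert_pos[i] + nv$length[i])
  }
  expect_lt(abs(mean(nv$gc) - 54.2), 3)
})

test_that("simulate_pairs honours its contract", {
  g <- small_genome()
  empty <- simulate_pairs(g, 0)
  expect_length(empty$reads1, 0L)
  p <- simulate_pairs(g, 50, insert_mean = 2000, insert_sd = 0,
                      read_length = 100, seed = 21)
  expect_true(all(p$info$insert == 2000))
  # reads are genuine genome substrings in the expected orientation
  for (i in 1:10) {
    chrom <- as.character(g$chromosomes[[p$info$chrom[i]]])
    expect_equal(as.character(p$reads1[[i]]),
                 substr(chrom, p$info$start[i] + 1, p$info$start[i] + 100))
    expect_equal(as.character(p$reads2[[i]]),
                 revcomp(substr(chrom, p$info$start[i] + 2000 - 100 + 1,
                                p$info$start[i] + 2000)))
  }
  # determinism
  p2 <- simulate_pairs(g, 50, insert_mean = 2000, insert_sd = 0,
                       read_length = 100, seed = 21)
  expect_identical(p$info, p2$info)
})
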