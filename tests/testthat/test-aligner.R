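test_that("k-mer index stores every position and excludes N", {
  idx <- build_index(c(t = "ACGTACGT"), k = 8)
  hit <- index_lookup(idx, "ACGTACGT")
  expect_equal(hit$position, 0L)
  idx4 <- build_index(c(t = "ACGTACGTACGT"), k = 8)
  expect_equal(index_lookup(idx4, "ACGTACGT")$position, c(0L, 4L))
  idxn <- build_index(c(t = strrep("N", 100)), k = 12)
  expect_equal(cpp_info_nkmers <- asmappraise:::cpp_index_info(idxn$ptr)$n_kmers, 0)
})

test_that("every indexed position is verified by substring equality", {
  tgt <- random_dna(10000, seed = 5)
  k <- 12
  idx <- build_index(c(t = tgt), k = k)
  set.seed(6)
  for (p in sample(0:(10000 - k), 200)) {
    kmer <- substr(tgt, p + 1, p + k)
    hits <- index_lookup(idx, kmer)
    expect_true(p %in% hits$position)
    for (h in hits$position) {
      expect_equal(substr(tgt, h + 1, h + k), kmer)
    }
  }
})

test_that("exact substrings align full-length at identity 1 on either strand", {
  tgt <- random_dna(5000, seed = 8)
  idx <- build_index(c(t = tgt), k = 12)
  q <- substr(tgt, 1001, 1500)
  al <- align_pairwise(c(q = q), idx, aligner_params(min_align_length = 100))
  expect_length(al, 1L)
  expect_equal(al[[1]]$strand, "+")
  expect_equal(alignment_identity(al[[1]]), 1.0)
  expect_equal(c(al[[1]]$qstart, al[[1]]$qend), c(0L, 500L))
  expect_equal(c(al[[1]]$tstart, al[[1]]$tend), c(1000L, 1500L))

  alr <- align_pairwise(c(q = revcomp(q)), idx,
                        aligner_params(min_align_length = 100))
  expect_equal(alr[[1]]$strand, "-")
  expect_equal(alignment_identity(alr[[1]]), 1.0)
  expect_equal(c(alr[[1]]$tstart, alr[[1]]$tend), c(1000L, 1500L))
})

test_that("banded scores equal the unrestricted DP optimum on small pairs", {
  skip_if_not_installed("Biostrings")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (i in 1:120) {
    tlen <- sample(100:300, 1)
    tgt <- random_dna(tlen)
    qs <- sample(1:(tlen - 80), 1)
    q <- substr(tgt, qs, qs + sample(60:min(200, tlen - qs), 1))
    ch <- strsplit(q, "")[[1]]
    nm <- rbinom(1, nchar(q), 0.02)
    if (nm > 0) {
      p <- sample(nchar(q), nm)
      ch[p] <- sample(bases, nm, TRUE)
    }
    if (runif(1) < 0.5 && length(ch) > 40) {
      d <- sample(length(ch) - 5, 1)
      ch <- ch[-(d:(d + sample(0:2, 1)))]
    }
    q <- paste0(ch, collapse = "")
    idx <- build_index(c(t = tgt), k = 12)
    al <- suppressWarnings(align_pairwise(c(q = q), idx,
      aligner_params(band_width = 400L, min_identity = 0.5,
                     min_align_length = 20L)))
    if (length(al) == 0) next
    n_checked <- n_checked + 1
    oracle <- Biostrings::pairwiseAlignment(
      pattern = q, subject = tgt, type = "global-local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    expect_equal(max(vapply(al, `[[`, numeric(1), "score")),
                 Biostrings::score(oracle))
  }
  expect_gt(n_checked, 100)
})

test_that("strand symmetry: the reverse-complemented query mirrors the alignment", {
  tgt <- random_dna(4000, seed = 13)
  idx <- build_index(c(t = tgt), k = 12)
  q <- substr(tgt, 501, 1200)
  ch <- strsplit(q, "")[[1]]
  ch[c(100, 400)] <- c("A", "T")
  q <- paste0(ch, collapse = "")
  a1 <- align_pairwise(c(q = q), idx, aligner_params())[[1]]
  a2 <- align_pairwise(c(q = revcomp(q)), idx, aligner_params())[[1]]
  expect_equal(a1$strand, "+")
  expect_equal(a2$strand, "-")
  expect_equal(alignment_identity(a1), alignment_identity(a2))
  expect_equal(a1$score, a2$score)
  expect_equal(c(a1$tstart, a1$tend), c(a2$tstart, a2$tend))
})

test_that("self-alignment identity is exactly 1", {
  s <- random_dna(2000, seed = 17)
  idx <- build_index(c(s = s), k = 12)
  al <- align_pairwise(c(s = s), idx, aligner_params())
  expect_equal(alignment_identity(best_alignment(al)), 1.0)
  expect_equal(best_alignment(al)$matches, 2000)
})

test_that("queries shorter than k give an empty result with a warning", {
  idx <- build_index(c(t = random_dna(1000, seed = 19)), k = 12)
  expect_warning(al <- align_pairwise(c(q = "ACGTACG"), idx), "shorter")
  expect_length(al, 0L)
})

test_that("best_alignment applies the deterministic tie-break chain", {
  expect_null(best_alignment(as_alignment_list()))
  mk <- function(score, matches, tid, tstart) {
    asmappraise:::new_pairwise_alignment(
      query_id = "q", target_id = tid, strand = "+", qstart = 0, qend = 100,
      tstart = tstart, tend = tstart + 100, qsize = 100, tsize = 1000,
      blocks = cbind(0L, as.integer(tstart), 100L), matches = matches,
      mismatches = 100 - matches, query_gap_bases = 0, target_gap_bases = 0,
      score = score)
  }
  a <- mk(50, 95, "chr2", 10)
  b <- mk(40, 99, "chr1", 0)
  expect_equal(best_alignment(as_alignment_list(a, b))$score, 50)
  # equal scores: more matches wins
  c1 <- mk(50, 96, "chr3", 5)
  expect_equal(best_alignment(as_alignment_list(a, c1))$target_id, "chr3")
  # equal scores and matches: lexicographically smallest target id
  d1 <- mk(50, 95, "chr10", 30)
  expect_equal(best_alignment(as_alignment_list(a, d1))$target_id, "chr10")
  # then smallest target start
  e1 <- mk(50, 95, "chr2", 3)
  expect_equal(best_alignment(as_alignment_list(a, e1))$tstart, 3)
})

test_that("homopolymer gaps are left-shifted to canonical coordinates", {
  # target has AAAA run; deleting any one A is equivalent; the reported
  # deletion must sit at the leftmost position of the run
  left <- paste0(random_dna(300, gc = 0.5, seed = 23), "C")
  right <- paste0("G", random_dna(300, gc = 0.5, seed = 24))
  tgt <- paste0(left, "AAAAA", right)
  q <- paste0(left, "AAAA", right)  # one A fewer
  idx <- build_index(c(t = tgt), k = 12)
  al <- align_pairwise(c(q = q), idx, aligner_params())
  a <- best_alignment(al)
  expect_equal(a$query_gap_bases, 1L)
  expect_equal(a$detail$del_runs[1, 1], 301L)
})
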