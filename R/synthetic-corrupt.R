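#' Specification of planted assembly defects
#'
#' Per-base event rates are drawn independently at each base (one event
#' class per base at most); the deletion rate is multiplied by
#' `homopolymer_del_bias` inside homopolymer runs of 4 bp or more,
#' reproducing the deletion-heavy error signature of flowgram-based
#' sequencing. Fragmentation targets contig/scaffold N50s; misjoins
#' splice contigs from two chromosomes; contaminant contigs are drawn
#' from a synthetic foreign genome at shifted GC; novel inserts are
#' placed into assembly contigs only, so they are absent from the
#' emitted reference.
#'
#' @param sub_rate,ins_rate,del_rate Per-base event probabilities,
#'   each in `[0, 0.01]`.
#' @param homopolymer_del_bias Multiplier on `del_rate` inside
#'   homopolymers of >= 4 bp.
#' @param target_contig_n50,target_scaffold_n50 Fragmentation targets (bp).
#' @param n_misjoins Interchromosomal misjoin contigs to plant.
#' @param misjoin_flank Minimum length (bp) of each joined segment.
#' @param contaminant_fraction Contaminant contigs as a proportion of
#'   the contig count.
#' @param n_novel_inserts,novel_insert_length Count and length of novel
#'   sequence insertions.
#' @param novel_gc GC proportion of novel inserts.
#' @param foreign_gc GC proportion of the contaminant source genome.
#' @param gap_length N-gap length between contigs within a scaffold.
#' @param seed Integer seed.
#' @return A list of class `corruption_spec`.
#' @export
corruption_spec <- function(sub_rate = 2e-4, ins_rate = 5e-5, del_rate = 1e-4,
                            homopolymer_del_bias = 3,
                            target_contig_n50 = 20000L,
                            target_scaffold_n50 = 300000L,
                            n_misjoins = 0L, misjoin_flank = 20000L,
                            contaminant_fraction = 0,
                            n_novel_inserts = 0L, novel_insert_length = 1000L,
                            novel_gc = 0.542, foreign_gc = 0.30,
                            gap_length = 100L, seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.01, ins_rate >= 0, ins_rate <= 0.01,
            del_rate >= 0, del_rate <= 0.01, homopolymer_del_bias >= 1,
            n_misjoins >= 0L, contaminant_fraction >= 0,
            contaminant_fraction <= 0.5, gap_length >= 1L)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 homopolymer_del_bias = homopolymer_del_bias,
                 target_contig_n50 = as.integer(target_contig_n50),
                 target_scaffold_n50 = as.integer(target_scaffold_n50),
                 n_misjoins = as.integer(n_misjoins),
                 misjoin_flank = as.integer(misjoin_flank),
                 contaminant_fraction = contaminant_fraction,
                 n_novel_inserts = as.integer(n_novel_inserts),
                 novel_insert_length = as.integer(novel_insert_length),
                 novel_gc = novel_gc, foreign_gc = foreign_gc,
                 gap_length = as.integer(gap_length),
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

# draw fragment lengths whose N50 approaches target (adaptive exponential)
draw_fragments <- function(chrom_lengths, target_n50, min_piece = 500L,
                           max_iter = 25L) {
  m <- target_n50 / 1.678  # length-weighted median of Exp(m) pieces
  for (iter in seq_len(max_iter)) {
    pieces <- lapply(chrom_lengths, function(L) {
      if (L <= m * 1.5) return(L)
      lens <- integer(0)
      left <- L
      while (left > 0) {
        l <- max(min_piece, round(stats::rexp(1L, rate = 1 / m)))
        if (l >= left || left - l < min_piece) { lens <- c(lens, left); break }
        lens <- c(lens, l)
        left <- left - l
      }
      lens
    })
    realized <- n_statistic(unlist(pieces), 0.5)
    if (abs(realized - target_n50) <= 0.1 * target_n50) break
    m <- m * target_n50 / realized
  }
  pieces
}

#' Corrupt a truth genome into a synthetic assembly with a truth ledger
#'
#' Fragments each chromosome to the target contig N50, plants per-base
#' substitution/insertion/deletion events (with homopolymer deletion
#' bias), splices misjoin contigs from pairs of long contigs on
#' different chromosomes, adds contaminant contigs drawn from a
#' synthetic foreign genome, inserts novel sequence into assembly
#' contigs, and groups contigs into N-gapped scaffolds at the target
#' scaffold N50. Every planted defect is recorded in the returned
#' ledger.
#'
#' @param genome A `truth_genome` from [generate_genome()].
#' @param spec A [corruption_spec()].
#' @return A list of class `corrupted_assembly`: `assembly`
#'   (`asm_assembly`), `ledger` (`truth_ledger`), `reference` (the truth
#'   chromosomes; novel inserts are absent from it by construction) and
#'   `foreign` (the contaminant source, the screening database).
#' @export
corrupt_assembly <- function(genome, spec = corruption_spec()) {
  stopifnot(inherits(genome, "truth_genome"), inherits(spec, "corruption_spec"))
  chroms <- as_dna_character(genome$chromosomes)
  chrom_lengths <- nchar(chroms)
  if (spec$target_contig_n50 > max(chrom_lengths)) {
    stop("target_contig_n50 exceeds the longest chromosome")
  }
  with_seed(spec$seed, {
    ## 1. fragmentation in truth coordinates
    pieces <- draw_fragments(chrom_lengths, spec$target_contig_n50)
    ctg <- list()
    for (ci in seq_along(chroms)) {
      ends <- cumsum(pieces[[ci]])
      starts <- c(0L, utils::head(ends, -1L))
      ctg[[ci]] <- data.frame(chrom = names(chroms)[ci], truth_start = starts,
                              truth_end = as.integer(ends),
                              stringsAsFactors = FALSE)
    }
    contigs <- do.call(rbind, ctg)
    contigs$type <- "normal"

    ## 2. select misjoin donors: long contigs, mostly non-repetitive
    misjoin_rows <- NULL
    if (spec$n_misjoins > 0L) {
      long_enough <- which(contigs$truth_end - contigs$truth_start >=
                             spec$misjoin_flank)
      rep_frac <- vapply(long_enough, function(i) {
        r <- genome$repeats[genome$repeats$chrom == contigs$chrom[i], ,
                            drop = FALSE]
        if (nrow(r) == 0L) return(0)
        ov <- pmin(r$end, contigs$truth_end[i]) -
          pmax(r$start, contigs$truth_start[i])
        sum(pmax(ov, 0)) / (contigs$truth_end[i] - contigs$truth_start[i])
      }, numeric(1))
      pool <- long_enough[rep_frac < 0.2]
      needed <- 2L * spec$n_misjoins
      if (length(pool) < needed) {
        stop("not enough long unique contigs for the requested misjoins")
      }
      # pair contigs from different chromosomes
      pool <- sample(pool)
      donors <- integer(0)
      i <- 1L
      while (length(donors) < needed && i <= length(pool)) {
        cand <- pool[i]
        if (length(donors) %% 2L == 1L &&
            contigs$chrom[cand] == contigs$chrom[donors[length(donors)]]) {
          i <- i + 1L
          next
        }
        donors <- c(donors, cand)
        pool <- setdiff(pool, cand)
        i <- 1L
      }
      if (length(donors) < needed) stop("could not pair misjoin donors")
      contigs$type[donors] <- rep(sprintf("misjoin%03d", seq_len(spec$n_misjoins)),
                                  each = 2L)
      misjoin_rows <- matrix(donors, ncol = 2L, byrow = TRUE)
    }

    ## 3. per-contig corruption
    n_ctg <- nrow(contigs)
    seqs <- character(n_ctg)
    events <- vector("list", n_ctg)
    n_sub <- 0; n_ins <- 0; n_del <- 0
    for (i in seq_len(n_ctg)) {
      s <- substr(chroms[[contigs$chrom[i]]], contigs$truth_start[i] + 1L,
                  contigs$truth_end[i])
      len <- nchar(s)
      hp <- cpp_homopolymer_mask(s, 4L)
      p_del <- spec$del_rate * ifelse(hp, spec$homopolymer_del_bias, 1)
      u <- stats::runif(len)
      t1 <- spec$sub_rate
      t2 <- t1 + spec$ins_rate
      t3 <- t2 + p_del
      hitpos <- which(u < t3)
      if (length(hitpos) > 0L) {
        type <- ifelse(u[hitpos] < t1, 0L, ifelse(u[hitpos] < t2, 1L, 2L))
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        base <- character(length(hitpos))
        is_sub <- type == 0L
        base[is_sub] <- substitute_bases(ch[hitpos[is_sub]])
        is_ins <- type == 1L
        base[is_ins] <- sample(c("A", "C", "G", "T"), sum(is_ins),
                               replace = TRUE)
        seqs[i] <- cpp_apply_mutations(s, hitpos - 1L, type, base)
        events[[i]] <- data.frame(
          type = c("substitution", "insertion", "deletion")[type + 1L],
          chrom = contigs$chrom[i],
          truth_pos = contigs$truth_start[i] + hitpos - 1L,
          contig_index = i, base = base, stringsAsFactors = FALSE)
        n_sub <- n_sub + sum(is_sub)
        n_ins <- n_ins + sum(is_ins)
        n_del <- n_del + sum(type == 2L)
      } else {
        seqs[i] <- s
      }
    }
    events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
    if (is.null(events)) {
      events <- data.frame(type = character(), chrom = character(),
                           truth_pos = integer(), contig_index = integer(),
                           base = character(), stringsAsFactors = FALSE)
    }
    genome_bases <- sum(as.numeric(contigs$truth_end - contigs$truth_start))

    ## 4. novel inserts into normal contigs
    novel <- data.frame(novel_id = character(), contig_index = integer(),
                        insert_pos = integer(), length = integer(),
                        gc = numeric(), stringsAsFactors = FALSE)
    novel_seqs <- character(0)
    if (spec$n_novel_inserts > 0L) {
      host_pool <- which(contigs$type == "normal" &
                           nchar(seqs) >= 3L * spec$novel_insert_length)
      if (length(host_pool) < spec$n_novel_inserts) {
        stop("not enough contigs to host the requested novel inserts")
      }
      hosts <- sample(host_pool, spec$n_novel_inserts)
      for (j in seq_along(hosts)) {
        i <- hosts[j]
        len <- nchar(seqs[i])
        pos <- sample(seq(round(0.2 * len), round(0.8 * len)), 1L)
        nseq <- random_seq(spec$novel_insert_length, spec$novel_gc)
        seqs[i] <- paste0(substr(seqs[i], 1L, pos), nseq,
                          substr(seqs[i], pos + 1L, len))
        novel_seqs <- c(novel_seqs, nseq)
        novel <- rbind(novel, data.frame(
          novel_id = sprintf("novel%03d", j), contig_index = i,
          insert_pos = pos, length = spec$novel_insert_length,
          gc = gc_content(nseq), stringsAsFactors = FALSE))
      }
    }

    ## 5. contaminant contigs from a synthetic foreign genome
    n_contam <- round(spec$contaminant_fraction * n_ctg)
    foreign_len <- max(200000L, 50L * 5000L)
    foreign <- random_seq(foreign_len, spec$foreign_gc)
    contam <- data.frame(contam_id = character(), length = integer(),
                         source_start = integer(), stringsAsFactors = FALSE)
    contam_seqs <- character(0)
    if (n_contam > 0L) {
      lens <- sample(1000:5000, n_contam, replace = TRUE)
      starts <- vapply(lens, function(l) sample.int(foreign_len - l, 1L),
                       integer(1))
      contam_seqs <- substring(foreign, starts + 1L, starts + lens)
      contam <- data.frame(contam_id = sprintf("contam%03d", seq_len(n_contam)),
                           length = lens, source_start = starts,
                           stringsAsFactors = FALSE)
    }

    ## 6. assemble final contig set (misjoins joined, labels assigned)
    final_seqs <- list()
    final_info <- list()  # one row per genome segment within a final contig
    add_final <- function(seq, segments) {
      final_seqs[[length(final_seqs) + 1L]] <<- seq
      segments$final_index <- length(final_seqs)
      final_info[[length(final_info) + 1L]] <<- segments
    }
    for (i in which(contigs$type == "normal")) {
      add_final(seqs[i], data.frame(
        chrom = contigs$chrom[i], truth_start = contigs$truth_start[i],
        truth_end = contigs$truth_end[i], segment_offset = 0L,
        type = "normal", stringsAsFactors = FALSE))
    }
    misjoin_list <- list()
    if (!is.null(misjoin_rows)) {
      for (mi in seq_len(nrow(misjoin_rows))) {
        a <- misjoin_rows[mi, 1L]; b <- misjoin_rows[mi, 2L]
        joined <- paste0(seqs[a], seqs[b])
        add_final(joined, data.frame(
          chrom = c(contigs$chrom[a], contigs$chrom[b]),
          truth_start = c(contigs$truth_start[a], contigs$truth_start[b]),
          truth_end = c(contigs$truth_end[a], contigs$truth_end[b]),
          segment_offset = c(0L, nchar(seqs[a])),
          type = "misjoin", stringsAsFactors = FALSE))
        misjoin_list[[mi]] <- data.frame(
          contig_id = NA_character_, chrom_a = contigs$chrom[a],
          a_start = contigs$truth_start[a], a_end = contigs$truth_end[a],
          chrom_b = contigs$chrom[b], b_start = contigs$truth_start[b],
          b_end = contigs$truth_end[b], final_index = length(final_seqs),
          stringsAsFactors = FALSE)
      }
    }
    misjoins <- if (length(misjoin_list) > 0L) do.call(rbind, misjoin_list) else
      data.frame(contig_id = character(), chrom_a = character(),
                 a_start = integer(), a_end = integer(),
                 chrom_b = character(), b_start = integer(),
                 b_end = integer(), final_index = integer(),
                 stringsAsFactors = FALSE)
    if (n_contam > 0L) {
      for (j in seq_len(n_contam)) {
        add_final(contam_seqs[j], data.frame(
          chrom = NA_character_, truth_start = NA_integer_,
          truth_end = NA_integer_, segment_offset = 0L,
          type = "contaminant", stringsAsFactors = FALSE))
      }
      contam$final_index <- length(final_seqs) - n_contam + seq_len(n_contam)
    }

    ## 7. scaffolding: group normal contigs per chromosome in order
    info <- do.call(rbind, final_info)
    normal_idx <- unique(info$final_index[info$type == "normal"])
    # genomic order within chromosome
    key <- info[match(normal_idx, info$final_index), ]
    normal_idx <- normal_idx[order(key$chrom, key$truth_start)]
    key <- key[order(key$chrom, key$truth_start), ]
    scaffold_of <- integer(length(final_seqs))
    ms <- spec$target_scaffold_n50 / 1.678
    flen <- vapply(final_seqs, nchar, integer(1))
    for (iter in 1:25) {
      sid <- 1L
      assign_try <- integer(length(normal_idx))
      acc <- 0
      target <- max(flen[normal_idx[1L]], round(stats::rexp(1L, 1 / ms)))
      for (r in seq_along(normal_idx)) {
        new_chrom <- r > 1L && key$chrom[r] != key$chrom[r - 1L]
        if (new_chrom || (acc > 0 && acc >= target)) {
          sid <- sid + 1L
          acc <- 0
          target <- round(stats::rexp(1L, 1 / ms))
        }
        assign_try[r] <- sid
        acc <- acc + flen[normal_idx[r]] + spec$gap_length
      }
      sc_lens <- tapply(flen[normal_idx] + spec$gap_length, assign_try, sum)
      realized <- n_statistic(as.integer(sc_lens), 0.5)
      if (abs(realized - spec$target_scaffold_n50) <=
            0.1 * spec$target_scaffold_n50) break
      ms <- ms * spec$target_scaffold_n50 / max(realized, 1)
    }
    scaffold_of[normal_idx] <- assign_try
    next_sid <- max(assign_try) + 1L
    for (i in seq_along(final_seqs)) {
      if (scaffold_of[i] == 0L) { scaffold_of[i] <- next_sid; next_sid <- next_sid + 1L }
    }

    scaffold_names <- sprintf("scaffold%04d", scaffold_of)
    scaf_seqs <- character(0)
    offsets <- integer(length(final_seqs))
    for (sid in unique(scaffold_of)) {
      members <- which(scaffold_of == sid)
      # keep genomic order for normal members
      members <- members[order(match(members, normal_idx))]
      off <- 0L
      parts <- character(0)
      for (m in members) {
        offsets[m] <- off
        parts <- c(parts, final_seqs[[m]])
        off <- off + nchar(final_seqs[[m]]) + spec$gap_length
      }
      scaf_seqs[sprintf("scaffold%04d", sid)] <-
        paste0(parts, collapse = strrep("N", spec$gap_length))
    }

    ## 8. decompose and translate construction ids to contig ids
    assembly <- decompose_scaffolds(scaf_seqs, gap_threshold = 10L)
    contig_id_of <- sprintf("%s:%d-%d", scaffold_names, offsets,
                            offsets + vapply(final_seqs, nchar, integer(1)))
    info$contig_id <- contig_id_of[info$final_index]
    info$scaffold_id <- scaffold_names[info$final_index]
    info$scaffold_offset <- offsets[info$final_index]
    # map construction contig index -> final contig id
    constr_to_final <- integer(n_ctg)
    for (i in seq_len(n_ctg)) {
      row <- which(info$chrom == contigs$chrom[i] &
                     info$truth_start == contigs$truth_start[i] &
                     !is.na(info$chrom))
      constr_to_final[i] <- if (length(row) > 0L) info$final_index[row[1L]] else NA_integer_
    }
    events$contig_id <- contig_id_of[constr_to_final[events$contig_index]]
    if (nrow(misjoins) > 0L) misjoins$contig_id <- contig_id_of[misjoins$final_index]
    if (nrow(novel) > 0L) {
      novel$contig_id <- contig_id_of[constr_to_final[novel$contig_index]]
    }
    if (n_contam > 0L) contam$contig_id <- contig_id_of[contam$final_index]

    ledger <- structure(list(
      contigs = info[, c("contig_id", "scaffold_id", "scaffold_offset",
                         "segment_offset", "chrom", "truth_start",
                         "truth_end", "type")],
      events = events[, c("type", "chrom", "truth_pos", "contig_id", "base")],
      realized = list(
        genome_bases = genome_bases,
        n_substitutions = n_sub, n_insertions = n_ins, n_deletions = n_del,
        sub_rate = n_sub / genome_bases, ins_rate = n_ins / genome_bases,
        del_rate = n_del / genome_bases),
      misjoins = misjoins[, c("contig_id", "chrom_a", "a_start", "a_end",
                              "chrom_b", "b_start", "b_end")],
      contaminants = if (n_contam > 0L)
        contam[, c("contig_id", "length", "source_start")] else
        data.frame(contig_id = character(), length = integer(),
                   source_start = integer(), stringsAsFactors = FALSE),
      novel = if (nrow(novel) > 0L)
        novel[, c("novel_id", "contig_id", "insert_pos", "length", "gc")] else
        data.frame(novel_id = character(), contig_id = character(),
                   insert_pos = integer(), length = integer(), gc = numeric(),
                   stringsAsFactors = FALSE),
      spec = spec), class = "truth_ledger")

    structure(list(assembly = assembly, ledger = ledger,
                   reference = genome$chromosomes,
                   foreign = Biostrings::DNAStringSet(c(foreign_genome = foreign))),
              class = "corrupted_assembly")
  })
}

#' @export
print.corrupted_assembly <- function(x, ...) {
  l <- x$ledger
  cat("corrupted_assembly\n")
  print(x$assembly)
  cat(sprintf(
    "  planted: %d sub, %d ins, %d del; %d misjoin(s), %d contaminant(s), %d novel insert(s)\n",
    l$realized$n_substitutions, l$realized$n_insertions,
    l$realized$n_deletions, nrow(l$misjoins), nrow(l$contaminants),
    nrow(l$novel)))
  invisible(x)
}

#' Simulate paired-end reads from a truth genome
#'
#' Pairs are drawn uniformly over the genome (weighted by chromosome
#' length); read 1 is the leftmost end on the plus strand, read 2 the
#' reverse complement of the rightmost end, with outer distance drawn
#' from `Normal(insert_mean, insert_sd)`. When a `corrupted_assembly`
#' is supplied, each pair is assigned its truth class relative to that
#' assembly's planted fragmentation and misjoins.
#'
#' @param genome A `truth_genome`.
#' @param n_pairs Number of pairs.
#' @param insert_mean,insert_sd Outer insert size distribution (bp).
#' @param read_length Read length (bp); `insert_mean` must exceed twice
#'   this.
#' @param seed Integer seed.
#' @param corruption Optional `corrupted_assembly` for truth classes.
#' @param insert_tolerance Tolerance used for the truth proper class.
#' @return A list of class `simulated_pairs`: `reads1`, `reads2`
#'   (DNAStringSets) and `info` (data.frame with positions and, if
#'   available, `truth_class`).
#' @export
simulate_pairs <- function(genome, n_pairs, insert_mean = 2000L,
                           insert_sd = 0L, read_length = 100L, seed = 1L,
                           corruption = NULL, insert_tolerance = 0.3) {
  stopifnot(inherits(genome, "truth_genome"), insert_mean > 2 * read_length)
  chroms <- as_dna_character(genome$chromosomes)
  if (n_pairs == 0L) {
    return(structure(list(reads1 = Biostrings::DNAStringSet(),
                          reads2 = Biostrings::DNAStringSet(),
                          info = data.frame()), class = "simulated_pairs"))
  }
  with_seed(seed, {
    lens <- nchar(chroms)
    ci <- sample.int(length(chroms), n_pairs, replace = TRUE, prob = lens)
    ins <- pmax(2L * read_length,
                as.integer(round(stats::rnorm(n_pairs, insert_mean, insert_sd))))
    start <- vapply(seq_len(n_pairs), function(i) {
      sample.int(lens[ci[i]] - ins[i] + 1L, 1L) - 1L
    }, integer(1))
    r1 <- substring(chroms[ci], start + 1L, start + read_length)
    r2_fwd <- substring(chroms[ci], start + ins - read_length + 1L, start + ins)
    r2 <- vapply(r2_fwd, cpp_revcomp, character(1), USE.NAMES = FALSE)
    ids <- sprintf("pair%06d", seq_len(n_pairs))
    info <- data.frame(pair_id = ids, chrom = names(chroms)[ci],
                       start = start, insert = ins, stringsAsFactors = FALSE)
    if (!is.null(corruption)) {
      info$truth_class <- pair_truth_class(info, read_length, corruption,
                                           insert_mean, insert_tolerance)
    }
    structure(list(
      reads1 = Biostrings::DNAStringSet(stats::setNames(r1, paste0(ids, "/1"))),
      reads2 = Biostrings::DNAStringSet(stats::setNames(r2, paste0(ids, "/2"))),
      info = info), class = "simulated_pairs")
  })
}

# truth class of each simulated pair relative to planted breaks
pair_truth_class <- function(info, read_length, corruption, insert_mean,
                             insert_tolerance) {
  segs <- corruption$ledger$contigs
  segs <- segs[!is.na(segs$chrom), , drop = FALSE]
  locate <- function(chrom, s, e) {
    # segment fully containing [s, e) -> scaffold id + scaffold position of s
    hit <- which(segs$chrom == chrom & segs$truth_start <= s &
                   segs$truth_end >= e)
    if (length(hit) == 0L) return(NULL)
    h <- hit[1L]
    list(scaffold = segs$scaffold_id[h],
         pos = segs$scaffold_offset[h] + segs$segment_offset[h] +
           (s - segs$truth_start[h]))
  }
  vapply(seq_len(nrow(info)), function(i) {
    s <- info$start[i]
    e2 <- s + info$insert[i]
    a <- locate(info$chrom[i], s, s + read_length)
    b <- locate(info$chrom[i], e2 - read_length, e2)
    if (is.null(a) && is.null(b)) return("both_unmapped")
    if (is.null(a) || is.null(b)) return("one_end_unmapped")
    if (a$scaffold != b$scaffold) return("cross_scaffold")
    outer <- (b$pos + read_length) - a$pos
    lo <- insert_mean * (1 - insert_tolerance)
    hi <- insert_mean * (1 + insert_tolerance)
    if (outer < lo || outer > hi) return("discordant_distance")
    "proper"
  }, character(1))
}

#' Map simulated pairs to an assembly and classify concordance
#'
#' Aligns both reads of every pair against the assembly scaffolds with
#' the built-in aligner, takes the best alignment per read, and applies
#' [classify_pair()].
#'
#' @param pairs A `simulated_pairs` object (or list with `reads1`,
#'   `reads2` DNAStringSets in pair order).
#' @param assembly An `asm_assembly`.
#' @param insert_mean,insert_tolerance Proper-pair insert window.
#' @param params Aligner parameters; defaults to short-read settings.
#' @return Character vector of pair classes, in input order.
#' @export
pair_concordance <- function(pairs, assembly, insert_mean = 2000L,
                             insert_tolerance = 0.3, params = NULL) {
  stopifnot(inherits(assembly, "asm_assembly"))
  if (is.null(params)) {
    params <- aligner_params(min_identity = 0.9, min_align_length = 30L)
  }
  idx <- build_index(assembly$scaffolds, k = params$k)
  n <- length(pairs$reads1)
  a1 <- suppressWarnings(align_pairwise(pairs$reads1, idx, params))
  a2 <- suppressWarnings(align_pairwise(pairs$reads2, idx, params))
  best_by_query <- function(alns, ids) {
    out <- stats::setNames(vector("list", length(ids)), ids)
    if (length(alns) == 0L) return(out)
    qids <- vapply(alns, `[[`, character(1), "query_id")
    for (qid in intersect(unique(qids), ids)) {
      out[[qid]] <- best_alignment(alns[qids == qid])
    }
    out
  }
  b1 <- best_by_query(a1, names(pairs$reads1))
  b2 <- best_by_query(a2, names(pairs$reads2))
  vapply(seq_len(n), function(i) {
    classify_pair(b1[[i]], b2[[i]], insert_mean, insert_tolerance)
  }, character(1))
}
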