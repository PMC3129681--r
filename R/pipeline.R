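#' Build an evaluation configuration
#'
#' Collects the inputs and thresholds for a full appraisal run. Every
#' threshold default is the conventional value used throughout the
#' package: contigs > 100 bp for contiguity, 95% identity for
#' reference alignment, 90% identity / runs > 50 bp for novelty, 98%
#' identity over 200 bp for contamination screening, > 95% identity
#' over >= 100 bp for transcript coverage, 90% identity at 90/50/20%
#' length cutoffs for cDNA completeness, and 10/25/50 kbp mis-assembly
#' size cutoffs.
#'
#' @param assemblies Named list: each element a FASTA path or an
#'   `asm_assembly`.
#' @param reference Chromosome-labelled reference FASTA path or
#'   sequences (for mis-assembly and novelty stages).
#' @param trusted Trusted ("finished") sequence FASTA path or sequences
#'   (for the accuracy stage).
#' @param transcripts,cdnas Optional transcript / cDNA FASTA paths or
#'   sequences.
#' @param contaminants Optional contaminant database.
#' @param gap_threshold,min_contig_length,misassembly_cutoffs,chunk_size
#'   Structural thresholds.
#' @param accuracy_min_identity,reference_min_identity,novel_min_identity
#'   Identity thresholds for the accuracy, mis-assembly, and novelty
#'   alignments.
#' @param min_novel_length,contaminant_min_identity,contaminant_min_length
#'   Novelty thresholds.
#' @param transcript_min_identity,transcript_min_length,cdna_min_identity,cdna_length_cutoffs
#'   Gene-representation thresholds.
#' @param insert_mean,insert_tolerance Proper-pair window (pair stage).
#' @param aligner Base [aligner_params()] used by all stages (identity
#'   and length thresholds are overridden per stage).
#' @param outdir Optional output directory for report and PSL artifacts.
#' @param seed Recorded in the provenance block (the evaluation itself
#'   is deterministic).
#' @return A list of class `evaluation_config`.
#' @export
evaluation_config <- function(assemblies, reference = NULL, trusted = NULL,
                              transcripts = NULL, cdnas = NULL,
                              contaminants = NULL,
                              gap_threshold = 10L, min_contig_length = 100L,
                              misassembly_cutoffs = c(10000L, 25000L, 50000L),
                              chunk_size = 1000L,
                              accuracy_min_identity = 0.90,
                              reference_min_identity = 0.95,
                              novel_min_identity = 0.90,
                              min_novel_length = 50L,
                              contaminant_min_identity = 0.98,
                              contaminant_min_length = 200L,
                              transcript_min_identity = 0.95,
                              transcript_min_length = 100L,
                              cdna_min_identity = 0.90,
                              cdna_length_cutoffs = c(0.9, 0.5, 0.2),
                              insert_mean = 2000L, insert_tolerance = 0.3,
                              aligner = aligner_params(),
                              outdir = NULL, seed = 1L) {
  if (!is.list(assemblies) || is.null(names(assemblies)) ||
        any(names(assemblies) == "")) {
    stop("assemblies must be a named list")
  }
  structure(as.list(environment()), class = "evaluation_config")
}

#' Read an evaluation configuration from YAML
#'
#' @param path YAML file whose keys mirror [evaluation_config()]
#'   arguments; `assemblies` must be a named mapping of FASTA paths.
#' @return An `evaluation_config`.
#' @export
read_evaluation_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(evaluation_config)))]
  do.call(evaluation_config, args)
}

load_sequences <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_fasta(x, quiet = TRUE))
  }
  Biostrings::DNAStringSet(as_dna_character(x))
}

#' Run the full appraisal pipeline
#'
#' Executes contiguity, accuracy, mis-assembly, novelty and gene
#' representation stages for each configured assembly, in that order,
#' and returns a combined machine-readable report. When `outdir` is
#' set, `report.json`, `report.tsv` and per-stage PSL files are
#' written. The run is deterministic for a fixed configuration and
#' inputs.
#'
#' @param config An [evaluation_config()].
#' @return A list of class `appraisal_report`.
#' @export
run_evaluation <- function(config) {
  stopifnot(inherits(config, "evaluation_config"))
  reference <- load_sequences(config$reference)
  trusted <- load_sequences(config$trusted)
  transcripts <- load_sequences(config$transcripts)
  cdnas <- load_sequences(config$cdnas)
  contaminants <- load_sequences(config$contaminants)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  ref_index <- if (!is.null(reference))
    build_index(reference, k = config$aligner$k) else NULL

  per_assembly <- list()
  errors <- list()
  novel_sets <- list()
  for (nm in names(config$assemblies)) {
    res <- tryCatch({
      a <- config$assemblies[[nm]]
      assembly <- if (inherits(a, "asm_assembly")) a else
        decompose_scaffolds(load_sequences(a), config$gap_threshold)
      out <- list()
      out$contiguity <- unclass(assembly_stats(assembly,
                                               config$min_contig_length))
      out$contiguity$nx_contig <- as.list(out$contiguity$nx_contig)
      out$contiguity$nx_scaffold <- as.list(out$contiguity$nx_scaffold)

      if (!is.null(trusted)) {
        tr_index <- build_index(trusted, k = config$aligner$k)
        pr <- config$aligner
        pr$min_identity <- config$accuracy_min_identity
        alns <- suppressWarnings(
          align_pairwise(assembly$contig_seqs, tr_index, pr))
        persist_psl(alns, outdir, nm, "accuracy")
        tally <- tally_discrepancies(alns, trusted)
        out$accuracy <- c(unclass(tally),
                          as.list(discrepancy_rates(tally)),
                          list(bac_coverage_percent = reference_coverage(tally)))
      }

      ref_alns <- NULL
      if (!is.null(ref_index)) {
        pr <- config$aligner
        pr$min_identity <- config$reference_min_identity
        ref_alns <- suppressWarnings(
          align_pairwise(assembly$contig_seqs, ref_index, pr))
        persist_psl(ref_alns, outdir, nm, "reference")
        raw <- vapply(config$misassembly_cutoffs, function(cc) {
          length(detect_split_contigs(ref_alns, size_cutoff = cc))
        }, integer(1))
        out$misassembly <- list(
          cutoffs = as.integer(config$misassembly_cutoffs),
          raw_counts = raw,
          mean_scaffold_length = out$contiguity$mean_scaffold_length)
      }

      if (!is.null(ref_index)) {
        segments <- chunk_contigs(assembly, config$chunk_size)
        pr <- config$aligner
        pr$min_identity <- config$novel_min_identity
        seg_alns <- suppressWarnings(
          align_pairwise(chunk_sequences(segments), ref_index, pr))
        novel <- find_unmapped_segments(segments, seg_alns,
                                        config$novel_min_identity,
                                        config$min_novel_length)
        contaminant_bases <- 0
        if (!is.null(contaminants) && nrow(novel) > 0L) {
          novel <- screen_contamination(novel, contaminants,
                                        config$contaminant_min_identity,
                                        config$contaminant_min_length)
          contaminant_bases <- sum(novel$length[novel$status == "contaminant"])
        }
        keep <- novel$status == "putative_novel"
        out$novelty <- list(
          novel_bases = sum(novel$length[keep]),
          n_novel_segments = sum(keep),
          contaminant_bases = contaminant_bases,
          contaminant_fraction =
            if (nrow(novel) > 0L) contaminant_bases / sum(novel$length) else 0,
          novel_gc_percent = if (any(keep))
            gc_content(novel_sequences(novel)[novel$novel_id[keep]]) else NA)
        novel_sets[[nm]] <- novel
      }

      if (!is.null(transcripts)) {
        segments <- chunk_contigs(assembly, config$chunk_size)
        tx_index <- build_index(transcripts, k = config$aligner$k)
        pr <- config$aligner
        pr$min_identity <- config$transcript_min_identity
        pr$min_align_length <- as.integer(config$transcript_min_length)
        tx_alns <- suppressWarnings(
          align_pairwise(chunk_sequences(segments), tx_index, pr))
        persist_psl(tx_alns, outdir, nm, "transcripts")
        tc <- transcript_base_coverage(tx_alns, transcripts,
                                       config$transcript_min_identity,
                                       config$transcript_min_length)
        out$genes <- list(gene_coverage_percent = tc$pooled_percent)
      }
      if (!is.null(cdnas)) {
        sc_index <- build_index(assembly$scaffolds, k = config$aligner$k)
        pr <- config$aligner
        pr$min_identity <- config$cdna_min_identity
        cd_alns <- suppressWarnings(align_pairwise(cdnas, sc_index, pr))
        curve <- cdna_completeness(cd_alns, cdnas, config$cdna_min_identity,
                                   config$cdna_length_cutoffs)
        out$genes$cdna_completeness <- as.data.frame(curve)
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
    } else {
      per_assembly[[nm]] <- res
    }
  }

  # normalized mis-assembly counts share one scale constant
  mls <- vapply(per_assembly, function(x)
    x$contiguity$mean_scaffold_length, numeric(1))
  scale_constant <- if (length(mls) > 0) min(mls) else NA_real_
  for (nm in names(per_assembly)) {
    ma <- per_assembly[[nm]]$misassembly
    if (!is.null(ma)) {
      per_assembly[[nm]]$misassembly$scale_constant <- scale_constant
      per_assembly[[nm]]$misassembly$normalized_counts <-
        normalize_event_count(ma$raw_counts, ma$mean_scaffold_length,
                              scale_constant)
    }
  }
  shared <- NULL
  if (length(novel_sets) >= 2L) {
    nms <- names(novel_sets)
    shared <- list()
    for (i in seq_len(length(nms) - 1L)) {
      for (j in seq(i + 1L, length(nms))) {
        key <- paste(nms[i], nms[j], sep = "|")
        shared[[key]] <- shared_novel(novel_sets[[nms[i]]],
                                      novel_sets[[nms[j]]],
                                      config$novel_min_identity)
      }
    }
  }

  report <- structure(list(
    assemblies = per_assembly,
    shared_novel = shared,
    errors = errors,
    provenance = list(
      package = "asmappraise",
      version = as.character(utils::packageVersion("asmappraise")),
      seed = config$seed,
      config_hash = config_hash(config),
      timestamp = NA)), class = "appraisal_report")
  if (!is.null(outdir)) write_report(report, outdir)
  if (length(errors) > 0L) {
    warning("stage failures for: ", paste(names(errors), collapse = ", "))
  }
  report
}

persist_psl <- function(alns, outdir, assembly_name, stage) {
  if (is.null(outdir)) return(invisible(NULL))
  write_psl(alns, file.path(outdir, sprintf("%s_%s.psl", assembly_name, stage)))
}

config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  x$assemblies <- lapply(x$assemblies, function(a) {
    if (is.character(a)) a else "in-memory"
  })
  # stable content digest without external dependencies
  sum(utf8ToInt(paste(utils::capture.output(utils::str(x)), collapse = "")))
}

#' Write an appraisal report to disk
#'
#' @param report An `appraisal_report`.
#' @param outdir Output directory; `report.json` and `report.tsv` are
#'   created.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  rows <- list()
  for (nm in names(report$assemblies)) {
    a <- report$assemblies[[nm]]
    add <- function(metric, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        assembly = nm, metric = metric, value = value,
        stringsAsFactors = FALSE)
    }
    ct <- a$contiguity
    add("n50_contig", ct$n50_contig)
    add("n50_scaffold", ct$n50_scaffold)
    add("total_contig_bases", ct$total_contig_bases)
    add("mean_scaffold_length", ct$mean_scaffold_length)
    if (!is.null(a$accuracy)) {
      add("substitution_rate_percent", a$accuracy$substitution_rate)
      add("deletion_rate_percent", a$accuracy$deletion_rate)
      add("insertion_rate_percent", a$accuracy$insertion_rate)
      add("bac_coverage_percent", a$accuracy$bac_coverage_percent)
    }
    if (!is.null(a$misassembly)) {
      for (i in seq_along(a$misassembly$cutoffs)) {
        add(sprintf("misassembly_raw_%d", a$misassembly$cutoffs[i]),
            a$misassembly$raw_counts[i])
        add(sprintf("misassembly_normalized_%d", a$misassembly$cutoffs[i]),
            a$misassembly$normalized_counts[i])
      }
    }
    if (!is.null(a$novelty)) {
      add("novel_bases", a$novelty$novel_bases)
      add("contaminant_fraction", a$novelty$contaminant_fraction)
      add("novel_gc_percent", a$novelty$novel_gc_percent)
    }
    if (!is.null(a$genes)) {
      add("gene_coverage_percent", a$genes$gene_coverage_percent)
    }
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(assembly = character(), metric = character(),
               value = numeric(), stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(outdir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Write a synthetic simulation to disk
#'
#' Emits `truth.fasta`, `assembly.fasta`, `reference.fasta`,
#' `transcripts.fasta`, `genes.gff3`, `contaminant_db.fasta`
#' (a synthetic foreign genome) and `ledger.json`.
#'
#' @param genome A `truth_genome`.
#' @param corruption A `corrupted_assembly`.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(genome, corruption, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_fasta(genome$chromosomes, file.path(outdir, "truth.fasta"))
  write_fasta(corruption$assembly$scaffolds, file.path(outdir, "assembly.fasta"))
  write_fasta(corruption$reference, file.path(outdir, "reference.fasta"))
  write_fasta(genome$transcripts, file.path(outdir, "transcripts.fasta"))
  write_fasta(corruption$foreign, file.path(outdir, "contaminant_db.fasta"))
  g <- genome$genes
  gff <- data.frame(seqid = g$chrom, source = "asmappraise", type = "gene",
                    start = g$start + 1L, end = g$end, score = ".",
                    strand = "+", phase = ".",
                    attributes = sprintf("ID=%s", g$gene_id),
                    stringsAsFactors = FALSE)
  con <- file(file.path(outdir, "genes.gff3"), "w")
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  jsonlite::write_json(unclass(corruption$ledger),
                       file.path(outdir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(outdir)
}

#' Read gene loci from GFF3 or BED
#'
#' GFF3 (1-based closed) is converted to the package's 0-based
#' half-open convention on read; BED already matches.
#'
#' @param path A `.gff`/`.gff3` or `.bed` file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_loci <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(gene_id = if (ncol(bed) >= 4L) bed[[4L]] else
                 sprintf("locus%d", seq_len(nrow(bed))),
               chrom = bed[[1L]], start = bed[[2L]], end = bed[[3L]],
               stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      sprintf("locus%d", seq_along(gr))
    data.frame(gene_id = ids,
               chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               stringsAsFactors = FALSE)
  }
}
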