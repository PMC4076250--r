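guess_aln_format <- function(path) {
  if (grepl("\\.m4(\\.gz)?$", path)) "m4" else "paf"
}

#' Run the full scaffolding pipeline
#'
#' Reads contigs and alignments (or invokes an external aligner on the
#' reads), filters placements, builds the linkage graph, scaffolds, and
#' writes `scaffolds.fasta` (when sequences are available),
#' `scaffolds.agp`, `summary.txt` and `linkage.tsv` into `outdir`.
#'
#' @param contigs path to the assembly FASTA, or `NULL` for alignment-only
#'   mode (contig lengths are then taken from the alignment records and no
#'   FASTA is written).
#' @param reads path to the long reads (FASTA/FASTQ), needed only when an
#'   aligner template is used.
#' @param alignments path to a PAF or m4 alignment file, or an alignment
#'   data.frame (e.g. from [simulate_placements()]).
#' @param aln_format `"paf"` or `"m4"`; guessed from the file name by
#'   default.
#' @param aligner optional external aligner command template with
#'   `{contigs}`, `{reads}` and `{output}` placeholders; used when
#'   `alignments` is `NULL`.
#' @param outdir output directory (created if needed), or `NULL` to skip
#'   all file output.
#' @param fparams,lparams,mparams parameter lists ([filter_params()],
#'   [link_params()], [merge_params()]).
#' @return (invisibly) `list(status = 0, scaffolds, linkage, stats,
#'   files)`.
#' @export
run_scaffold <- function(contigs = NULL, reads = NULL, alignments = NULL,
                         aln_format = NULL, aligner = NULL, outdir = NULL,
                         fparams = filter_params(), lparams = link_params(),
                         mparams = merge_params()) {
  seqs <- NULL
  if (!is.null(contigs)) {
    dss <- read_fasta(contigs)
    seqs <- as.character(dss)
  }
  if (is.null(alignments)) {
    if (is.null(aligner) || is.null(reads)) {
      ls_input_error("either an alignment file or an aligner template plus reads must be given")
    }
    if (!file.exists(reads)) ls_input_error("read file not found: %s", reads)
    if (is.null(outdir)) ls_input_error("aligner mode requires an output directory")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    alignments <- run_aligner(aligner, contigs, reads,
                              file.path(outdir, "alignments.paf"))
  }
  if (is.character(alignments)) {
    fmt <- aln_format %||% guess_aln_format(alignments)
    aln <- parse_alignments(alignments, fmt)
  } else {
    aln <- alignments
  }
  ls_log("alignments: %d records", nrow(aln))
  if (is.null(seqs)) {
    contig_lengths <- vapply(split(aln$contig_len, aln$contig_id), max,
                             numeric(1))
  } else {
    contig_lengths <- nchar(seqs)
    names(contig_lengths) <- names(seqs)
  }
  placements <- collect_placements(aln, seqs, fparams)
  ls_log("placements kept: %d on %d reads", nrow(placements),
         length(unique(placements$read_id)))
  res <- build_scaffolds(placements, contig_lengths, seqs, lparams, mparams)
  scafs <- res$scaffolds
  merged <- sum(unlist(lapply(scafs, function(s) {
    sum(!is.na(s$parts$j_kind) & s$parts$j_kind == "merge")
  })))
  out_lens <- vapply(scafs, function(s) as.numeric(s$length), numeric(1))
  stats <- list(
    input_contigs = length(contig_lengths),
    input_bases = sum(contig_lengths),
    input_n50 = n50(contig_lengths),
    final_scaffolds = length(scafs),
    final_bases = sum(out_lens),
    final_n50 = n50(out_lens),
    inserted_gap_bases = sum(unlist(lapply(scafs, function(s) {
      g <- s$parts$gap_len; g[!is.na(g)]
    }))),
    merged_junctions = merged,
    repeat_contigs = length(res$repeat_flags),
    circular_scaffolds = sum(vapply(scafs, function(s) isTRUE(s$circular),
                                    logical(1)))
  )
  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(seqs)) {
      f <- file.path(outdir, "scaffolds.fasta")
      write_scaffolds_fasta(scafs, seqs, f)
      files <- c(files, f)
    } else {
      warning("no contig sequences given; FASTA output skipped")
    }
    f <- file.path(outdir, "scaffolds.agp")
    write_agp(scafs, contig_lengths, f)
    files <- c(files, f)
    f <- file.path(outdir, "summary.txt")
    write_summary(stats, f)
    files <- c(files, f)
    f <- file.path(outdir, "linkage.tsv")
    write_linkage_tsv(res$linkage$accepted, f)
    files <- c(files, f)
  }
  ls_log("done: %d contigs -> %d scaffolds (N50 %d)",
         stats$input_contigs, stats$final_scaffolds, stats$final_n50)
  invisible(list(status = 0L, scaffolds = scafs, linkage = res$linkage,
                 repeat_flags = res$repeat_flags,
                 placed_repeats = res$placed_repeats, stats = stats,
                 files = files))
}

#' Simulate a benchmark dataset and write it to disk
#'
#' Generates a genome (with optional planted repeats), fragments it into
#' draft contigs with known gaps, simulates CLR-style reads, and writes
#' `genome.fasta`, `contigs.fasta`, `reads.fastq`, `truth.tsv` and
#' `truth.agp` into `outdir`.
#'
#' @param config a [sim_config()] list.
#' @param outdir output directory, or `NULL` to skip file output.
#' @param reads whether to simulate error-carrying read sequences (set
#'   `FALSE` when only [simulate_placements()] will be used).
#' @return (invisibly) `list(genome, repeats, contigs, layout, reads)`.
#' @export
run_simulate <- function(config = sim_config(), outdir = NULL, reads = TRUE) {
  g <- simulate_genome(config)
  fr <- fragment_contigs(g$genome, g$repeats, config)
  rd <- if (reads) simulate_reads(g$genome, config) else NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    gen <- Biostrings::DNAStringSet(g$genome)
    names(gen) <- "genome"
    Biostrings::writeXStringSet(gen, file.path(outdir, "genome.fasta"))
    cdss <- Biostrings::DNAStringSet(fr$contigs)
    Biostrings::writeXStringSet(cdss, file.path(outdir, "contigs.fasta"))
    if (!is.null(rd)) write_fastq(rd, file.path(outdir, "reads.fastq"))
    write_truth(fr$layout, file.path(outdir, "truth.tsv"))
    truth_scaf <- truth_as_scaffold(fr$layout)
    write_agp(list(truth_scaf), nchar(fr$contigs),
              file.path(outdir, "truth.agp"))
  }
  ls_log("simulated %d bp genome, %d contigs, %d truth segments%s",
         config$genome_len, length(fr$contigs), nrow(fr$layout),
         if (reads) sprintf(", %d reads", length(rd)) else "")
  invisible(list(genome = g$genome, repeats = g$repeats,
                 contigs = fr$contigs, layout = fr$layout, reads = rd))
}

# the truth layout expressed as a single scaffold object (for truth.agp)
truth_as_scaffold <- function(layout) {
  n <- nrow(layout)
  parts <- data.frame(
    contig_id = layout$contig_id, orientation = layout$orientation,
    gap_est = NA_real_, support = NA_integer_,
    j_kind = c(rep("gap", n - 1L), NA_character_),
    gap_len = c(pmax(layout$gap_after[-n], 1L), NA_integer_),
    overlap_len = NA_integer_, stringsAsFactors = FALSE)
  # 0-bp true gaps cannot be represented in AGP; recorded as 1 N
  s <- new_scaffold(parts)
  s$id <- "truth"
  s
}

#' Evaluate a written scaffold set against a written truth layout
#'
#' @param scaffolds_agp path to the scaffolds AGP (or a `scaffold_set`).
#' @param truth path to `truth.tsv` (or a layout data.frame).
#' @param circular whether the simulated replicon was circular.
#' @return an `lr_eval` report (printed).
#' @export
run_evaluate <- function(scaffolds_agp, truth, circular = FALSE) {
  layout <- if (is.character(truth)) read_truth(truth) else truth
  if (is.character(scaffolds_agp)) {
    scafs <- read_agp(scaffolds_agp)
  } else {
    scafs <- scaffolds_agp
  }
  ev <- evaluate_scaffolds(scafs, layout, circular)
  print(ev)
  invisible(ev)
}

#' Invoke an external long-read aligner
#'
#' Substitutes `{contigs}`, `{reads}` and `{output}` into the command
#' template, runs it through the shell, and verifies that a non-empty
#' output file was produced. The template must route the aligner's output
#' to `{output}` (e.g. `"minimap2 -x map-pb {contigs} {reads} > {output}"`).
#'
#' @param template command template containing all three placeholders.
#' @param contigs,reads,output file paths substituted into the template.
#' @return `output`, invisibly.
#' @export
run_aligner <- function(template, contigs, reads, output) {
  for (ph in c("{contigs}", "{reads}", "{output}")) {
    if (!grepl(ph, template, fixed = TRUE)) {
      ls_input_error("aligner template lacks the %s placeholder", ph)
    }
  }
  cmd <- template
  cmd <- gsub("{contigs}", shQuote(contigs), cmd, fixed = TRUE)
  cmd <- gsub("{reads}", shQuote(reads), cmd, fixed = TRUE)
  cmd <- gsub("{output}", shQuote(output), cmd, fixed = TRUE)
  ls_log("running aligner: %s", cmd)
  status <- system(cmd)
  if (status != 0L) {
    ls_aligner_error("aligner command failed (exit %d): %s", status, cmd)
  }
  if (!file.exists(output) || file.size(output) == 0L) {
    ls_aligner_error("aligner produced no output: %s", cmd)
  }
  invisible(output)
}
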