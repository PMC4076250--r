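#' Read an assembly FASTA file
#'
#' Reads pre-assembled contigs (or scaffolds) and normalizes them for the
#' pipeline: sequences are upper-cased and each record id is the first
#' whitespace-delimited token of its header.
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return a named [Biostrings::DNAStringSet] of contigs.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) ls_input_error("contig FASTA not found: %s", path)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) ls_parse_error("failed to parse FASTA %s: %s",
                                       path, conditionMessage(e))
  )
  if (length(dss) == 0L) ls_parse_error("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(dss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    ls_parse_error("duplicate id %s in %s", dup[1L], path)
  }
  names(dss) <- ids
  dss <- Biostrings::DNAStringSet(toupper(as.character(dss)))
  names(dss) <- ids
  dss
}

#' Read long reads in FASTA or FASTQ format
#'
#' The format is auto-detected from the first byte of the (possibly
#' gzip-compressed) file: `@` means FASTQ, `>` means FASTA. Base qualities
#' are ignored by the pipeline.
#'
#' @param path path to a FASTA/FASTQ file, optionally gzipped.
#' @return a named [Biostrings::DNAStringSet] of reads.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) ls_input_error("read file not found: %s", path)
  con <- gzfile(path, "rb")
  first <- rawToChar(readBin(con, "raw", n = 1L))
  close(con)
  fmt <- switch(first, "@" = "fastq", ">" = "fasta",
                ls_parse_error("cannot detect FASTA/FASTQ format of %s", path))
  if (fmt == "fastq") validate_fastq(path)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) ls_parse_error("failed to parse %s %s: %s",
                                       fmt, path, conditionMessage(e))
  )
  names(dss) <- sub("\\s.*$", "", names(dss))
  dss
}

# structural FASTQ checks Biostrings does not enforce: strict 4-line
# records and per-record sequence/quality length agreement
validate_fastq <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    last_id <- lines[max(which(startsWith(lines, "@")))]
    ls_parse_error("truncated record at end of %s (near %s)", path, last_id)
  }
  sq <- lines[seq(2L, length(lines), by = 4L)]
  qu <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad) > 0L) {
    ls_parse_error("sequence/quality length mismatch in record %s",
                   lines[(bad[1L] - 1L) * 4L + 1L])
  }
  invisible(TRUE)
}

# oriented part sequences of one scaffold (character vector, one per part)
scaffold_part_seqs <- function(parts, seqs) {
  miss <- setdiff(parts$contig_id, names(seqs))
  if (length(miss) > 0L) {
    ls_input_error("missing contig sequence: %s", miss[1L])
  }
  out <- as.character(seqs[parts$contig_id])
  rev <- parts$orientation == "-"
  if (any(rev)) out[rev] <- revcomp(out[rev])
  out
}

# emit the linear sequence of one scaffold (gaps as N runs, merges spliced)
scaffold_sequence <- function(scaf, seqs) {
  ps <- scaffold_part_seqs(scaf$parts, seqs)
  n <- length(ps)
  pieces <- character(0)
  for (i in seq_len(n)) {
    s <- ps[i]
    if (i < n) {
      kind <- scaf$parts$j_kind[i]
      if (identical(kind, "merge")) {
        ov <- scaf$parts$overlap_len[i]
        s <- substr(s, 1L, nchar(s) - ov)
      } else {
        s <- paste0(s, strrep("N", scaf$parts$gap_len[i]))
      }
    }
    pieces <- c(pieces, s)
  }
  out <- paste(pieces, collapse = "")
  if (isTRUE(scaf$circular) && identical(scaf$circ_kind, "merge") &&
      scaf$circ_overlap > 0L) {
    out <- substr(out, 1L, nchar(out) - scaf$circ_overlap)
  }
  out
}

#' Write scaffolds to FASTA
#'
#' Gaps are emitted as runs of `N`, reverse-oriented contigs as reverse
#' complements, and merged junctions are spliced at their overlap. Scaffold
#' records are named `scaffold_1..scaffold_n` in order of decreasing length
#' (ties broken by first contig id); call [finalize_scaffolds()] first so
#' names here and in the AGP agree.
#'
#' @param scaffolds a `scaffold_set` with resolved junctions.
#' @param seqs named contig sequences ([Biostrings::DNAStringSet] or
#'   character vector).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scaffolds_fasta <- function(scaffolds, seqs, path) {
  ids <- names(seqs)
  seqs <- as.character(seqs)
  names(seqs) <- ids
  out <- vapply(scaffolds, scaffold_sequence, character(1), seqs = seqs)
  dss <- Biostrings::DNAStringSet(out)
  names(dss) <- vapply(scaffolds, function(s) s$id, character(1))
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

#' Write reads to FASTQ with constant quality
#'
#' Used by the simulator; qualities carry no information for this pipeline
#' and are written as a constant `I`.
#'
#' @param reads named character vector or DNAStringSet.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  s <- as.character(reads)
  names(s) <- ids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(s), "\n", s, "\n+\n",
                    strrep("I", nchar(s))), con)
  invisible(path)
}
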