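#' Parse read-to-contig alignments (PAF or BLASR m4)
#'
#' All coordinates are normalized to the internal convention: 0-based
#' half-open intervals on the forward strand of both read and contig, with a
#' single `strand` column (`+`/`-`) for the relative orientation.
#'
#' For PAF (minimap2 dialect, columns 1-12; trailing tags ignored) the score
#' is column 10 (residue matches) and identity is column 10 / column 11.
#' For m4 (`qname tname score pctsimilarity qstrand qstart qend qseqlength
#' tstrand tstart tend tseqlength mapqv`) the strand is the product of
#' qstrand and tstrand, reverse-strand coordinates are flipped to the
#' forward strand, identity is `pctsimilarity/100`, and the
#' negative-is-better m4 score is stored as a positive magnitude so that
#' "higher score is better" holds for both formats.
#'
#' @param path alignment file.
#' @param format `"paf"` or `"m4"`.
#' @return a data.frame with columns `read_id, read_len, read_start,
#'   read_end, strand, contig_id, contig_len, contig_start, contig_end,
#'   score, identity, block_len, mapq`.
#' @export
parse_alignments <- function(path, format = c("paf", "m4")) {
  format <- match.arg(format)
  if (!file.exists(path)) ls_input_error("alignment file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("no alignments in ", path)
    return(empty_alignments())
  }
  fields <- strsplit(lines, "[ \t]+")
  ncols <- if (format == "paf") 12L else 13L
  bad <- which(lengths(fields) < ncols)
  if (length(bad) > 0L) {
    ls_parse_error("malformed %s line %d in %s (expected >= %d columns)",
                   format, bad[1L], path, ncols)
  }
  m <- do.call(rbind, lapply(fields, function(f) f[seq_len(ncols)]))
  if (format == "paf") parse_paf_matrix(m) else parse_m4_matrix(m)
}

empty_alignments <- function() {
  data.frame(read_id = character(0), read_len = integer(0),
             read_start = integer(0), read_end = integer(0),
             strand = character(0), contig_id = character(0),
             contig_len = integer(0), contig_start = integer(0),
             contig_end = integer(0), score = numeric(0),
             identity = numeric(0), block_len = integer(0),
             mapq = integer(0), stringsAsFactors = FALSE)
}

parse_paf_matrix <- function(m) {
  num <- function(i) suppressWarnings(as.numeric(m[, i]))
  df <- data.frame(
    read_id = m[, 1L], read_len = num(2L),
    read_start = num(3L), read_end = num(4L),
    strand = m[, 5L],
    contig_id = m[, 6L], contig_len = num(7L),
    contig_start = num(8L), contig_end = num(9L),
    score = num(10L), identity = num(10L) / num(11L),
    block_len = num(11L), mapq = num(12L),
    stringsAsFactors = FALSE
  )
  validate_alignments(df)
}

parse_m4_matrix <- function(m) {
  num <- function(i) suppressWarnings(as.numeric(m[, i]))
  qstrand <- num(5L); tstrand <- num(9L)
  qs <- num(6L); qe <- num(7L); qlen <- num(8L)
  ts <- num(10L); te <- num(11L); tlen <- num(12L)
  # flip reverse-strand coordinates to the forward strand
  flipq <- qstrand == 1
  qs2 <- ifelse(flipq, qlen - qe, qs)
  qe2 <- ifelse(flipq, qlen - qs, qe)
  flipt <- tstrand == 1
  ts2 <- ifelse(flipt, tlen - te, ts)
  te2 <- ifelse(flipt, tlen - ts, te)
  df <- data.frame(
    read_id = m[, 1L], read_len = qlen,
    read_start = qs2, read_end = qe2,
    strand = ifelse(qstrand == tstrand, "+", "-"),
    contig_id = m[, 2L], contig_len = tlen,
    contig_start = ts2, contig_end = te2,
    score = abs(num(3L)), identity = num(4L) / 100,
    block_len = NA_real_, mapq = num(13L),
    stringsAsFactors = FALSE
  )
  validate_alignments(df)
}

validate_alignments <- function(df) {
  if (anyNA(df[c("read_len", "read_start", "read_end",
                 "contig_start", "contig_end", "score")])) {
    ls_parse_error("non-numeric coordinate field in alignment file")
  }
  bad <- with(df, read_start < 0 | read_start >= read_end |
                read_end > read_len |
                contig_start < 0 | contig_start >= contig_end |
                contig_end > contig_len |
                identity < 0 | identity > 1 |
                !(strand %in% c("+", "-")))
  if (any(bad)) {
    ls_parse_error("invalid alignment record at line %d", which(bad)[1L])
  }
  df
}

#' Serialize alignments back to PAF or m4 lines
#'
#' Inverse of [parse_alignments()]; used for round-trip checks and debug
#' dumps. m4 records are written with `qstrand = 0`, so the relative strand
#' is carried entirely by `tstrand` and reverse-strand target coordinates
#' are flipped back to the m4 on-strand convention.
#'
#' @param df alignment data.frame in the internal convention.
#' @param format `"paf"` or `"m4"`.
#' @return character vector of lines.
#' @export
format_alignments <- function(df, format = c("paf", "m4")) {
  format <- match.arg(format)
  fi <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (format == "paf") {
    paste(df$read_id, fi(df$read_len), fi(df$read_start), fi(df$read_end),
          df$strand, df$contig_id, fi(df$contig_len), fi(df$contig_start),
          fi(df$contig_end), fi(df$score), fi(df$block_len), fi(df$mapq),
          sep = "\t")
  } else {
    flip <- df$strand == "-"
    ts <- ifelse(flip, df$contig_len - df$contig_end, df$contig_start)
    te <- ifelse(flip, df$contig_len - df$contig_start, df$contig_end)
    paste(df$read_id, df$contig_id, fi(-df$score),
          fi(df$identity * 100), "0",
          fi(df$read_start), fi(df$read_end), fi(df$read_len),
          fi(as.integer(flip)), fi(ts), fi(te), fi(df$contig_len),
          fi(df$mapq), sep = " ")
  }
}
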