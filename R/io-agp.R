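# per-part right-end trims implied by merge junctions (and a circular
# closing merge, which trims the last part)
part_trims <- function(scaf) {
  n <- nrow(scaf$parts)
  trim <- ifelse(!is.na(scaf$parts$j_kind) & scaf$parts$j_kind == "merge",
                 scaf$parts$overlap_len, 0L)
  trim[is.na(trim)] <- 0L
  if (isTRUE(scaf$circular) && identical(scaf$circ_kind, "merge")) {
    trim[n] <- trim[n] + scaf$circ_overlap
  }
  as.integer(trim)
}

agp_rows_one <- function(scaf, contig_lengths) {
  p <- scaf$parts
  n <- nrow(p)
  lens <- as.integer(contig_lengths[p$contig_id])
  if (anyNA(lens)) {
    ls_input_error("contig %s has no known length",
                   p$contig_id[which(is.na(lens))[1L]])
  }
  trim <- part_trims(scaf)
  rows <- list()
  pos <- 0L
  part_no <- 0L
  for (i in seq_len(n)) {
    emit_len <- lens[i] - trim[i]
    part_no <- part_no + 1L
    if (p$orientation[i] == "+") {
      cbeg <- 1L; cend <- emit_len
    } else {
      cbeg <- trim[i] + 1L; cend <- lens[i]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      object = scaf$id, object_beg = pos + 1L, object_end = pos + emit_len,
      part_number = part_no, component_type = "W",
      component_id = p$contig_id[i], component_beg = cbeg,
      component_end = cend, orientation = p$orientation[i],
      stringsAsFactors = FALSE)
    pos <- pos + emit_len
    if (i < n && identical(p$j_kind[i], "gap")) {
      g <- as.integer(p$gap_len[i])
      part_no <- part_no + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = scaf$id, object_beg = pos + 1L, object_end = pos + g,
        part_number = part_no, component_type = "N",
        component_id = as.character(g), component_beg = "scaffold",
        component_end = "yes", orientation = "align_genus",
        stringsAsFactors = FALSE)
      pos <- pos + g
    }
  }
  do.call(rbind, rows)
}

#' Write scaffolds as AGP v2.1
#'
#' Contigs become `W` rows (with `+`/`-` orientation) and gap junctions
#' become `N` rows with gap type `scaffold`, linkage `yes` and evidence
#' `align_genus`. Merged junctions produce no gap row; the merge overlap is
#' accounted for in the left component's coordinates, so object lengths
#' always equal the emitted FASTA lengths exactly.
#'
#' @param scaffolds a finalized `scaffold_set`.
#' @param contig_lengths named integer vector of contig lengths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(scaffolds, contig_lengths, path) {
  rows <- do.call(rbind, lapply(scaffolds, agp_rows_one,
                                contig_lengths = contig_lengths))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(rows, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an AGP file back into a scaffold layout
#'
#' Reconstructs object order, component orientation and gap lengths.
#' Adjacent `W` rows with no intervening gap row are interpreted as merged
#' junctions; when `contig_lengths` is supplied, the merge overlap is
#' recovered from the component coordinates.
#'
#' @param path AGP file.
#' @param contig_lengths optional named integer vector of contig lengths.
#' @return a list of scaffolds, each `list(id, parts, circular = FALSE)`.
#' @export
read_agp <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) ls_input_error("AGP file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t")
  bad <- which(lengths(f) < 9L)
  if (length(bad)) ls_parse_error("malformed AGP line %d in %s", bad[1L], path)
  m <- do.call(rbind, lapply(f, `[`, 1:9))
  objs <- unique(m[, 1L])
  lapply(objs, function(o) {
    sub <- m[m[, 1L] == o, , drop = FALSE]
    sub <- sub[order(as.integer(sub[, 4L])), , drop = FALSE]
    parts <- list()
    pending_gap <- NA_integer_
    for (i in seq_len(nrow(sub))) {
      if (sub[i, 5L] == "N" || sub[i, 5L] == "U") {
        pending_gap <- as.integer(sub[i, 6L])
        if (length(parts)) {
          parts[[length(parts)]]$j_kind <- "gap"
          parts[[length(parts)]]$gap_len <- pending_gap
        }
      } else {
        if (length(parts) && is.na(parts[[length(parts)]]$j_kind)) {
          # no gap row between two W rows: merged junction
          prev <- parts[[length(parts)]]
          ov <- NA_integer_
          if (!is.null(contig_lengths)) {
            ov <- as.integer(contig_lengths[prev$contig_id]) -
              (prev$comp_end - prev$comp_beg + 1L)
          }
          parts[[length(parts)]]$j_kind <- "merge"
          parts[[length(parts)]]$overlap_len <- ov
        }
        parts[[length(parts) + 1L]] <- list(
          contig_id = sub[i, 6L], orientation = sub[i, 9L],
          comp_beg = as.integer(sub[i, 7L]), comp_end = as.integer(sub[i, 8L]),
          j_kind = NA_character_, gap_len = NA_integer_,
          overlap_len = NA_integer_)
      }
    }
    pdf <- data.frame(
      contig_id = vapply(parts, `[[`, character(1), "contig_id"),
      orientation = vapply(parts, `[[`, character(1), "orientation"),
      gap_est = NA_real_, support = NA_integer_,
      j_kind = vapply(parts, `[[`, character(1), "j_kind"),
      gap_len = vapply(parts, `[[`, integer(1), "gap_len"),
      overlap_len = vapply(parts, `[[`, integer(1), "overlap_len"),
      stringsAsFactors = FALSE)
    pdf$j_kind[nrow(pdf)] <- NA_character_
    list(id = o, parts = pdf, circular = FALSE,
         length = max(as.integer(sub[, 3L])))
  })
}

#' Write a plain-text run summary
#'
#' @param run_stats named list of summary quantities (input contig count /
#'   bases / N50, scaffold count / bases / N50, gap bases, merges, repeat
#'   flags, circular scaffolds, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(run_stats, path) {
  keys <- names(run_stats)
  vals <- vapply(run_stats, function(v) paste(format(v, scientific = FALSE),
                                              collapse = ","), character(1))
  writeLines(c("# longscaff assembly summary",
               sprintf("%s: %s", keys, vals)), path)
  invisible(path)
}
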