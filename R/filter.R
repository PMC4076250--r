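#' Filtering parameters for read placements
#'
#' @param g minimum overlap (bp) between aligned read intervals for the
#'   lower-scoring placement to be removed (the `-g` flag). Raise to ~500
#'   for drafts that carry repeats on contig edges.
#' @param min_identity minimum alignment identity to consider a placement.
#' @param min_aln_len minimum aligned length (bp) on the read.
#' @return a `filter_params` list.
#' @export
filter_params <- function(g = 200, min_identity = 0.70, min_aln_len = 100) {
  stopifnot(g >= 0, min_identity >= 0, min_identity <= 1, min_aln_len >= 0)
  structure(list(g = g, min_identity = min_identity,
                 min_aln_len = min_aln_len), class = "filter_params")
}

#' Extend local alignments to projected full-contig spans
#'
#' For gap estimation each local alignment is extended so that it covers
#' the whole contig, projected onto read coordinates at the alignment's
#' local scale `s = (read_end - read_start) / (contig_end - contig_start)`.
#' On the forward strand the unaligned contig head extends the span to the
#' left and the tail to the right; on the reverse strand the two tails swap
#' sides. Extended coordinates are deliberately left unclamped (they may be
#' negative or exceed the read length).
#'
#' @param alignments alignment data.frame from [parse_alignments()].
#' @return a placement data.frame with columns `read_id, contig_id, strand`
#'   (`F`/`R`, contig orientation as read along the read), `aln_read_start,
#'   aln_read_end, ext_read_start, ext_read_end, score, identity`.
#' @export
extend_placements <- function(alignments) {
  a <- alignments
  span_c <- a$contig_end - a$contig_start
  if (any(span_c <= 0)) {
    a <- a[span_c > 0, , drop = FALSE]
    span_c <- a$contig_end - a$contig_start
  }
  s <- (a$read_end - a$read_start) / span_c
  left_tail <- ifelse(a$strand == "+", a$contig_start,
                      a$contig_len - a$contig_end)
  right_tail <- ifelse(a$strand == "+", a$contig_len - a$contig_end,
                       a$contig_start)
  data.frame(
    read_id = a$read_id,
    contig_id = a$contig_id,
    strand = ifelse(a$strand == "+", "F", "R"),
    aln_read_start = a$read_start,
    aln_read_end = a$read_end,
    ext_read_start = a$read_start - round(s * left_tail),
    ext_read_end = a$read_end + round(s * right_tail),
    score = a$score,
    identity = a$identity,
    stringsAsFactors = FALSE
  )
}

# deterministic placement ranking: best first
placement_order <- function(p) {
  order(-p$score, -p$identity, p$contig_id, p$aln_read_start)
}

#' Keep only the best placements on one read
#'
#' Best-alignment filter: placements are ranked by score (ties: identity,
#' contig id, position) and a placement is removed when its aligned read
#' interval overlaps that of any higher-ranked placement by more than `g`
#' bases. Overlap is measured on the aligned intervals, not the extended
#' spans. The survivor set is therefore monotone in `g` (raising `g` never
#' loses a survivor), and a contig may survive several times on one read at
#' disjoint positions (repeat copies).
#'
#' @param p placement data.frame for a single read.
#' @param params a [filter_params()] list.
#' @return the surviving rows of `p`.
#' @export
filter_read_placements <- function(p, params = filter_params()) {
  n <- nrow(p)
  if (n <= 1L) return(p)
  ord <- placement_order(p)
  s <- p$aln_read_start[ord]
  e <- p$aln_read_end[ord]
  keep <- logical(n)
  for (i in seq_len(n)) {
    hi <- seq_len(i - 1L)
    ov <- pmin(e[hi], e[i]) - pmax(s[hi], s[i])
    keep[i] <- !any(ov > params$g)
  }
  p[sort(ord[keep]), , drop = FALSE]
}

#' Extend, pre-filter and best-filter all alignments into placements
#'
#' Applies the identity/length pre-filters, extends alignments to projected
#' contig spans, and runs [filter_read_placements()] per read. The result is
#' deterministic regardless of input record order.
#'
#' @param alignments alignment data.frame.
#' @param contigs optional named contig sequences or lengths; when given,
#'   alignments to unknown contigs are an error and contig lengths are
#'   cross-checked.
#' @param params a [filter_params()] list.
#' @return a placement data.frame covering all reads with >= 1 surviving
#'   placement, sorted by `(read_id, aln_read_start, contig_id)`.
#' @export
collect_placements <- function(alignments, contigs = NULL,
                               params = filter_params()) {
  a <- alignments
  if (!is.null(contigs)) {
    ids <- names(contigs)
    unknown <- setdiff(unique(a$contig_id), ids)
    if (length(unknown) > 0L) {
      ls_input_error("alignment references contig %s absent from the assembly",
                     unknown[1L])
    }
  }
  a <- a[a$identity >= params$min_identity &
           (a$read_end - a$read_start) >= params$min_aln_len, , drop = FALSE]
  p <- extend_placements(a)
  if (nrow(p) == 0L) return(p)
  # canonical row order, then per-read filtering
  p <- p[order(p$read_id, p$aln_read_start, p$contig_id, -p$score), ,
         drop = FALSE]
  idx <- split(seq_len(nrow(p)), p$read_id)
  multi <- idx[lengths(idx) > 1L]
  drop <- unlist(lapply(multi, function(i) {
    sub <- p[i, , drop = FALSE]
    keep <- rownames(filter_read_placements(sub, params))
    i[!(rownames(sub) %in% keep)]
  }), use.names = FALSE)
  if (length(drop) > 0L) p <- p[-drop, , drop = FALSE]
  rownames(p) <- NULL
  p
}
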