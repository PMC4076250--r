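# canonical junction key between two oriented scaffold parts
junction_key <- function(cid_l, or_l, cid_r, or_r) {
  e <- canon_link(cid_l, ifelse(or_l == "+", "tail", "head"),
                  cid_r, ifelse(or_r == "+", "head", "tail"))
  link_key(e$a_id, e$a_end, e$b_id, e$b_end)
}

# junction keys + output gap estimates of a scaffold set
scaffold_junctions <- function(scaffolds) {
  out <- lapply(scaffolds, function(s) {
    p <- s$parts
    n <- nrow(p)
    if (n < 2L) return(NULL)
    i <- seq_len(n - 1L)
    gap <- p$gap_est[i]
    fallback <- ifelse(!is.na(p$j_kind[i]) & p$j_kind[i] == "merge",
                       -p$overlap_len[i], p$gap_len[i])
    df <- data.frame(key = junction_key(p$contig_id[i], p$orientation[i],
                                  p$contig_id[i + 1L], p$orientation[i + 1L]),
               gap = ifelse(is.na(gap), fallback, gap),
               left = p$contig_id[i], right = p$contig_id[i + 1L],
               stringsAsFactors = FALSE)
    if (isTRUE(s$circular) && !is.na(s$circ_gap_est)) {
      df <- rbind(df, data.frame(
        key = junction_key(p$contig_id[n], p$orientation[n],
                           p$contig_id[1L], p$orientation[1L]),
        gap = s$circ_gap_est, left = p$contig_id[n],
        right = p$contig_id[1L], stringsAsFactors = FALSE))
    }
    df
  })
  do.call(rbind, out)
}

# junction keys + true gaps of the truth layout
truth_junctions <- function(layout, circular = FALSE) {
  n <- nrow(layout)
  i <- seq_len(n - 1L)
  df <- data.frame(
    key = junction_key(layout$contig_id[i], layout$orientation[i],
                       layout$contig_id[i + 1L], layout$orientation[i + 1L]),
    gap = layout$gap_after[i],
    left = layout$contig_id[i], right = layout$contig_id[i + 1L],
    stringsAsFactors = FALSE)
  if (circular && n > 1L) {
    df <- rbind(df, data.frame(
      key = junction_key(layout$contig_id[n], layout$orientation[n],
                         layout$contig_id[1L], layout$orientation[1L]),
      gap = layout$gap_after[n],
      left = layout$contig_id[n], right = layout$contig_id[1L],
      stringsAsFactors = FALSE))
  }
  df
}

#' Evaluate scaffolds against the simulated truth layout
#'
#' Junctions are compared as canonical oriented contig-end adjacencies
#' (orientation-agnostic to the scaffold's reading direction). A scaffold
#' junction matching a truth adjacency is a correct join; one contradicting
#' the truth (adjacency or relative orientation) is a misjoin; a truth
#' adjacency absent from the output is a missed join. Gap-size errors are
#' reported on the estimated gaps of correct joins. Truth adjacencies are
#' matched as a multiset, so multi-copy repeat junctions must each be
#' recovered separately.
#'
#' @param scaffolds a `scaffold_set` (or list of scaffolds with `parts`).
#' @param layout truth layout from [fragment_contigs()].
#' @param circular whether the simulated replicon was circular.
#' @return an `lr_eval` list: scaffold/junction counts, `correct_joins`,
#'   `missed_joins`, `misjoins`, `gap_errors` (per matched junction),
#'   repeat placement counts, N50 and total gap bases.
#' @export
evaluate_scaffolds <- function(scaffolds, layout, circular = FALSE) {
  known <- unique(layout$contig_id)
  used <- unique(unlist(lapply(scaffolds, function(s) s$parts$contig_id)))
  unknown <- setdiff(used, known)
  if (length(unknown) > 0L) {
    ls_input_error("contig %s unknown to the truth layout", unknown[1L])
  }
  sj <- scaffold_junctions(scaffolds)
  tj <- truth_junctions(layout, circular)
  n_out <- if (is.null(sj)) 0L else nrow(sj)
  tcount <- table(tj$key)
  ocount <- if (n_out) table(sj$key) else table(character(0))
  shared <- intersect(names(tcount), names(ocount))
  correct <- sum(pmin(tcount[shared], ocount[shared]))
  misjoins <- n_out - correct
  missed <- nrow(tj) - correct
  gap_err <- numeric(0)
  if (n_out > 0L) {
    match_idx <- match(sj$key, tj$key)
    ok <- !is.na(match_idx)
    gap_err <- abs(sj$gap[ok] - tj$gap[match_idx[ok]])
  }
  rep_ids <- unique(layout$contig_id[layout$multiplicity > 1L])
  rep_truth <- tj$left %in% rep_ids | tj$right %in% rep_ids
  rep_out <- if (n_out) (sj$left %in% rep_ids | sj$right %in% rep_ids) else logical(0)
  rep_shared <- intersect(names(table(tj$key[rep_truth])),
                          names(if (n_out) table(sj$key[rep_out]) else table(character(0))))
  rep_correct <- if (length(rep_shared))
    sum(pmin(table(tj$key[rep_truth])[rep_shared],
             table(sj$key[rep_out])[rep_shared])) else 0L
  lens <- vapply(scaffolds, function(s) as.numeric(s$length %||% NA), numeric(1))
  gapbases <- sum(unlist(lapply(scaffolds, function(s) {
    g <- s$parts$gap_len; g[!is.na(g)]
  })))
  structure(list(
    n_scaffolds = length(scaffolds),
    n_truth_junctions = nrow(tj),
    n_output_junctions = n_out,
    correct_joins = as.integer(correct),
    missed_joins = as.integer(missed),
    misjoins = as.integer(misjoins),
    gap_errors = as.numeric(gap_err),
    repeat_junctions_truth = as.integer(sum(rep_truth)),
    repeat_junctions_correct = as.integer(rep_correct),
    n50 = n50(lens),
    total_gap_bases = as.integer(gapbases),
    circular_scaffolds = sum(vapply(scaffolds, function(s)
      isTRUE(s$circular), logical(1)))
  ), class = "lr_eval")
}

#' @export
print.lr_eval <- function(x, ...) {
  cat(sprintf(paste0(
    "scaffolds: %d (N50 %d)\njunctions: %d output / %d truth\n",
    "correct joins: %d  misjoins: %d  missed: %d\n",
    "repeat junctions recovered: %d/%d\n",
    "gap error: mean %.1f, max %.1f (n=%d)\n"),
    x$n_scaffolds, x$n50, x$n_output_junctions, x$n_truth_junctions,
    x$correct_joins, x$misjoins, x$missed_joins,
    x$repeat_junctions_correct, x$repeat_junctions_truth,
    if (length(x$gap_errors)) mean(x$gap_errors) else NA,
    if (length(x$gap_errors)) max(x$gap_errors) else NA,
    length(x$gap_errors)))
  invisible(x)
}

#' Write / read a truth layout as TSV
#'
#' @param layout truth layout data.frame.
#' @param path file path.
#' @return `path` (write) or the layout data.frame (read).
#' @export
write_truth <- function(layout, path) {
  write.table(layout, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) ls_input_error("truth file not found: %s", path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(contig_id = "character"))
}
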