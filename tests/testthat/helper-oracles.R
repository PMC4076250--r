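# Independent oracle implementations and small fixture builders.
# These deliberately re-derive expected behaviour by a different route than
# the package code paths they check.

# pairwise formulation of the best-placement filter: placement i survives
# iff no placement ranked above it overlaps its aligned interval by more
# than g. Rank comparison is spelled out tuple-by-tuple rather than via
# order(), so this is an independent route to the same definition.
brute_filter <- function(p, g) {
  ranks_above <- function(i, j) {  # is j ranked strictly above i?
    if (p$score[j] != p$score[i]) return(p$score[j] > p$score[i])
    if (p$identity[j] != p$identity[i]) return(p$identity[j] > p$identity[i])
    if (p$contig_id[j] != p$contig_id[i]) return(p$contig_id[j] < p$contig_id[i])
    p$aln_read_start[j] < p$aln_read_start[i]
  }
  n <- nrow(p)
  acc <- Filter(function(i) {
    for (j in seq_len(n)) {
      if (j == i || !ranks_above(i, j)) next
      ov <- min(p$aln_read_end[i], p$aln_read_end[j]) -
        max(p$aln_read_start[i], p$aln_read_start[j])
      if (ov > g) return(FALSE)
    }
    TRUE
  }, seq_len(n))
  p[sort(unlist(acc)), , drop = FALSE]
}

# containment oracle: is the direct link (a_id, a_end)--(b_id, b_end)
# shortcutting some stored path (same relative orientation, >= 1
# intervening contig)? Uses unordered end-set comparison, independent of
# the package's canonical-key machinery.
path_shortcuts_link <- function(path_cids, path_strands, a_id, a_end,
                                b_id, b_end) {
  facing_next <- c(F = "tail", R = "head")
  facing_prev <- c(F = "head", R = "tail")
  m <- length(path_cids)
  want <- sort(paste0(c(a_id, b_id), "/", c(a_end, b_end)))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j - i < 2) next
      got <- sort(paste0(
        c(path_cids[i], path_cids[j]), "/",
        c(facing_next[[path_strands[i]]], facing_prev[[path_strands[j]]])))
      if (identical(got, want)) return(TRUE)
    }
  }
  FALSE
}

# fixture builders -----------------------------------------------------------

mk_placements <- function(starts, ends, scores, read_id = "r1",
                          contig_id = NULL, identity = 0.9) {
  n <- length(starts)
  data.frame(
    read_id = rep(read_id, n),
    contig_id = contig_id %||% paste0("c", seq_len(n)),
    strand = rep("F", n),
    aln_read_start = starts, aln_read_end = ends,
    ext_read_start = starts, ext_read_end = ends,
    score = scores, identity = rep_len(identity, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a links data.frame row in the package's canonical form
mk_link <- function(a_id, a_end, b_id, b_end, support, gaps = NULL) {
  cl <- longscaff:::canon_link(a_id, a_end, b_id, b_end)
  out <- data.frame(key = longscaff:::link_key(cl$a_id, cl$a_end,
                                               cl$b_id, cl$b_end),
                    a_id = cl$a_id, a_end = cl$a_end,
                    b_id = cl$b_id, b_end = cl$b_end,
                    support = support, stringsAsFactors = FALSE)
  out$gaps <- list(gaps %||% rep(100, support))
  out
}

mk_links <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# a stored multi-contig path entry (n supporting reads, one gap row each)
mk_path <- function(cids, strands, gaps, n = 1L) {
  gm <- matrix(rep(gaps, n), nrow = n, byrow = TRUE)
  list(cids = cids, strands = strands, n = n, gaps = gm)
}

mk_graph <- function(links = NULL, paths = list(), flags = character(0)) {
  structure(list(links = links %||% longscaff:::empty_links(),
                 paths = paths, repeat_flags = flags),
            class = "linkage_graph")
}

mk_scaffold <- function(cids, orients, gap_est = NULL, support = NULL) {
  n <- length(cids)
  p <- do.call(rbind, lapply(seq_len(n), function(i) {
    longscaff:::part_row(cids[i], orients[i])
  }))
  if (!is.null(gap_est)) p$gap_est <- c(gap_est, NA_real_)[seq_len(n)]
  if (!is.null(support)) p$support <- c(support, NA_integer_)[seq_len(n)]
  longscaff:::new_scaffold(p)
}

# alignment record builder in the internal convention
mk_aln <- function(read_id = "r1", read_len = 1000, read_start = 0,
                   read_end = 500, strand = "+", contig_id = "c1",
                   contig_len = 600, contig_start = 0, contig_end = 500,
                   score = NULL, identity = 0.95) {
  score <- score %||% (read_end - read_start)
  data.frame(read_id = read_id, read_len = read_len,
             read_start = read_start, read_end = read_end, strand = strand,
             contig_id = contig_id, contig_len = contig_len,
             contig_start = contig_start, contig_end = contig_end,
             score = score, identity = identity,
             block_len = read_end - read_start, mapq = 60,
             stringsAsFactors = FALSE)
}

# quick noise-free simulated dataset for end-to-end checks
quick_sim <- function(seed, genome_len = 100000, n_contigs = 10,
                      coverage = 20, error_rate = 0, read_len_mean = 3000,
                      read_len_sigma = 0, ...) {
  cfg <- sim_config(genome_len = genome_len, n_contigs = n_contigs,
                    coverage = coverage, error_rate = error_rate,
                    read_len_mean = read_len_mean,
                    read_len_sigma = read_len_sigma, seed = seed, ...)
  sim <- suppressMessages(run_simulate(cfg, reads = FALSE))
  list(cfg = cfg, sim = sim, aln = simulate_placements(sim$layout, cfg))
}
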