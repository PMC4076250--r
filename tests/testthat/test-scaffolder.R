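test_that("accepted links chain into oriented scaffolds", {
  scafs <- chain_scaffolds(mk_links(
    mk_link("A", "tail", "B", "head", 5),
    mk_link("B", "tail", "C", "head", 5)), c("A", "B", "C", "D"))
  chains <- lapply(scafs, function(s) paste0(s$parts$contig_id,
                                             s$parts$orientation))
  expect_true(list(c("A+", "B+", "C+")) %in% chains ||
                list(c("C-", "B-", "A-")) %in% chains)
  # the unlinked contig becomes a singleton
  expect_true(list("D+") %in% chains)

  # tail-tail link flips the second contig
  scafs <- chain_scaffolds(mk_links(mk_link("A", "tail", "B", "tail", 5)),
                           c("A", "B"))
  chains <- lapply(scafs, function(s) paste0(s$parts$contig_id,
                                             s$parts$orientation))
  expect_true(list(c("A+", "B-")) %in% chains ||
                list(c("B+", "A-")) %in% chains)

  # a cyclic component is opened at its weakest junction and marked circular
  scafs <- chain_scaffolds(mk_links(
    mk_link("A", "tail", "B", "head", 5),
    mk_link("B", "tail", "C", "head", 4),
    mk_link("C", "tail", "A", "head", 2, gaps = c(7, 9))), c("A", "B", "C"))
  expect_length(scafs, 1)
  s <- scafs[[1]]
  expect_true(s$circular)
  expect_equal(nrow(s$parts), 3)
  expect_equal(s$circ_support, 2L)   # weakest link forms the closure
  expect_equal(s$circ_gap_est, 7)    # lower median of its estimates
})

test_that("duplicate accepted links on one end are an internal error", {
  expect_error(chain_scaffolds(mk_links(
    mk_link("A", "tail", "B", "head", 5),
    mk_link("A", "tail", "C", "head", 5)), c("A", "B", "C")),
    "2 accepted links")
})

test_that("repeats are placed at junctions from path evidence", {
  scaf <- mk_scaffold(c("X", "Y"), c("+", "+"), gap_est = 2100,
                      support = 4L)
  g <- mk_graph(paths = list(p = mk_path(c("X", "R", "Y"), c("F", "F", "F"),
                                         c(40, 60), n = 4)),
                flags = "R")
  out <- place_repeats(list(scaf), g, link_params(k = 3))
  expect_equal(out$placed, "R")
  p <- out$scaffolds[[1]]$parts
  expect_equal(p$contig_id, c("X", "R", "Y"))
  expect_equal(p$gap_est[1:2], c(40, 60))

  # insufficient path support: not placed
  g2 <- mk_graph(paths = list(p = mk_path(c("X", "R", "Y"),
                                          c("F", "F", "F"), c(40, 60),
                                          n = 2)), flags = "R")
  out <- place_repeats(list(scaf), g2, link_params(k = 3))
  expect_length(out$placed, 0)

  # two distinct repeats with equal support: neither placed, with a warning
  g3 <- mk_graph(paths = list(
    p1 = mk_path(c("X", "R1", "Y"), c("F", "F", "F"), c(40, 60), n = 3),
    p2 = mk_path(c("X", "R2", "Y"), c("F", "F", "F"), c(40, 60), n = 3)),
    flags = c("R1", "R2"))
  expect_warning(out <- place_repeats(list(scaf), g3, link_params(k = 3)),
                 "conflicting repeat")
  expect_length(out$placed, 0)

  # one repeat serving two junctions is placed twice
  scaf2 <- list(mk_scaffold(c("X", "Y"), c("+", "+"), gap_est = 2100),
                mk_scaffold(c("P", "Q"), c("+", "+"), gap_est = 2100))
  g4 <- mk_graph(paths = list(
    p1 = mk_path(c("X", "R", "Y"), c("F", "F", "F"), c(40, 60), n = 4),
    p2 = mk_path(c("P", "R", "Q"), c("F", "F", "F"), c(10, 20), n = 5)),
    flags = "R")
  out <- place_repeats(scaf2, g4, link_params(k = 3))
  expect_equal(out$placed, "R")
  expect_equal(out$scaffolds[[1]]$parts$contig_id, c("X", "R", "Y"))
  expect_equal(out$scaffolds[[2]]$parts$contig_id, c("P", "R", "Q"))
})

test_that("edge repeats are stripped iteratively and conserved", {
  s <- mk_scaffold(c("R1", "A", "B", "R2"), rep("+", 4))
  tr <- trim_edge_repeats(list(s), c("R1", "R2"))
  expect_equal(tr$scaffolds[[1]]$parts$contig_id, c("A", "B"))
  expect_setequal(tr$stripped, c("R1", "R2"))

  s <- mk_scaffold(c("R1", "R2", "A"), rep("+", 3))
  tr <- trim_edge_repeats(list(s), c("R1", "R2"))
  expect_equal(tr$scaffolds[[1]]$parts$contig_id, "A")

  s <- mk_scaffold(c("R1", "R2"), rep("+", 2))
  tr <- trim_edge_repeats(list(s), c("R1", "R2"))
  expect_length(tr$scaffolds, 0)
  expect_setequal(tr$stripped, c("R1", "R2"))
})

test_that("preliminary scaffolds rejoin through terminal links", {
  sA <- mk_scaffold(c("A", "B"), c("+", "+"), gap_est = 10, support = 5L)
  sB <- mk_scaffold(c("C", "D"), c("+", "+"), gap_est = 10, support = 5L)
  g <- mk_graph(mk_links(mk_link("B", "tail", "C", "head", 3,
                                 gaps = c(30, 31, 32))))
  out <- rejoin_scaffolds(list(sA, sB), g, link_params(k = 3))
  expect_length(out, 1)
  expect_equal(out[[1]]$parts$contig_id, c("A", "B", "C", "D"))
  expect_equal(out[[1]]$parts$gap_est[2], 31)

  # support below k joins nothing
  g2 <- mk_graph(mk_links(mk_link("B", "tail", "C", "head", 2)))
  out <- rejoin_scaffolds(list(sA, sB), g2, link_params(k = 3))
  expect_length(out, 2)

  # a link to an internal (non-terminal) end joins nothing
  g3 <- mk_graph(mk_links(mk_link("A", "tail", "C", "head", 5)))
  out <- rejoin_scaffolds(list(sA, sB), g3, link_params(k = 3))
  expect_length(out, 2)
})

test_that("junctions resolve to gaps or verified merges", {
  mp <- merge_params()
  j <- resolve_junction(120)
  expect_equal(j[c("kind", "gap_len")], list(kind = "gap", gap_len = 120L))

  # exact 4-mer suffix/prefix overlap within the band
  j <- resolve_junction(-20, "ACGTACGT", "ACGTTTTT", mp)
  expect_equal(j$kind, "merge")
  expect_equal(j$overlap_len, 4L)

  # brute-force scan oracle over a random merge case
  set.seed(13)
  a <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  b_ov <- substr(a, 371, 400)  # true 30 bp overlap
  b <- paste0(b_ov, paste(sample(c("A", "C", "G", "T"), 300,
                                 replace = TRUE), collapse = ""))
  brute <- function(a, b, est, band, minid) {
    best <- NA; bestd <- Inf
    for (o in max(1, abs(est) - band):min(abs(est) + band,
                                          min(nchar(a), nchar(b)) - 1)) {
      sa <- strsplit(substr(a, nchar(a) - o + 1, nchar(a)), "")[[1]]
      pb <- strsplit(substr(b, 1, o), "")[[1]]
      if (mean(sa == pb) >= minid && abs(o - abs(est)) < bestd) {
        best <- o; bestd <- abs(o - abs(est))
      }
    }
    best
  }
  j <- resolve_junction(-27, a, b, mp)
  expect_equal(j$kind, "merge")
  expect_equal(j$overlap_len, brute(a, b, -27, mp$merge_band,
                                    mp$merge_min_identity))
  expect_equal(j$overlap_len, 30L)

  # no qualifying overlap: fall back to a 1 N gap
  j <- resolve_junction(-50, strrep("A", 200), strrep("C", 200), mp)
  expect_equal(j[c("kind", "gap_len")], list(kind = "gap", gap_len = 1L))

  # without sequences a negative estimate still yields the minimal gap
  j <- resolve_junction(-50, NULL, NULL, mp)
  expect_equal(j$kind, "gap")
})

test_that("contig conservation and length bookkeeping hold end to end", {
  qs <- quick_sim(4, genome_len = 150000, n_contigs = 15)
  res <- suppressMessages(run_scaffold(alignments = qs$aln, outdir = NULL))
  seen <- unlist(lapply(res$scaffolds, function(s) s$parts$contig_id))
  expect_setequal(seen, unique(qs$sim$layout$contig_id))
  expect_false(any(duplicated(seen[!seen %in% res$repeat_flags])))

  # emitted length == sum(contigs) + sum(gaps) - sum(overlaps)
  seqs <- qs$sim$contigs
  for (s in res$scaffolds) {
    lens <- nchar(seqs[s$parts$contig_id])
    gaps <- s$parts$gap_len[!is.na(s$parts$gap_len)]
    ovs <- s$parts$overlap_len[!is.na(s$parts$overlap_len)]
    closing <- if (isTRUE(s$circular) && identical(s$circ_kind, "merge"))
      s$circ_overlap else 0L
    expect_equal(nchar(longscaff:::scaffold_sequence(s, seqs)),
                 sum(lens) + sum(gaps) - sum(ovs) - closing)
    expect_equal(s$length, sum(lens) + sum(gaps) - sum(ovs) - closing)
  }
})

test_that("a circular replicon is flagged but emitted linear", {
  cfg <- sim_config(genome_len = 80000, n_contigs = 8, coverage = 20,
                    read_len_mean = 3000, read_len_sigma = 0,
                    error_rate = 0, circular = TRUE, seed = 3)
  sim <- suppressMessages(run_simulate(cfg, reads = FALSE))
  aln <- simulate_placements(sim$layout, cfg)
  res <- suppressMessages(run_scaffold(alignments = aln, outdir = NULL))
  expect_length(res$scaffolds, 1)
  expect_true(res$scaffolds[[1]]$circular)
  ev <- evaluate_scaffolds(res$scaffolds, sim$layout, circular = TRUE)
  expect_equal(ev$misjoins, 0)
  expect_equal(ev$missed_joins, 0)

  # a linear genome never gains the flag
  qs <- quick_sim(6, genome_len = 80000, n_contigs = 8)
  res <- suppressMessages(run_scaffold(alignments = qs$aln, outdir = NULL))
  expect_false(any(vapply(res$scaffolds, function(s) isTRUE(s$circular),
                          logical(1))))
})
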