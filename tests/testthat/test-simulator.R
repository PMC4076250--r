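test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(genome_len = 30000, n_contigs = 5, coverage = 5,
                    read_len_mean = 1500, seed = 17)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  r1 <- simulate_reads(g1$genome, cfg)
  r2 <- simulate_reads(g1$genome, cfg)
  expect_identical(r1, r2)
  p1 <- simulate_placements(fragment_contigs(g1$genome, g1$repeats,
                                             cfg)$layout, cfg)
  p2 <- simulate_placements(fragment_contigs(g2$genome, g2$repeats,
                                             cfg)$layout, cfg)
  expect_identical(p1, p2)
})

test_that("planted repeat copies are near-identical and annotated", {
  cfg <- sim_config(genome_len = 60000, repeat_families = list(c(2000, 2)),
                    seed = 8)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$repeats), 2)
  c1 <- substr(g$genome, g$repeats$start[1], g$repeats$end[1])
  c2 <- substr(g$genome, g$repeats$start[2], g$repeats$end[2])
  ident <- mean(strsplit(c1, "")[[1]] == strsplit(c2, "")[[1]])
  expect_gte(ident, 0.97)
  expect_lt(ident, 1)  # copies diverge, they are not exact duplicates

  # no families: no annotation
  g0 <- simulate_genome(sim_config(genome_len = 20000, seed = 8))
  expect_equal(nrow(g0$repeats), 0)

  # impossible placement is an error
  expect_error(simulate_genome(sim_config(
    genome_len = 15000, repeat_families = list(c(4000, 3)), seed = 1)),
    "fit")
})

test_that("repeat-aware fragmentation emits one shared repeat contig", {
  cfg <- sim_config(genome_len = 80000, repeat_families = list(c(2000, 2)),
                    break_at_repeats = TRUE, seed = 12)
  g <- simulate_genome(cfg)
  fr <- fragment_contigs(g$genome, g$repeats, cfg)
  expect_equal(sum(fr$layout$contig_id == "repeat_1"), 2)
  expect_equal(sum(names(fr$contigs) == "repeat_1"), 1)
  expect_equal(unique(fr$layout$multiplicity[
    fr$layout$contig_id == "repeat_1"]), 2L)
  # unique flanks: 3 segments around 2 repeat copies
  expect_equal(sum(fr$layout$multiplicity == 1L), 3)
  # layout tiles the genome: contig intervals are disjoint and ordered
  expect_true(all(diff(fr$layout$start) > 0))
  expect_true(all(fr$layout$start[-1] > fr$layout$end[-nrow(fr$layout)]))
  # contig sequences match their genome intervals
  first <- fr$layout[!duplicated(fr$layout$contig_id), ]
  for (i in seq_len(nrow(first))) {
    expect_equal(fr$contigs[[first$contig_id[i]]],
                 substr(g$genome, first$start[i], first$end[i]))
  }
})

test_that("a zero gap range makes contigs abut exactly", {
  cfg <- sim_config(genome_len = 40000, n_contigs = 6, gap_range = c(0, 0),
                    seed = 2)
  g <- simulate_genome(cfg)
  fr <- fragment_contigs(g$genome, g$repeats, cfg)
  expect_true(all(fr$layout$gap_after[-nrow(fr$layout)] == 0))
})

test_that("read count follows coverage arithmetic; lengths are truncated", {
  cfg <- sim_config(genome_len = 100000, coverage = 20,
                    read_len_mean = 2500, seed = 4)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(g$genome, cfg)
  expect_length(rd, round(20 * 100000 / 2500))  # fixed before sampling
  expect_true(all(nchar(rd) >= 250))  # 300 minus deletion shrinkage
})

test_that("noise-free reads are exact substrings of the genome", {
  cfg <- sim_config(genome_len = 20000, n_contigs = 4, coverage = 3,
                    read_len_mean = 1500, error_rate = 0, seed = 9)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(g$genome, cfg)
  iv <- attr(rd, "intervals")
  for (i in seq_len(min(20, length(rd)))) {
    src <- substr(g$genome, iv$start[i], iv$start[i] + iv$len[i] - 1)
    if (iv$strand[i] == "-") src <- revcomp(src)
    expect_identical(rd[[i]], src)
  }
})

test_that("the realized per-base error rate matches the configured 15%", {
  cfg <- sim_config(genome_len = 60000, coverage = 3, read_len_mean = 1200,
                    read_len_sigma = 0, error_rate = 0.15, seed = 14)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(g$genome, cfg)
  iv <- attr(rd, "intervals")
  n <- min(120, length(rd))
  rate <- vapply(seq_len(n), function(i) {
    src <- substr(g$genome, iv$start[i], iv$start[i] + iv$len[i] - 1)
    if (iv$strand[i] == "-") src <- revcomp(src)
    utils::adist(rd[[i]], src) / nchar(src)
  }, numeric(1))
  expect_gte(mean(rate), 0.13)
  expect_lte(mean(rate), 0.17)
})

test_that("ideal placements carry valid coordinates and strand symmetry", {
  cfg <- sim_config(genome_len = 50000, n_contigs = 6, coverage = 10,
                    read_len_mean = 2000, error_rate = 0.15, seed = 6)
  sim <- suppressMessages(run_simulate(cfg, reads = FALSE))
  aln <- simulate_placements(sim$layout, cfg)
  expect_true(all(aln$read_start >= 0 & aln$read_start < aln$read_end &
                    aln$read_end <= aln$read_len))
  expect_true(all(aln$contig_start >= 0 &
                    aln$contig_start < aln$contig_end &
                    aln$contig_end <= aln$contig_len))
  expect_true(all(aln$strand %in% c("+", "-")))
  expect_gt(sum(aln$strand == "-"), 0)
  # a multi-contig read lists its contigs in consistent genomic order
  p <- collect_placements(aln)
  rp <- build_read_paths(p)
  g <- derive_links(rp)
  truth_pairs <- paste(sim$layout$contig_id[-nrow(sim$layout)],
                       sim$layout$contig_id[-1])
  for (i in seq_len(nrow(g$links))) {
    pair_fwd <- paste(g$links$a_id[i], g$links$b_id[i])
    pair_rev <- paste(g$links$b_id[i], g$links$a_id[i])
    expect_true(pair_fwd %in% truth_pairs || pair_rev %in% truth_pairs)
  }
})

test_that("the evaluator applies the join/misjoin definitions", {
  layout <- data.frame(contig_id = c("A", "B", "C"), orientation = "+",
                       start = c(1, 1001, 2001), end = c(900, 1900, 2900),
                       gap_after = c(100, 100, NA), multiplicity = 1L,
                       stringsAsFactors = FALSE)
  perfect <- mk_scaffold(c("A", "B", "C"), rep("+", 3),
                         gap_est = c(100, 100))
  ev <- evaluate_scaffolds(list(perfect), layout)
  expect_equal(ev$correct_joins, 2)
  expect_equal(ev$misjoins, 0)
  expect_equal(ev$gap_errors, c(0, 0))

  # the reverse-complement reading of the truth is equally correct
  flipped <- mk_scaffold(c("C", "B", "A"), rep("-", 3),
                         gap_est = c(100, 100))
  ev <- evaluate_scaffolds(list(flipped), layout)
  expect_equal(ev$correct_joins, 2)
  expect_equal(ev$misjoins, 0)

  # scrambled order contradicts the truth
  wrong <- mk_scaffold(c("A", "C", "B"), rep("+", 3), gap_est = c(1, 1))
  ev <- evaluate_scaffolds(list(wrong), layout)
  expect_gte(ev$misjoins, 1)

  # unknown contigs are rejected
  alien <- mk_scaffold("Z", "+")
  expect_error(evaluate_scaffolds(list(alien), layout), "unknown")
})
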