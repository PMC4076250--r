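test_that("read paths are ordered by aligned position on the read", {
  p <- mk_placements(c(500, 100, 900), c(600, 200, 1000), c(1, 2, 3))
  rp <- build_read_paths(p)
  expect_equal(rp$aln_read_start, c(100, 500, 900))
  # reverse-strand placements keep their position, only the strand differs
  p$strand[p$aln_read_start == 500] <- "R"
  rp <- build_read_paths(p)
  expect_equal(rp$strand[rp$aln_read_start == 500], "R")
})

test_that("consecutive placements yield orientation-aware links with gaps", {
  # A(F) ext [0,100) then B(F) ext [150,250): A.tail--B.head, gap +50
  p <- data.frame(read_id = "r1", contig_id = c("A", "B"),
                  strand = c("F", "F"),
                  aln_read_start = c(10, 160), aln_read_end = c(90, 240),
                  ext_read_start = c(0, 150), ext_read_end = c(100, 250),
                  score = c(80, 80), identity = 0.9,
                  stringsAsFactors = FALSE)
  g <- derive_links(build_read_paths(p))
  expect_equal(nrow(g$links), 1)
  expect_equal(g$links$key, "A:tail|B:head")
  expect_equal(g$links$gaps[[1]], 50)

  # A(F) then B(R) joins A.tail to B.tail
  p$strand[2] <- "R"
  g <- derive_links(build_read_paths(p))
  expect_equal(g$links$key, "A:tail|B:tail")

  # two reads supporting one junction aggregate their estimates
  p2 <- rbind(
    within(p, { strand <- c("F", "F"); ext_read_start <- c(0, 148)
                ext_read_end <- c(100, 250) }),
    within(p, { read_id <- "r2"; strand <- c("F", "F")
                ext_read_start <- c(0, 152); ext_read_end <- c(100, 250) }))
  g <- derive_links(build_read_paths(p2))
  expect_equal(g$links$support, 2)
  expect_setequal(g$links$gaps[[1]], c(48, 52))
})

test_that("a junction read in either strand produces the same canonical key", {
  set.seed(21)
  for (i in 1:40) {
    sA <- sample(c("F", "R"), 1); sB <- sample(c("F", "R"), 1)
    fwd <- data.frame(read_id = "f", contig_id = c("A", "B"),
                      strand = c(sA, sB),
                      aln_read_start = c(0, 200), aln_read_end = c(100, 300),
                      ext_read_start = c(0, 180), ext_read_end = c(120, 300),
                      score = 100, identity = 0.9, stringsAsFactors = FALSE)
    # the same physical junction observed from the opposite read strand:
    # order reversed, strands flipped
    rev_ <- fwd[2:1, ]
    rev_$read_id <- "r"
    rev_$strand <- ifelse(rev_$strand == "F", "R", "F")
    rev_$aln_read_start <- c(0, 200); rev_$aln_read_end <- c(100, 300)
    rev_$ext_read_start <- c(0, 180); rev_$ext_read_end <- c(120, 300)
    g <- derive_links(build_read_paths(rbind(fwd, rev_)))
    expect_equal(nrow(g$links), 1)
    expect_equal(g$links$support, 2)
  }
})

test_that("transitive links are removed per the path-containment rule", {
  # with path A>B>C>D stored, the direct A--C shortcut is dropped
  links <- mk_links(mk_link("A", "tail", "B", "head", 3),
                    mk_link("B", "tail", "C", "head", 3),
                    mk_link("C", "tail", "D", "head", 3),
                    mk_link("A", "tail", "C", "head", 3))
  paths <- list(p1 = mk_path(c("A", "B", "C", "D"), c("F", "F", "F", "F"),
                             c(10, 10, 10), n = 3))
  g <- remove_transitive_links(mk_graph(links, paths))
  expect_equal(sort(g$links$key),
               sort(c("A:tail|B:head", "B:tail|C:head", "C:tail|D:head")))

  # no multi-contig paths: graph unchanged
  g0 <- remove_transitive_links(mk_graph(links))
  expect_equal(nrow(g0$links), 4)

  # the shortcut is removed even when the intermediate direct links are absent
  g1 <- remove_transitive_links(mk_graph(
    mk_links(mk_link("A", "tail", "C", "head", 3)),
    list(p = mk_path(c("A", "B", "C"), c("F", "F", "F"), c(5, 5)))))
  expect_equal(nrow(g1$links), 0)
})

test_that("ambiguous ends resolve by ratio, paths, or repeat flagging", {
  k3 <- link_params(k = 3, ratio = 0.7)
  # clear winner: 2/10 <= 0.7
  res <- resolve_ambiguities(mk_graph(mk_links(
    mk_link("A", "tail", "B", "head", 10),
    mk_link("A", "tail", "C", "head", 2),
    mk_link("B", "tail", "D", "head", 5))), link_params(k = 1, ratio = 0.7))
  expect_true("A:tail|B:head" %in% res$accepted$key)
  expect_false("A:tail|C:head" %in% res$accepted$key)
  expect_length(res$repeat_flags, 0)

  # balanced candidates with no disambiguating paths: owner is flagged
  res <- resolve_ambiguities(mk_graph(mk_links(
    mk_link("R", "head", "U1", "tail", 5),
    mk_link("R", "head", "U3", "tail", 5))), k3)
  expect_equal(nrow(res$accepted), 0)
  expect_equal(res$repeat_flags, "R")

  # balanced candidates solved by a stored path through the end
  res <- resolve_ambiguities(mk_graph(
    mk_links(mk_link("A", "tail", "B", "head", 5),
             mk_link("A", "tail", "C", "head", 5)),
    list(p = mk_path(c("Z", "A", "B"), c("F", "F", "F"), c(5, 5), n = 2))),
    k3)
  expect_equal(res$accepted$key, "A:tail|B:head")
  expect_length(res$repeat_flags, 0)

  # support below k is discarded before resolution; boundary k is kept
  res <- resolve_ambiguities(mk_graph(mk_links(
    mk_link("A", "tail", "B", "head", 3),
    mk_link("C", "tail", "D", "head", 2))), k3)
  expect_equal(res$accepted$key, "A:tail|B:head")
})

test_that("gap estimates use the outlier-robust lower median", {
  expect_equal(estimate_gap(c(48, 52, 50)), 50)
  expect_equal(estimate_gap(-30), -30)
  expect_equal(estimate_gap(c(10, 20, 30, 1000)), 20)
})

test_that("linkage recovers all true adjacencies on clean simulations", {
  for (seed in c(2, 9)) {
    qs <- quick_sim(seed, genome_len = 120000, n_contigs = 12)
    placements <- collect_placements(qs$aln)
    lk <- build_linkage(placements)
    truth_keys <- with(qs$sim$layout, {
      n <- length(contig_id)
      longscaff:::link_key(contig_id[-n], rep("tail", n - 1),
                           contig_id[-1], rep("head", n - 1))
    })
    canon_truth <- vapply(seq_along(truth_keys), function(i) {
      l <- qs$sim$layout
      cl <- longscaff:::canon_link(l$contig_id[i], "tail",
                                   l$contig_id[i + 1], "head")
      longscaff:::link_key(cl$a_id, cl$a_end, cl$b_id, cl$b_end)
    }, character(1))
    expect_setequal(lk$accepted$key, canon_truth)
    # noise-free gap estimates are exact
    est <- vapply(lk$accepted$gaps, estimate_gap, numeric(1))
    truth_gap <- qs$sim$layout$gap_after[
      match(lk$accepted$key, canon_truth)]
    expect_equal(est, as.numeric(truth_gap))
  }
})
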