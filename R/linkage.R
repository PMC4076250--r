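#' Linkage parameters
#'
#' @param k minimum number of supporting reads for a link (`-k`).
#' @param ratio support ratio between the two best alternative links at a
#'   contig end below which the best is accepted outright (`-r`).
#' @return a `link_params` list.
#' @export
link_params <- function(k = 3, ratio = 0.7) {
  stopifnot(k >= 1, ratio > 0, ratio <= 1)
  structure(list(k = k, ratio = ratio), class = "link_params")
}

# read-facing ends of a consecutive placement pair: on the forward strand a
# contig exposes its tail downstream along the read and its head upstream
downstream_end <- function(strand) ifelse(strand == "F", "tail", "head")
upstream_end <- function(strand) ifelse(strand == "F", "head", "tail")
flip_strand <- function(strand) ifelse(strand == "F", "R", "F")
other_end <- function(end) ifelse(end == "head", "tail", "head")

# canonical undirected key for a link between two oriented contig ends
canon_link <- function(a_id, a_end, b_id, b_end) {
  swap <- (b_id < a_id) | (b_id == a_id & b_end < a_end)
  data.frame(
    a_id = ifelse(swap, b_id, a_id), a_end = ifelse(swap, b_end, a_end),
    b_id = ifelse(swap, a_id, b_id), b_end = ifelse(swap, a_end, b_end),
    stringsAsFactors = FALSE
  )
}

link_key <- function(a_id, a_end, b_id, b_end) {
  paste0(a_id, ":", a_end, "|", b_id, ":", b_end)
}

#' Order placements into per-read paths
#'
#' Sorts surviving placements by their aligned start position on each read
#' (ties by contig id), yielding the ordered, oriented sequence of contig
#' placements every read induces.
#'
#' @param placements placement data.frame from [collect_placements()].
#' @return the same data.frame sorted by `(read_id, aln_read_start,
#'   contig_id)`, with class `read_paths`.
#' @export
build_read_paths <- function(placements) {
  p <- placements[order(placements$read_id, placements$aln_read_start,
                        placements$contig_id), , drop = FALSE]
  rownames(p) <- NULL
  class(p) <- c("read_paths", class(p))
  p
}

# canonical representation of one multi-contig path: the lexicographically
# smaller of the forward reading and the reverse-complement reading
canon_path <- function(cids, strands, gaps) {
  fwd <- paste(paste0(cids, ":", strands), collapse = ">")
  rcids <- rev(cids)
  rstrands <- flip_strand(rev(strands))
  rev_repr <- paste(paste0(rcids, ":", rstrands), collapse = ">")
  if (rev_repr < fwd) {
    list(key = rev_repr, cids = rcids, strands = rstrands, gaps = rev(gaps))
  } else {
    list(key = fwd, cids = cids, strands = strands, gaps = gaps)
  }
}

#' Derive the contig-linkage graph from per-read placement order
#'
#' Every pair of consecutive placements (A, B) on a read records a link
#' between the downstream-facing end of A and the upstream-facing end of B,
#' with a signed gap estimate `B$ext_read_start - A$ext_read_end` (negative
#' values imply overlap). Every read path with >= 3 steps additionally
#' stores its full oriented contig tuple and every contiguous sub-tuple of
#' length >= 3 in the multi-contig path store, which later drives transitive
#' reduction, ambiguity resolution and repeat placement.
#'
#' @param read_paths sorted placements from [build_read_paths()].
#' @return a `linkage_graph`: `list(links, paths, repeat_flags)` where
#'   `links` is a data.frame (`key, a_id, a_end, b_id, b_end, support`) with
#'   a list-column `gaps`, and `paths` maps canonical tuple keys to
#'   `list(cids, strands, n, gaps)` (`gaps`: one row per supporting read).
#' @export
derive_links <- function(read_paths) {
  p <- read_paths
  n <- nrow(p)
  links <- empty_links()
  paths <- list()
  if (n >= 2L) {
    i <- which(p$read_id[-n] == p$read_id[-1L])
    if (length(i) > 0L) {
      j <- i + 1L
      cl <- canon_link(p$contig_id[i], downstream_end(p$strand[i]),
                       p$contig_id[j], upstream_end(p$strand[j]))
      cl$key <- link_key(cl$a_id, cl$a_end, cl$b_id, cl$b_end)
      cl$gap <- p$ext_read_start[j] - p$ext_read_end[i]
      gaps <- split(cl$gap, cl$key)
      first <- cl[!duplicated(cl$key), , drop = FALSE]
      first <- first[order(first$key), , drop = FALSE]
      links <- data.frame(key = first$key, a_id = first$a_id,
                          a_end = first$a_end, b_id = first$b_id,
                          b_end = first$b_end,
                          support = lengths(gaps)[first$key],
                          stringsAsFactors = FALSE)
      links$gaps <- unname(gaps[first$key])
      rownames(links) <- NULL
    }
  }
  # multi-contig path store
  counts <- table(p$read_id)
  multi <- names(counts)[counts >= 3L]
  if (length(multi) > 0L) {
    idx <- split(seq_len(n), p$read_id)[multi]
    store <- new.env(parent = emptyenv())
    for (ii in idx) {
      if (is.null(ii) || length(ii) < 3L) next
      cids <- p$contig_id[ii]
      strands <- p$strand[ii]
      gaps <- p$ext_read_start[ii][-1L] - p$ext_read_end[ii][-length(ii)]
      m <- length(ii)
      for (w in 3:m) {
        for (s0 in seq_len(m - w + 1L)) {
          sl <- s0:(s0 + w - 1L)
          cp <- canon_path(cids[sl], strands[sl], gaps[sl[-w]])
          cur <- store[[cp$key]]
          if (is.null(cur)) {
            store[[cp$key]] <- list(cids = cp$cids, strands = cp$strands,
                                    n = 1L, gaps = matrix(cp$gaps, nrow = 1L))
          } else {
            cur$n <- cur$n + 1L
            cur$gaps <- rbind(cur$gaps, cp$gaps)
            store[[cp$key]] <- cur
          }
        }
      }
    }
    paths <- as.list(store)
    paths <- paths[order(names(paths))]
  }
  structure(list(links = links, paths = paths, repeat_flags = character(0)),
            class = "linkage_graph")
}

empty_links <- function() {
  out <- data.frame(key = character(0), a_id = character(0),
                    a_end = character(0), b_id = character(0),
                    b_end = character(0), support = integer(0),
                    stringsAsFactors = FALSE)
  out$gaps <- list()
  out
}

#' @export
print.linkage_graph <- function(x, ...) {
  cat(sprintf("linkage_graph: %d links, %d multi-contig paths, %d repeat flags\n",
              nrow(x$links), length(x$paths), length(x$repeat_flags)))
  invisible(x)
}

# canonical keys of all contig pairs implied at step distance >= min_dist
# within the stored multi-contig paths
implied_pair_keys <- function(paths, min_dist = 2L) {
  keys <- lapply(paths, function(pp) {
    m <- length(pp$cids)
    out <- character(0)
    for (i in seq_len(m)) {
      js <- seq_len(m)
      js <- js[js >= i + min_dist]
      for (j in js) {
        cl <- canon_link(pp$cids[i], downstream_end(pp$strands[i]),
                         pp$cids[j], upstream_end(pp$strands[j]))
        out <- c(out, link_key(cl$a_id, cl$a_end, cl$b_id, cl$b_end))
      }
    }
    out
  })
  unique(unlist(keys, use.names = FALSE))
}

#' Remove transitive links shortcutting observed multi-contig paths
#'
#' A direct link X--Y is deleted when some stored multi-contig path contains
#' X and Y in the same relative orientation with at least one intervening
#' contig (e.g. with paths A>B>C>D, the direct A--C link is removed).
#' Deletions are computed against the original graph simultaneously, not
#' cascaded.
#'
#' @param graph a `linkage_graph`.
#' @return the graph with transitive links removed.
#' @export
remove_transitive_links <- function(graph) {
  if (length(graph$paths) == 0L || nrow(graph$links) == 0L) return(graph)
  shortcut <- implied_pair_keys(graph$paths, min_dist = 2L)
  graph$links <- graph$links[!(graph$links$key %in% shortcut), , drop = FALSE]
  rownames(graph$links) <- NULL
  graph
}

# canonical keys of adjacent pairs inside stored paths (distance exactly 1)
adjacent_pair_keys <- function(paths) {
  keys <- lapply(paths, function(pp) {
    m <- length(pp$cids)
    i <- seq_len(m - 1L)
    cl <- canon_link(pp$cids[i], downstream_end(pp$strands[i]),
                     pp$cids[i + 1L], upstream_end(pp$strands[i + 1L]))
    link_key(cl$a_id, cl$a_end, cl$b_id, cl$b_end)
  })
  unique(unlist(keys, use.names = FALSE))
}

#' Resolve ambiguous contig ends and flag repeats
#'
#' Links with support below `k` are discarded first. A contig end with a
#' single surviving candidate accepts it outright. For an end with several
#' candidates, the candidates are ranked by support; if the ratio of the
#' second-best to the best support is at most `ratio` the best is accepted.
#' Otherwise the multi-contig path store is consulted: if exactly one
#' candidate also occurs as an adjacent pair inside a stored path through
#' this end, that candidate is accepted; if not, no candidate is accepted
#' and the contig owning the conflicted end -- the shared neighbor of the
#' conflicting partners, i.e. the repeated element -- is flagged. A link is
#' finally accepted only when it is accepted from both of its ends.
#'
#' @param graph a transitively reduced `linkage_graph`.
#' @param params a [link_params()] list.
#' @return `list(accepted, repeat_flags)`: the accepted links data.frame and
#'   the character vector of repeat-flagged contig ids.
#' @export
resolve_ambiguities <- function(graph, params = link_params()) {
  links <- graph$links
  links <- links[links$support >= params$k, , drop = FALSE]
  if (nrow(links) == 0L) {
    return(list(accepted = empty_links(), repeat_flags = character(0)))
  }
  rownames(links) <- NULL
  ends <- rbind(
    data.frame(end = paste0(links$a_id, ":", links$a_end),
               owner = links$a_id, li = seq_len(nrow(links)),
               stringsAsFactors = FALSE),
    data.frame(end = paste0(links$b_id, ":", links$b_end),
               owner = links$b_id, li = seq_len(nrow(links)),
               stringsAsFactors = FALSE)
  )
  path_adj <- adjacent_pair_keys(graph$paths)
  votes <- integer(nrow(links))
  flags <- character(0)
  for (grp in split(seq_len(nrow(ends)), ends$end)) {
    lis <- ends$li[grp]
    if (length(lis) == 1L) {
      votes[lis] <- votes[lis] + 1L
      next
    }
    sup <- links$support[lis]
    ord <- order(-sup, links$key[lis])
    lis <- lis[ord]; sup <- sup[ord]
    if (sup[2L] / sup[1L] <= params$ratio) {
      votes[lis[1L]] <- votes[lis[1L]] + 1L
    } else {
      consistent <- lis[links$key[lis] %in% path_adj]
      if (length(consistent) == 1L) {
        votes[consistent] <- votes[consistent] + 1L
      } else {
        flags <- c(flags, ends$owner[grp][1L])
      }
    }
  }
  accepted <- links[votes == 2L, , drop = FALSE]
  rownames(accepted) <- NULL
  list(accepted = accepted, repeat_flags = sort(unique(flags)))
}

#' Point estimate of a link's gap size
#'
#' The lower median of the per-read signed gap estimates (for even support,
#' the lower of the two central values), robust to a single outlying read.
#' Negative values are legal and signal an overlap between the contigs.
#'
#' @param gaps numeric vector of per-read signed gap estimates.
#' @return a single number.
#' @export
estimate_gap <- function(gaps) {
  stopifnot(length(gaps) >= 1L)
  lower_median(gaps)
}

#' Build the full linkage graph with iterative repeat handling
#'
#' Runs link derivation, transitive reduction and ambiguity resolution, then
#' iterates: placements of repeat-flagged contigs are removed from the read
#' paths and links are re-derived, so that the flanking contigs of a repeat
#' become directly adjacent (their gap estimates then span the repeat
#' copy). Iteration stops when the flag set reaches a fixed point.
#'
#' @param placements placement data.frame from [collect_placements()].
#' @param params a [link_params()] list.
#' @return `list(accepted, repeat_flags, graph, graph_full)`: accepted
#'   links among non-repeat contigs, the flag set, the final-pass graph and
#'   the first-pass graph (whose path store retains the repeat tuples used
#'   later for repeat placement).
#' @export
build_linkage <- function(placements, params = link_params()) {
  paths0 <- build_read_paths(placements)
  flags <- character(0)
  graph_full <- NULL
  for (pass in 1:10) {
    pp <- paths0[!(paths0$contig_id %in% flags), , drop = FALSE]
    graph <- derive_links(pp)
    if (is.null(graph_full)) graph_full <- graph
    graph <- remove_transitive_links(graph)
    res <- resolve_ambiguities(graph, params)
    new_flags <- setdiff(res$repeat_flags, flags)
    if (length(new_flags) == 0L) break
    flags <- sort(union(flags, new_flags))
  }
  graph$repeat_flags <- flags
  graph_full$repeat_flags <- flags
  list(accepted = res$accepted, repeat_flags = flags,
       graph = graph, graph_full = graph_full)
}

#' Dump a linkage graph's links as TSV
#'
#' Debug output with one row per link: `a_contig, a_end, b_contig, b_end,
#' support, median_gap`.
#'
#' @param links links data.frame (e.g. `graph$links` or accepted links).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_linkage_tsv <- function(links, path) {
  df <- data.frame(a_contig = links$a_id, a_end = links$a_end,
                   b_contig = links$b_id, b_end = links$b_end,
                   support = links$support,
                   median_gap = vapply(links$gaps, estimate_gap, numeric(1)),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("a_contig\ta_end\tb_contig\tb_end\tsupport\tmedian_gap", con)
  if (nrow(df) > 0L) {
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
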