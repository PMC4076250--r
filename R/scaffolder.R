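#' Merge parameters for junction resolution
#'
#' @param merge_min_identity minimum identity for a suffix/prefix overlap to
#'   merge two contigs.
#' @param merge_band slack (bp) around the estimated overlap length when
#'   searching for the merge overlap; absorbs long-read gap-estimate noise.
#' @param min_gap_n gap length (N bases) emitted when a negative gap
#'   estimate cannot be verified as an overlap.
#' @return a `merge_params` list.
#' @export
merge_params <- function(merge_min_identity = 0.85, merge_band = 100,
                         min_gap_n = 1) {
  stopifnot(merge_min_identity > 0, merge_min_identity <= 1,
            merge_band >= 0, min_gap_n >= 1)
  structure(list(merge_min_identity = merge_min_identity,
                 merge_band = merge_band, min_gap_n = min_gap_n),
            class = "merge_params")
}

new_scaffold <- function(parts, circular = FALSE) {
  list(id = NA_character_, parts = parts, circular = circular,
       circ_kind = NA_character_, circ_overlap = 0L,
       circ_gap_est = NA_real_, circ_support = NA_integer_)
}

empty_parts <- function() {
  data.frame(contig_id = character(0), orientation = character(0),
             gap_est = numeric(0), support = integer(0),
             j_kind = character(0), gap_len = integer(0),
             overlap_len = integer(0), stringsAsFactors = FALSE)
}

part_row <- function(cid, orient) {
  data.frame(contig_id = cid, orientation = orient, gap_est = NA_real_,
             support = NA_integer_, j_kind = NA_character_,
             gap_len = NA_integer_, overlap_len = NA_integer_,
             stringsAsFactors = FALSE)
}

# end-keyed adjacency of accepted links; errors if any end is used twice
build_end_map <- function(links) {
  map <- new.env(parent = emptyenv())
  add <- function(from, to, li) {
    if (!is.null(map[[from]])) {
      stop("internal error: contig end ", from, " has 2 accepted links")
    }
    map[[from]] <- list(partner = to, li = li)
  }
  for (li in seq_len(nrow(links))) {
    a <- paste0(links$a_id[li], ":", links$a_end[li])
    b <- paste0(links$b_id[li], ":", links$b_end[li])
    add(a, b, li)
    add(b, a, li)
  }
  map
}

split_end_key <- function(key) {
  i <- regexpr(":[^:]*$", key)
  list(cid = substr(key, 1L, i - 1L), end = substring(key, i + 1L))
}

# walk a chain starting from a free (unlinked) oriented contig end
walk_chain <- function(start_key, map, links) {
  se <- split_end_key(start_key)
  cid <- se$cid
  entered <- se$end
  parts <- part_row(cid, if (entered == "head") "+" else "-")
  seen <- cid
  repeat {
    exit_key <- paste0(cid, ":", other_end(entered))
    hit <- map[[exit_key]]
    if (is.null(hit)) break
    pe <- split_end_key(hit$partner)
    if (pe$cid %in% seen) break
    n <- nrow(parts)
    parts$gap_est[n] <- estimate_gap(links$gaps[[hit$li]])
    parts$support[n] <- links$support[hit$li]
    cid <- pe$cid
    entered <- pe$end
    parts <- rbind(parts, part_row(cid, if (entered == "head") "+" else "-"))
    seen <- c(seen, cid)
  }
  list(parts = parts, seen = seen)
}

#' Chain accepted links into preliminary scaffolds
#'
#' Scaffolds are the connected components of the oriented contig-end graph,
#' linearized by walking from a free end; orientation is propagated from the
#' walk's seed contig. Unlinked contigs become singleton scaffolds. A
#' component that closes on itself is marked circular and opened at the
#' junction with the weakest support (ties broken lexicographically by link
#' key).
#'
#' @param links accepted links data.frame (each contig end occurs at most
#'   once; guaranteed by [resolve_ambiguities()]).
#' @param contig_ids character vector of all assembly contig ids.
#' @return a list of scaffolds.
#' @export
chain_scaffolds <- function(links, contig_ids) {
  map <- build_end_map(links)
  linked <- unique(c(links$a_id, links$b_id))
  visited <- character(0)
  scafs <- list()
  # linear components: start from every free end, smallest key first
  all_ends <- paste0(rep(linked, each = 2L), ":", c("head", "tail"))
  free <- sort(all_ends[vapply(all_ends, function(k) is.null(map[[k]]),
                               logical(1))])
  for (k in free) {
    cid <- split_end_key(k)$cid
    if (cid %in% visited) next
    w <- walk_chain(k, map, links)
    visited <- c(visited, w$seen)
    scafs[[length(scafs) + 1L]] <- new_scaffold(w$parts)
  }
  # remaining linked contigs sit on cycles
  remaining <- sort(setdiff(linked, visited))
  while (length(remaining) > 0L) {
    cid <- remaining[1L]
    # collect the cycle's links by walking from this contig
    cyc_lis <- integer(0)
    cur <- cid; entered <- "head"
    repeat {
      hit <- map[[paste0(cur, ":", other_end(entered))]]
      cyc_lis <- c(cyc_lis, hit$li)
      pe <- split_end_key(hit$partner)
      cur <- pe$cid; entered <- pe$end
      if (cur == cid) break
    }
    cyc_lis <- unique(cyc_lis)
    ord <- order(links$support[cyc_lis], links$key[cyc_lis])
    weakest <- cyc_lis[ord[1L]]
    a_key <- paste0(links$a_id[weakest], ":", links$a_end[weakest])
    b_key <- paste0(links$b_id[weakest], ":", links$b_end[weakest])
    rm(list = c(a_key, b_key), envir = map)
    start <- min(a_key, b_key)
    w <- walk_chain(start, map, links)
    visited <- c(visited, w$seen)
    s <- new_scaffold(w$parts, circular = TRUE)
    s$circ_gap_est <- estimate_gap(links$gaps[[weakest]])
    s$circ_support <- links$support[weakest]
    scafs[[length(scafs) + 1L]] <- s
    remaining <- sort(setdiff(remaining, w$seen))
  }
  for (cid in sort(setdiff(contig_ids, linked))) {
    scafs[[length(scafs) + 1L]] <- new_scaffold(part_row(cid, "+"))
  }
  scafs
}

# junction ends of adjacent scaffold parts: the right-facing end of the
# left part and the left-facing end of the right part
junction_ends <- function(orient_left, orient_right) {
  c(if (orient_left == "+") "tail" else "head",
    if (orient_right == "+") "head" else "tail")
}

# candidate repeat insertions for junction X--Y from stored path triples
repeat_candidates <- function(X, eX, Y, eY, paths, flags) {
  out <- list()
  for (key in names(paths)) {
    pp <- paths[[key]]
    if (length(pp$cids) != 3L) next
    if (!(pp$cids[2L] %in% flags)) next
    readings <- list(
      list(cids = pp$cids, strands = pp$strands, gaps = pp$gaps),
      list(cids = rev(pp$cids), strands = flip_strand(rev(pp$strands)),
           gaps = pp$gaps[, 2:1, drop = FALSE])
    )
    for (rd in readings) {
      if (rd$cids[1L] != X || rd$cids[3L] != Y) next
      if (downstream_end(rd$strands[1L]) != eX) next
      if (upstream_end(rd$strands[3L]) != eY) next
      out[[length(out) + 1L]] <- list(
        rep_id = rd$cids[2L],
        orient = if (rd$strands[2L] == "F") "+" else "-",
        support = pp$n,
        gap1 = lower_median(rd$gaps[, 1L]),
        gap2 = lower_median(rd$gaps[, 2L]))
    }
  }
  out
}

#' Place repeat-flagged contigs at scaffold junctions
#'
#' For each junction (X, Y) inside a scaffold, if the multi-contig path
#' store holds a tuple X > R > Y (in the junction's orientation frame) with
#' at least `k` supporting reads and R repeat-flagged, a copy of R is
#' inserted at the junction, with the two gaps taken from the tuple's
#' per-read estimates. A repeat may be placed at several junctions (one copy
#' each). When two distinct repeats qualify with equal support, neither is
#' placed and a warning is raised.
#'
#' @param scaffolds list of scaffolds from [chain_scaffolds()].
#' @param graph the first-pass `linkage_graph` (its path store still
#'   contains the repeat tuples).
#' @param params a [link_params()] list.
#' @return `list(scaffolds, placed)`: updated scaffolds and the ids of the
#'   repeats that were placed somewhere.
#' @export
place_repeats <- function(scaffolds, graph, params = link_params()) {
  flags <- graph$repeat_flags
  placed <- character(0)
  if (length(flags) == 0L) return(list(scaffolds = scaffolds, placed = placed))
  triples <- Filter(function(pp) length(pp$cids) == 3L &&
                      (pp$cids[2L] %in% flags), graph$paths)
  for (si in seq_along(scaffolds)) {
    p <- scaffolds[[si]]$parts
    i <- 1L
    while (i < nrow(p)) {
      je <- junction_ends(p$orientation[i], p$orientation[i + 1L])
      cand <- repeat_candidates(p$contig_id[i], je[1L],
                                p$contig_id[i + 1L], je[2L], triples, flags)
      cand <- Filter(function(cc) cc$support >= params$k, cand)
      if (length(cand) > 0L) {
        sup <- vapply(cand, `[[`, numeric(1), "support")
        ids <- vapply(cand, `[[`, character(1), "rep_id")
        ord <- order(-sup, ids)
        cand <- cand[ord]; sup <- sup[ord]; ids <- ids[ord]
        if (length(cand) > 1L && sup[2L] == sup[1L] && ids[2L] != ids[1L]) {
          warning("conflicting repeat candidates (", ids[1L], ", ", ids[2L],
                  ") at junction ", p$contig_id[i], "--", p$contig_id[i + 1L],
                  "; placing neither")
        } else {
          cc <- cand[[1L]]
          newrow <- part_row(cc$rep_id, cc$orient)
          newrow$gap_est <- cc$gap2
          newrow$support <- cc$support
          p$gap_est[i] <- cc$gap1
          p$support[i] <- cc$support
          p <- rbind(p[seq_len(i), , drop = FALSE], newrow,
                     p[(i + 1L):nrow(p), , drop = FALSE])
          placed <- c(placed, cc$rep_id)
          i <- i + 1L
        }
      }
      i <- i + 1L
    }
    rownames(p) <- NULL
    scaffolds[[si]]$parts <- p
  }
  list(scaffolds = scaffolds, placed = sort(unique(placed)))
}

#' Strip repeat contigs from scaffold edges
#'
#' Repeat-flagged contigs are removed from both ends of every multi-contig
#' scaffold, iterating until the ends are non-repeat. Stripped contigs are
#' returned so the caller can re-emit them as singleton scaffolds
#' (conservation: every input contig appears in the output).
#'
#' @param scaffolds list of scaffolds.
#' @param flags repeat-flagged contig ids.
#' @return `list(scaffolds, stripped)`.
#' @export
trim_edge_repeats <- function(scaffolds, flags) {
  stripped <- character(0)
  out <- list()
  for (s in scaffolds) {
    p <- s$parts
    if (nrow(p) > 1L && !isTRUE(s$circular)) {
      while (nrow(p) > 0L && p$contig_id[1L] %in% flags) {
        stripped <- c(stripped, p$contig_id[1L])
        p <- p[-1L, , drop = FALSE]
      }
      while (nrow(p) > 0L && p$contig_id[nrow(p)] %in% flags) {
        stripped <- c(stripped, p$contig_id[nrow(p)])
        p <- p[-nrow(p), , drop = FALSE]
      }
      if (nrow(p) > 0L) {
        p$gap_est[nrow(p)] <- NA_real_
        p$support[nrow(p)] <- NA_integer_
        p$j_kind[nrow(p)] <- NA_character_
      }
    }
    if (nrow(p) > 0L) {
      rownames(p) <- NULL
      s$parts <- p
      out[[length(out) + 1L]] <- s
    }
  }
  list(scaffolds = out, stripped = sort(unique(stripped)))
}

reverse_scaffold <- function(s) {
  p <- s$parts
  n <- nrow(p)
  q <- p[n:1, , drop = FALSE]
  q$orientation <- ifelse(q$orientation == "+", "-", "+")
  # junction i in the reversed scaffold is junction n-i of the original
  if (n > 1L) {
    for (col in c("gap_est", "support", "j_kind", "gap_len", "overlap_len")) {
      q[[col]] <- c(rev(p[[col]][seq_len(n - 1L)]), p[[col]][n])
    }
  }
  rownames(q) <- NULL
  s$parts <- q
  s
}

scaffold_terminal_ends <- function(s) {
  p <- s$parts
  n <- nrow(p)
  left <- paste0(p$contig_id[1L], ":",
                 if (p$orientation[1L] == "+") "head" else "tail")
  right <- paste0(p$contig_id[n], ":",
                  if (p$orientation[n] == "+") "tail" else "head")
  c(left = left, right = right)
}

#' Rejoin preliminary scaffolds via their non-repeat terminal contigs
#'
#' Link acceptance is re-run restricted to the terminal non-repeat contig
#' ends of distinct scaffolds (same support and ratio rules, over all
#' surviving links including those previously shadowed by trimmed repeats);
#' mutually accepted terminal links merge the scaffolds. Iterates to a
#' fixed point.
#'
#' @param scaffolds list of scaffolds (edges trimmed).
#' @param graph the final-pass `linkage_graph` (transitively reduced).
#' @param params a [link_params()] list.
#' @param flags repeat-flagged contig ids.
#' @return the merged list of scaffolds.
#' @export
rejoin_scaffolds <- function(scaffolds, graph, params = link_params(),
                             flags = character(0)) {
  links <- graph$links
  links <- links[links$support >= params$k, , drop = FALSE]
  if (nrow(links) > 0L) {
    links <- links[!(links$a_id %in% flags) & !(links$b_id %in% flags), ,
                   drop = FALSE]
  }
  if (nrow(links) == 0L) return(scaffolds)
  rownames(links) <- NULL
  repeat {
    open <- which(!vapply(scaffolds, function(s) isTRUE(s$circular),
                          logical(1)))
    term <- lapply(scaffolds[open], scaffold_terminal_ends)
    end2scaf <- list()
    for (ti in seq_along(term)) {
      for (k in term[[ti]]) end2scaf[[k]] <- open[ti]
    }
    akey <- paste0(links$a_id, ":", links$a_end)
    bkey <- paste0(links$b_id, ":", links$b_end)
    cand <- which(akey %in% names(end2scaf) & bkey %in% names(end2scaf))
    cand <- cand[vapply(cand, function(li) {
      end2scaf[[akey[li]]] != end2scaf[[bkey[li]]]
    }, logical(1))]
    if (length(cand) == 0L) break
    # per terminal end, keep the single best candidate by the ratio rule
    accept_at <- function(keys) {
      ok <- logical(length(cand))
      for (grp in split(seq_along(cand), keys)) {
        lis <- cand[grp]
        ord <- order(-links$support[lis], links$key[lis])
        if (length(lis) == 1L ||
            links$support[lis[ord[2L]]] / links$support[lis[ord[1L]]] <=
              params$ratio) {
          ok[grp[ord[1L]]] <- TRUE
        }
      }
      ok
    }
    mutual <- accept_at(akey[cand]) & accept_at(bkey[cand])
    cand <- cand[mutual]
    if (length(cand) == 0L) break
    ord <- order(-links$support[cand], links$key[cand])
    joined <- FALSE
    used <- integer(0)
    for (li in cand[ord]) {
      sa <- end2scaf[[akey[li]]]
      sb <- end2scaf[[bkey[li]]]
      if (sa %in% used || sb %in% used) next
      A <- scaffolds[[sa]]; B <- scaffolds[[sb]]
      if (scaffold_terminal_ends(A)[["left"]] == akey[li]) {
        A <- reverse_scaffold(A)
      }
      if (scaffold_terminal_ends(B)[["right"]] == bkey[li]) {
        B <- reverse_scaffold(B)
      }
      if (scaffold_terminal_ends(A)[["right"]] != akey[li] ||
          scaffold_terminal_ends(B)[["left"]] != bkey[li]) {
        warning("terminal link ", links$key[li],
                " inconsistent with scaffold orientation; skipped")
        next
      }
      na <- nrow(A$parts)
      A$parts$gap_est[na] <- estimate_gap(links$gaps[[li]])
      A$parts$support[na] <- links$support[li]
      A$parts <- rbind(A$parts, B$parts)
      rownames(A$parts) <- NULL
      scaffolds[[sa]] <- A
      scaffolds[[sb]] <- NULL
      joined <- TRUE
      used <- c(used, sa, sb)
      break  # indices shifted; recompute terminals
    }
    if (!joined) break
  }
  scaffolds
}

#' Resolve one junction to a gap or a merge
#'
#' A positive gap estimate becomes an N-gap of that length. A non-positive
#' estimate triggers an overlap search between the suffix of the left
#' oriented sequence and the prefix of the right one: candidate overlap
#' lengths within `merge_band` of the estimated overlap are scored by
#' per-base identity, and the qualifying length closest to the estimate
#' wins. If no overlap qualifies (or sequences are unavailable) a gap of
#' `min_gap_n` N bases is emitted.
#'
#' @param gap_est signed gap estimate (bp).
#' @param seq_a_tail oriented sequence of the left contig (or `NULL`).
#' @param seq_b_head oriented sequence of the right contig (or `NULL`).
#' @param params a [merge_params()] list.
#' @return `list(kind, gap_len, overlap_len)` with exactly one of
#'   `gap_len`/`overlap_len` set.
#' @export
resolve_junction <- function(gap_est, seq_a_tail = NULL, seq_b_head = NULL,
                             params = merge_params()) {
  est <- round(gap_est)
  if (est > 0) {
    return(list(kind = "gap", gap_len = as.integer(est),
                overlap_len = NA_integer_))
  }
  fallback <- list(kind = "gap", gap_len = as.integer(params$min_gap_n),
                   overlap_len = NA_integer_)
  if (is.null(seq_a_tail) || is.null(seq_b_head)) {
    fallback$gap_len <- as.integer(max(est, params$min_gap_n))
    return(fallback)
  }
  target <- abs(est)
  la <- nchar(seq_a_tail); lb <- nchar(seq_b_head)
  hi <- min(target + params$merge_band, min(la, lb) - 1L)
  lo <- max(1L, target - params$merge_band)
  if (hi < lo) return(fallback)
  sa <- utf8ToInt(substr(seq_a_tail, la - hi + 1L, la))
  pb <- utf8ToInt(substr(seq_b_head, 1L, hi))
  best_o <- NA_integer_; best_d <- Inf
  for (o in lo:hi) {
    idn <- mean(sa[(hi - o + 1L):hi] == pb[1L:o])
    if (idn >= params$merge_min_identity) {
      d <- abs(o - target)
      if (d < best_d || (d == best_d && o > best_o)) {
        best_o <- o; best_d <- d
      }
    }
  }
  if (is.na(best_o)) return(fallback)
  list(kind = "merge", gap_len = NA_integer_, overlap_len = as.integer(best_o))
}

# resolve every junction of every scaffold; seqs may be NULL
resolve_all_junctions <- function(scaffolds, seqs = NULL,
                                  params = merge_params()) {
  for (si in seq_along(scaffolds)) {
    p <- scaffolds[[si]]$parts
    n <- nrow(p)
    if (n < 2L) { scaffolds[[si]]$parts <- p; next }
    ps <- if (!is.null(seqs)) scaffold_part_seqs(p, seqs) else NULL
    for (i in seq_len(n - 1L)) {
      j <- resolve_junction(p$gap_est[i],
                            if (is.null(ps)) NULL else ps[i],
                            if (is.null(ps)) NULL else ps[i + 1L],
                            params)
      p$j_kind[i] <- j$kind
      p$gap_len[i] <- j$gap_len
      p$overlap_len[i] <- j$overlap_len
    }
    scaffolds[[si]]$parts <- p
  }
  scaffolds
}

#' Detect and annotate circular scaffolds
#'
#' A scaffold whose two terminal contig ends carry a surviving link with
#' support at least `k` (including a self-link of a single-contig plasmid)
#' is flagged circular. The closing junction is resolved like any other;
#' when it is a merge, the terminal overlap is trimmed from the emitted
#' sequence end. Output sequences remain linear.
#'
#' @param scaffolds list of scaffolds with internal junctions resolved.
#' @param graph the final-pass `linkage_graph`.
#' @param params a [link_params()] list.
#' @param seqs optional named contig sequences.
#' @param mparams a [merge_params()] list.
#' @return the annotated list of scaffolds.
#' @export
circularize <- function(scaffolds, graph, params = link_params(),
                        seqs = NULL, mparams = merge_params()) {
  links <- graph$links
  links <- links[links$support >= params$k, , drop = FALSE]
  for (si in seq_along(scaffolds)) {
    s <- scaffolds[[si]]
    if (!isTRUE(s$circular)) {
      te <- scaffold_terminal_ends(s)
      lcl <- canon_link(split_end_key(te[["right"]])$cid,
                        split_end_key(te[["right"]])$end,
                        split_end_key(te[["left"]])$cid,
                        split_end_key(te[["left"]])$end)
      key <- link_key(lcl$a_id, lcl$a_end, lcl$b_id, lcl$b_end)
      hit <- which(links$key == key)
      if (length(hit) == 0L) next
      if (nrow(s$parts) == 1L &&
          split_end_key(te[["left"]])$end == split_end_key(te[["right"]])$end) {
        next  # degenerate self-link joining the same physical end
      }
      s$circular <- TRUE
      s$circ_gap_est <- estimate_gap(links$gaps[[hit[1L]]])
      s$circ_support <- links$support[hit[1L]]
    }
    if (is.na(s$circ_gap_est)) { scaffolds[[si]] <- s; next }
    ps <- if (!is.null(seqs)) scaffold_part_seqs(s$parts, seqs) else NULL
    j <- resolve_junction(s$circ_gap_est,
                          if (is.null(ps)) NULL else ps[length(ps)],
                          if (is.null(ps)) NULL else ps[1L],
                          mparams)
    s$circ_kind <- j$kind
    s$circ_overlap <- if (identical(j$kind, "merge")) j$overlap_len else 0L
    scaffolds[[si]] <- s
  }
  scaffolds
}

scaffold_emitted_length <- function(s, contig_lengths) {
  p <- s$parts
  lens <- as.numeric(contig_lengths[p$contig_id])
  gaps <- p$gap_len[!is.na(p$gap_len)]
  sum(lens) + sum(gaps) - sum(part_trims(s))
}

#' Finalize a scaffold set: deterministic naming and order
#'
#' Scaffolds are ordered by decreasing emitted length (ties broken by first
#' contig id) and named `scaffold_1..scaffold_n`.
#'
#' @param scaffolds list of scaffolds with resolved junctions.
#' @param contig_lengths named integer vector of contig lengths.
#' @return a `scaffold_set` list.
#' @export
finalize_scaffolds <- function(scaffolds, contig_lengths) {
  lens <- vapply(scaffolds, scaffold_emitted_length, numeric(1),
                 contig_lengths = contig_lengths)
  firsts <- vapply(scaffolds, function(s) s$parts$contig_id[1L], character(1))
  ord <- order(-lens, firsts)
  scaffolds <- scaffolds[ord]
  for (i in seq_along(scaffolds)) {
    scaffolds[[i]]$id <- paste0("scaffold_", i)
    scaffolds[[i]]$length <- lens[ord[i]]
  }
  structure(scaffolds, class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  lens <- vapply(x, function(s) as.numeric(s$length %||% NA), numeric(1))
  cat(sprintf("scaffold_set: %d scaffolds, %d contig parts, N50 %d\n",
              length(x), sum(vapply(x, function(s) nrow(s$parts), integer(1))),
              n50(lens)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full scaffolding stage on filtered placements
#'
#' Builds the linkage graph (with iterative repeat flagging), chains
#' accepted links, places repeats from multi-contig paths, trims scaffold
#' edge repeats, rejoins preliminary scaffolds through their terminal
#' contigs, resolves every junction to a gap or merge, detects circular
#' scaffolds, and returns the finalized, deterministically named set.
#'
#' @param placements placement data.frame from [collect_placements()].
#' @param contig_lengths named integer vector of all contig lengths.
#' @param seqs optional named contig sequences (enables overlap merging and
#'   FASTA output).
#' @param lparams a [link_params()] list.
#' @param mparams a [merge_params()] list.
#' @return `list(scaffolds, linkage, repeat_flags, placed_repeats)`.
#' @export
build_scaffolds <- function(placements, contig_lengths, seqs = NULL,
                            lparams = link_params(),
                            mparams = merge_params()) {
  lk <- build_linkage(placements, lparams)
  ls_log("linkage: %d links kept, %d repeat flags",
         nrow(lk$accepted), length(lk$repeat_flags))
  scafs <- chain_scaffolds(lk$accepted, names(contig_lengths))
  pr <- place_repeats(scafs, lk$graph_full, lparams)
  scafs <- pr$scaffolds
  # a repeat placed at a junction no longer needs its singleton copy
  if (length(pr$placed) > 0L) {
    keep <- vapply(scafs, function(s) {
      !(nrow(s$parts) == 1L && s$parts$contig_id[1L] %in% pr$placed)
    }, logical(1))
    scafs <- scafs[keep]
  }
  tr <- trim_edge_repeats(scafs, lk$repeat_flags)
  scafs <- tr$scaffolds
  present <- unique(unlist(lapply(scafs, function(s) s$parts$contig_id)))
  for (cid in sort(setdiff(c(tr$stripped, lk$repeat_flags), present))) {
    scafs[[length(scafs) + 1L]] <- new_scaffold(part_row(cid, "+"))
  }
  scafs <- rejoin_scaffolds(scafs, lk$graph, lparams, lk$repeat_flags)
  scafs <- resolve_all_junctions(scafs, seqs, mparams)
  scafs <- circularize(scafs, lk$graph, lparams, seqs, mparams)
  scafs <- finalize_scaffolds(scafs, contig_lengths)
  ls_log("scaffolding: %d scaffolds from %d contigs",
         length(scafs), length(contig_lengths))
  list(scaffolds = scafs, linkage = lk, repeat_flags = lk$repeat_flags,
       placed_repeats = pr$placed)
}
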