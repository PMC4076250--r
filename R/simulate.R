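#' Simulation configuration
#'
#' Defaults emulate a bacterial-scale scaffolding experiment with CLR-type
#' long reads: mean read length 2.5 kb (lognormal), 15% indel-dominated
#' error (50% insertion / 35% deletion / 15% substitution), and true
#' inter-contig gaps drawn uniformly from 0-500 bp so that typical reads
#' span the junctions.
#'
#' @param genome_len genome length (bp).
#' @param repeat_families list of `c(unit_len, copies)` pairs to plant.
#' @param n_contigs number of contigs in random fragmentation mode.
#' @param break_at_repeats if `TRUE`, each repeat copy becomes its own
#'   truth segment and the family is emitted as one shared contig.
#' @param coverage fold coverage of simulated reads.
#' @param read_len_mean,read_len_sigma lognormal read-length parameters
#'   (arithmetic mean and log-sd shape; `sigma = 0` gives constant length).
#' @param error_rate total per-base error rate.
#' @param error_mix fractions `c(insert, delete, substitute)`, summing to 1.
#' @param gap_range range (bp) of true inter-contig gaps.
#' @param circular simulate a circular replicon.
#' @param min_olap minimum read/contig overlap (bp) an ideal aligner
#'   reports as a local alignment.
#' @param seed integer RNG seed (full determinism given the seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_len = 200000, repeat_families = list(),
                       n_contigs = 20, break_at_repeats = length(repeat_families) > 0,
                       coverage = 20, read_len_mean = 2500,
                       read_len_sigma = 0.4, error_rate = 0.15,
                       error_mix = c(0.50, 0.35, 0.15),
                       gap_range = c(0, 500), circular = FALSE,
                       min_olap = 100, seed = 1L) {
  stopifnot(genome_len > 0, coverage > 0, error_rate >= 0, error_rate < 1,
            abs(sum(error_mix) - 1) < 1e-8, length(gap_range) == 2L,
            gap_range[1] >= 0, gap_range[2] >= gap_range[1])
  structure(list(genome_len = as.integer(genome_len),
                 repeat_families = repeat_families,
                 n_contigs = as.integer(n_contigs),
                 break_at_repeats = break_at_repeats,
                 coverage = coverage, read_len_mean = read_len_mean,
                 read_len_sigma = read_len_sigma, error_rate = error_rate,
                 error_mix = error_mix, gap_range = as.integer(gap_range),
                 circular = circular, min_olap = as.integer(min_olap),
                 seed = as.integer(seed)), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute a fraction of bases (repeat copies stay >= 97% identical)
mutate_seq <- function(s, rate = 0.01) {
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(x)) < rate)
  for (i in hit) {
    x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
  }
  paste(x, collapse = "")
}

#' Simulate a genome with planted repeat families
#'
#' Generates a uniform-random base sequence and copies each repeat family's
#' unit (copies >= 97% identical, 1% substitution divergence) into
#' non-overlapping, well-spaced positions. Fully deterministic given the
#' seed in `config`.
#'
#' @param config a [sim_config()] list.
#' @return `list(genome, repeats)` where `repeats` is a data.frame
#'   (`family, copy, start, end`; 1-based inclusive genome coordinates).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  G <- config$genome_len
  genome <- random_dna(G)
  ann <- data.frame(family = character(0), copy = integer(0),
                    start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  occupied <- matrix(numeric(0), ncol = 2)
  spacing <- 3000L
  margin <- 5000L
  fi <- 0L
  for (fam in config$repeat_families) {
    fi <- fi + 1L
    unit_len <- as.integer(fam[1]); copies <- as.integer(fam[2])
    if (copies * (unit_len + spacing) + 2L * margin > G) {
      ls_input_error("repeat family %d does not fit in the genome", fi)
    }
    unit <- random_dna(unit_len)
    placed <- 0L
    tries <- 0L
    while (placed < copies) {
      tries <- tries + 1L
      if (tries > 10000L) {
        ls_input_error("could not place repeat family %d", fi)
      }
      st <- floor(runif(1, margin, G - margin - unit_len)) + 1L
      en <- st + unit_len - 1L
      if (nrow(occupied) > 0L &&
          any(st - spacing <= occupied[, 2] & en + spacing >= occupied[, 1])) {
        next
      }
      placed <- placed + 1L
      copy_seq <- if (placed == 1L) unit else mutate_seq(unit, 0.01)
      substr(genome, st, en) <- copy_seq
      occupied <- rbind(occupied, c(st, en))
      ann <- rbind(ann, data.frame(family = paste0("repeat_", fi),
                                   copy = placed, start = st, end = en,
                                   stringsAsFactors = FALSE))
    }
  }
  list(genome = genome, repeats = ann[order(ann$start), , drop = FALSE])
}

#' Fragment a simulated genome into draft contigs with ground truth
#'
#' In repeat-aware mode (`break_at_repeats = TRUE`) every repeat copy
#' becomes one truth segment, unique sequence between repeats becomes
#' unique contigs, and each repeat family is emitted once as a shared
#' contig (multiplicity recorded in the truth layout) -- mimicking draft
#' assemblers that split contigs at repeat boundaries. Otherwise the genome
#' is broken at `n_contigs - 1` near-even jittered breakpoints. True
#' inter-contig gaps are created by trimming `U(gap_range)` bases from the
#' unique side of each junction.
#'
#' @param genome genome sequence (character scalar).
#' @param annotation repeat annotation from [simulate_genome()].
#' @param config a [sim_config()] list.
#' @return `list(contigs, layout)`: named contig sequences and the truth
#'   layout data.frame (`contig_id, orientation, start, end, gap_after,
#'   multiplicity`), rows ordered along the genome. `gap_after` of the last
#'   row is the wrap gap for circular genomes and `NA` otherwise.
#' @export
fragment_contigs <- function(genome, annotation, config) {
  G <- nchar(genome)
  draw_gap <- function(n) {
    if (config$gap_range[2] == config$gap_range[1]) {
      rep(config$gap_range[1], n)
    } else {
      floor(runif(n, config$gap_range[1], config$gap_range[2] + 1))
    }
  }
  if (config$break_at_repeats && nrow(annotation) > 0L) {
    segs <- list()
    pos <- 1L
    for (i in seq_len(nrow(annotation))) {
      if (annotation$start[i] > pos) {
        segs[[length(segs) + 1L]] <- list(kind = "unique",
                                          start = pos,
                                          end = annotation$start[i] - 1L)
      }
      segs[[length(segs) + 1L]] <- list(kind = annotation$family[i],
                                        start = annotation$start[i],
                                        end = annotation$end[i])
      pos <- annotation$end[i] + 1L
    }
    if (pos <= G) {
      segs[[length(segs) + 1L]] <- list(kind = "unique", start = pos, end = G)
    }
  } else {
    n <- config$n_contigs
    if (n < 1L || n > G %/% 1000L) {
      ls_input_error("n_contigs = %d infeasible for a %d bp genome", n, G)
    }
    base <- round(seq(0L, G, length.out = n + 1L))
    jit <- floor(runif(n - 1L, -0.25, 0.25) * (G / n))
    cuts <- c(0L, sort(base[2:n] + jit), G)
    segs <- lapply(seq_len(n), function(i) {
      list(kind = "unique", start = cuts[i] + 1L, end = cuts[i + 1L])
    })
  }
  ns <- length(segs)
  gaps <- draw_gap(ns)  # gap after each segment (trimmed from next unique)
  # trim the unique side of every junction to create true gaps
  starts <- vapply(segs, function(s) s$start, numeric(1))
  ends <- vapply(segs, function(s) s$end, numeric(1))
  kinds <- vapply(segs, function(s) s$kind, character(1))
  for (i in seq_len(ns)) {
    prev <- if (i == 1L) ns else i - 1L
    internal <- i > 1L || config$circular
    if (internal && kinds[i] == "unique") {
      starts[i] <- starts[i] + gaps[prev]
    } else if (internal && kinds[prev] == "unique") {
      ends[prev] <- ends[prev] - gaps[prev]
    } else if (internal) {
      gaps[prev] <- 0L  # repeat-repeat junction: keep abutting
    }
  }
  if (any(ends - starts + 1 < 300)) {
    ls_input_error("fragmentation produced a contig shorter than 300 bp; enlarge the genome or reduce n_contigs")
  }
  # actual gap sizes after trimming
  gap_after <- c(starts[-1L] - ends[-ns] - 1L,
                 if (config$circular) (G - ends[ns]) + (starts[1L] - 1L)
                 else NA_integer_)
  uniq_idx <- which(kinds == "unique")
  ids <- character(ns)
  ids[uniq_idx] <- sprintf("contig_%03d", seq_along(uniq_idx))
  ids[kinds != "unique"] <- kinds[kinds != "unique"]
  mult <- table(ids)
  layout <- data.frame(contig_id = ids, orientation = "+",
                       start = as.integer(starts), end = as.integer(ends),
                       gap_after = as.integer(gap_after),
                       multiplicity = as.integer(mult[ids]),
                       stringsAsFactors = FALSE)
  # one sequence per contig id; repeat families use their first copy
  first <- layout[!duplicated(layout$contig_id), , drop = FALSE]
  contigs <- vapply(seq_len(nrow(first)), function(i) {
    substr(genome, first$start[i], first$end[i])
  }, character(1))
  names(contigs) <- first$contig_id
  list(contigs = contigs, layout = layout)
}

# shared read-interval sampler (lengths, starts, strands)
sample_read_intervals <- function(config) {
  G <- config$genome_len
  n <- round(config$coverage * G / config$read_len_mean)
  if (config$read_len_sigma > 0) {
    len <- rlnorm(n, meanlog = log(config$read_len_mean) -
                    config$read_len_sigma^2 / 2,
                  sdlog = config$read_len_sigma)
  } else {
    len <- rep(config$read_len_mean, n)
  }
  len <- pmin(pmax(round(len), 300L), G)
  if (config$circular) {
    start <- floor(runif(n, 0, G)) + 1L
  } else {
    start <- floor(runif(n) * (G - len + 1)) + 1L
  }
  data.frame(read_id = sprintf("read_%05d", seq_len(n)),
             start = as.integer(start), len = as.integer(len),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# apply CLR-style errors to one sequence; returns the erroneous sequence
apply_clr_errors <- function(s, error_rate, error_mix) {
  if (error_rate == 0) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(x)
  err <- runif(L) < error_rate
  type <- integer(L)  # 0 none, 1 ins, 2 del, 3 sub
  ne <- sum(err)
  if (ne > 0L) {
    type[err] <- sample(1:3, ne, replace = TRUE, prob = error_mix)
  }
  reps <- ifelse(type == 2L, 0L, ifelse(type == 1L, 2L, 1L))
  out <- x[rep.int(seq_len(L), reps)]
  cum <- cumsum(reps)
  bases <- c("A", "C", "G", "T")
  ins_at <- cum[type == 1L]  # second copy position: replace with random base
  if (length(ins_at) > 0L) {
    out[ins_at] <- sample(bases, length(ins_at), replace = TRUE)
  }
  sub_at <- cum[type == 3L]
  if (length(sub_at) > 0L) {
    cur <- out[sub_at]
    alt <- sample(bases, length(sub_at), replace = TRUE)
    clash <- alt == cur
    while (any(clash)) {
      alt[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- alt == cur
    }
    out[sub_at] <- alt
  }
  paste(out, collapse = "")
}

#' Simulate CLR-style reads from a genome
#'
#' Read starts are uniform over the genome (wrapping if circular), lengths
#' are lognormal truncated to `[300, genome_len]`, and per-base errors are
#' applied with the configured insertion/deletion/substitution mix. The
#' read count is fixed as `round(coverage * genome_len / read_len_mean)`
#' before length sampling, for reproducibility.
#'
#' @param genome genome sequence.
#' @param config a [sim_config()] list; its `seed` is applied.
#' @return a named character vector of read sequences.
#' @export
simulate_reads <- function(genome, config) {
  set.seed(config$seed + 1L)
  G <- nchar(genome)
  iv <- sample_read_intervals(config)
  genome2 <- if (config$circular) paste0(genome, genome) else genome
  out <- character(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    s <- substr(genome2, iv$start[i], iv$start[i] + iv$len[i] - 1L)
    if (iv$strand[i] == "-") s <- revcomp(s)
    out[i] <- apply_clr_errors(s, config$error_rate, config$error_mix)
  }
  names(out) <- iv$read_id
  attr(out, "intervals") <- iv  # source coordinates, for validation
  out
}

# expected length of a genomic span after indel-dominated errors, with
# binomial noise (insertions lengthen, deletions shorten the read copy)
expand_lengths <- function(m, error_rate, error_mix) {
  if (error_rate == 0) return(m)
  m + rbinom(length(m), m, error_rate * error_mix[1]) -
    rbinom(length(m), m, error_rate * error_mix[2])
}

#' Simulate the placements an ideal aligner would produce
#'
#' Bypasses sequence-level alignment: read intervals are sampled on the
#' genome and intersected with the truth layout, and each overlap of at
#' least `min_olap` bp becomes one read-to-contig alignment record. Read
#' coordinates are distorted by the configured indel error model (binomial
#' insertion/deletion counts per span), so gap estimates carry realistic
#' long-read noise; with `error_rate = 0` the records are exact. Repeat
#' copies map to the single shared repeat contig, reproducing repeat
#' ambiguity.
#'
#' @param layout truth layout from [fragment_contigs()].
#' @param config a [sim_config()] list; its `seed` is applied.
#' @return an alignment data.frame in the [parse_alignments()] convention,
#'   ready for [collect_placements()].
#' @export
simulate_placements <- function(layout, config) {
  set.seed(config$seed + 2L)
  G <- config$genome_len
  iv <- sample_read_intervals(config)
  seg_start <- layout$start
  seg_end <- layout$end
  # circular reads may wrap: duplicate segments shifted by G
  if (config$circular) {
    seg_start <- c(seg_start, seg_start + G)
    seg_end <- c(seg_end, seg_end + G)
    seg_row <- rep(seq_len(nrow(layout)), 2L)
  } else {
    seg_row <- seq_len(nrow(layout))
  }
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(iv$start, iv$start + iv$len - 1L),
    IRanges::IRanges(seg_start, seg_end),
    minoverlap = config$min_olap)
  ri <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov_start <- pmax(iv$start[ri], seg_start[si])
  ov_end <- pmin(iv$start[ri] + iv$len[ri] - 1L, seg_end[si])
  m <- ov_end - ov_start + 1L
  row <- seg_row[si]
  contig_id <- layout$contig_id[row]
  contig_len0 <- seg_end[si] - seg_start[si] + 1L
  cstart <- ov_start - seg_start[si]          # 0-based on contig
  cend <- ov_end - seg_start[si] + 1L
  e <- config$error_rate; mix <- config$error_mix
  r_start <- expand_lengths(ov_start - iv$start[ri], e, mix)
  r_span <- pmax(expand_lengths(m, e, mix), 50L)
  r_end <- r_start + r_span
  # erroneous read length: at least the furthest aligned coordinate
  rl <- expand_lengths(iv$len, e, mix)
  read_len <- pmax(rl[ri], unsplit(lapply(split(r_end, ri), max), ri))
  flip <- iv$strand[ri] == "-"
  rs <- ifelse(flip, read_len - r_end, r_start)
  re <- ifelse(flip, read_len - r_start, r_end)
  data.frame(read_id = iv$read_id[ri], read_len = as.integer(read_len),
             read_start = as.integer(rs), read_end = as.integer(re),
             strand = ifelse(flip, "-", "+"),
             contig_id = contig_id, contig_len = as.integer(contig_len0),
             contig_start = as.integer(cstart), contig_end = as.integer(cend),
             score = as.integer(m), identity = 1 - e,
             block_len = as.integer(m), mapq = 60L,
             stringsAsFactors = FALSE)
}
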