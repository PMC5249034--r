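# Seeded synthetic-data generators: a circular bacterial genome (scaled to
# tens of kbp for desk tests), its fragmentation into gapped/overlapping
# contigs, indel-dominant single-end reads, and a sizing-error-bearing
# experimental restriction map. Every generator is a pure function of its
# parameters and seed.

#' Generate a random genome sequence
#'
#' I.i.d. bases at the requested GC content, with optional planted exact
#' repeat copies (the hard case for anchoring and merging).
#'
#' @param length Genome length in bp (minimum 1000).
#' @param gc GC fraction in (0,1) (default 0.5).
#' @param repeat_spec Optional list of `c(unit_len, copies)` pairs; each
#'   unit is drawn once and planted `copies` times at random non-overlapping
#'   positions.
#' @param seed Integer RNG seed.
#' @return A DNA string.
#' @export
generate_genome <- function(length, gc = 0.5, repeat_spec = NULL, seed = 1L) {
  stopifnot(length >= 1000L, gc > 0, gc < 1)
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(probs), length, replace = TRUE, prob = probs)
    if (!is.null(repeat_spec)) {
      total_rep <- sum(vapply(repeat_spec, function(r) r[1] * r[2], numeric(1)))
      if (total_rep > length / 2) stop("repeats exceed genome length")
      for (r in repeat_spec) {
        unit_len <- as.integer(r[1])
        copies <- as.integer(r[2])
        unit <- sample(names(probs), unit_len, replace = TRUE, prob = probs)
        # place copies at disjoint random positions
        placed <- 0L
        used <- IRanges::IRanges()
        tries <- 0L
        while (placed < copies && tries < 1000L) {
          tries <- tries + 1L
          p <- sample.int(length - unit_len + 1L, 1L)
          cand <- IRanges::IRanges(p, p + unit_len - 1L)
          if (length(IRanges::findOverlaps(cand, used)) == 0L) {
            bases[p:(p + unit_len - 1L)] <- unit
            used <- c(used, cand)
            placed <- placed + 1L
          }
        }
        if (placed < copies) stop("could not place repeats (genome too small?)")
      }
    }
    paste(bases, collapse = "")
  })
}

#' Fragment a genome into contigs with known truth
#'
#' Junctions between consecutive contigs are drawn as sequence gaps (the
#' intervening genome sequence is dropped) or overlaps (both contigs carry a
#' shared copy) with probability `p_overlap`. Contigs are optionally
#' reverse-complemented and shuffled. The returned truth record is
#' self-checked: reassembling the contigs with the recorded gap sequences
#' and overlap lengths must reproduce the genome exactly.
#'
#' @param genome DNA string.
#' @param n_contigs Number of contigs.
#' @param gap_range Length 2 vector: gap size range in bp.
#' @param overlap_range Length 2 vector: overlap size range in bp.
#' @param p_overlap Probability a junction is an overlap (default 0).
#' @param p_revcomp Probability a contig is reverse-complemented
#'   (default 0).
#' @param shuffle Shuffle contig order (default `TRUE`).
#' @param seed Integer RNG seed.
#' @return A list of class `fragmentation_truth`: `genome`, `contigs`
#'   (contig table, in shuffled order), `true_placements` (one row per
#'   contig: genome coordinates, strand, rank), `true_gaps` (junction index
#'   and dropped sequence for gap junctions), `overlaps` (junction index and
#'   overlap length for overlap junctions).
#' @export
fragment_genome <- function(genome, n_contigs, gap_range = c(200L, 800L),
                            overlap_range = c(50L, 300L), p_overlap = 0,
                            p_revcomp = 0, shuffle = TRUE, seed = 1L) {
  len <- nchar(genome)
  stopifnot(n_contigs >= 1L)
  seg <- len %/% n_contigs
  if (seg <= max(gap_range) + max(overlap_range) + 100L) {
    stop("infeasible partition: contigs too short for the gap/overlap ranges")
  }
  with_seed(seed, {
    # jittered junction anchor points
    anchors <- round(seq_len(n_contigs - 1L) * len / n_contigs +
                       stats::runif(n_contigs - 1L, -seg / 8, seg / 8))
    starts <- integer(n_contigs)
    ends <- integer(n_contigs)
    starts[1] <- 0L
    gaps <- list()
    overlaps <- list()
    for (j in seq_len(n_contigs - 1L)) {
      if (stats::runif(1) < p_overlap) {
        v <- sample(overlap_range[1]:overlap_range[2], 1L)
        ends[j] <- anchors[j] + v
        starts[j + 1L] <- anchors[j]
        overlaps[[length(overlaps) + 1L]] <- list(junction = j, overlap_len = v)
      } else {
        g <- sample(gap_range[1]:gap_range[2], 1L)
        ends[j] <- anchors[j]
        starts[j + 1L] <- anchors[j] + g
        gaps[[length(gaps) + 1L]] <- list(
          junction = j,
          gap_seq = substring(genome, anchors[j] + 1L, anchors[j] + g))
      }
    }
    ends[n_contigs] <- len
    if (any(starts >= ends)) stop("infeasible partition")
    ids <- sprintf("ctg_%02d", seq_len(n_contigs))
    seqs <- substring(genome, starts + 1L, ends)
    strands <- ifelse(stats::runif(n_contigs) < p_revcomp, "-", "+")
    out_seqs <- ifelse(strands == "-", revcomp(seqs), seqs)
    contigs <- data.frame(id = ids, seq = out_seqs, source = "fragment_genome")
    placements <- data.frame(contig_id = ids, axis = "reference",
                             start = starts, end = ends, strand = strands,
                             rank = seq_len(n_contigs),
                             coverage_frac = 1)
    if (shuffle) contigs <- contigs[sample.int(n_contigs), ]
    rownames(contigs) <- NULL
    truth <- structure(list(genome = genome, contigs = contigs,
                            true_placements = placements, true_gaps = gaps,
                            overlaps = overlaps),
                       class = "fragmentation_truth")
    check_reassembly(truth)
    truth
  })
}

# Self-check: truth record must reassemble the genome exactly.
check_reassembly <- function(truth) {
  pl <- truth$true_placements
  ctg <- truth$contigs
  oriented <- vapply(seq_len(nrow(pl)), function(i) {
    s <- contig_seq(ctg, pl$contig_id[i])
    if (pl$strand[i] == "-") revcomp(s) else s
  }, character(1))
  out <- oriented[1]
  gap_by_junc <- setNames(
    lapply(truth$true_gaps, `[[`, "gap_seq"),
    vapply(truth$true_gaps, function(g) as.character(g$junction), character(1)))
  ov_by_junc <- setNames(
    lapply(truth$overlaps, `[[`, "overlap_len"),
    vapply(truth$overlaps, function(o) as.character(o$junction), character(1)))
  for (j in seq_len(nrow(pl) - 1L)) {
    nxt <- oriented[j + 1L]
    jc <- as.character(j)
    if (!is.null(gap_by_junc[[jc]])) {
      out <- paste0(out, gap_by_junc[[jc]], nxt)
    } else {
      out <- paste0(out, substring(nxt, ov_by_junc[[jc]] + 1L))
    }
  }
  if (!identical(out, truth$genome)) {
    stop("internal error: fragmentation truth failed its reassembly check")
  }
  invisible(TRUE)
}

#' Simulate single-end reads with an indel-dominant error profile
#'
#' Emulates short single-end reads from a 200 bp chemistry: positions
#' uniform (wrapping when circular), strand uniform, per-base substitution
#' and indel errors with indels dominating (insertions duplicate the
#' current base, matching homopolymer-type errors). Qualities are constant
#' Phred 30.
#'
#' @param genome DNA string.
#' @param coverage Fold coverage (> 0).
#' @param read_len_mean Mean read length (default 200).
#' @param read_len_sd Read length SD (default 20).
#' @param indel_rate Per-base indel rate (default 0.01).
#' @param sub_rate Per-base substitution rate (default 0.002).
#' @param circular Treat the genome as circular (default `TRUE`).
#' @param seed Integer RNG seed.
#' @return A `read_set`.
#' @export
simulate_reads <- function(genome, coverage, read_len_mean = 200L,
                           read_len_sd = 20L, indel_rate = 0.01,
                           sub_rate = 0.002, circular = TRUE, seed = 1L) {
  len <- nchar(genome)
  stopifnot(coverage > 0)
  if (read_len_mean > len) stop("read length exceeds genome length")
  with_seed(seed, {
    n <- max(1L, round(coverage * len / read_len_mean))
    rl <- pmax(30L, pmin(len, round(rnorm(n, read_len_mean, read_len_sd))))
    pos <- if (circular) {
      sample.int(len, n, replace = TRUE) - 1L
    } else {
      vapply(rl, function(l) sample.int(len - l + 1L, 1L) - 1L, integer(1))
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    doubled <- if (circular) paste0(genome, genome) else genome
    seqs <- substring(doubled, pos + 1L, pos + rl)
    flip <- strands == "-"
    seqs[flip] <- revcomp(seqs[flip])
    if (indel_rate > 0 || sub_rate > 0) {
      seqs <- vapply(seqs, inject_errors, character(1),
                     indel_rate = indel_rate, sub_rate = sub_rate,
                     USE.NAMES = FALSE)
    }
    structure(list(
      id = sprintf("read_%06d", seq_len(n)),
      seq = seqs,
      qual = lapply(nchar(seqs), function(l) rep(30L, l))
    ), class = "read_set")
  })
}

# Per-base error injection: substitutions, deletions, and homopolymer-style
# insertions (the inserted base duplicates the current one).
inject_errors <- function(seq, indel_rate, sub_rate) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  u <- stats::runif(n)
  sub <- u < sub_rate
  del <- !sub & u < sub_rate + indel_rate / 2
  ins <- !sub & !del & u < sub_rate + indel_rate
  if (any(sub)) {
    bases[sub] <- vapply(bases[sub], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  out <- bases
  out[ins] <- paste0(bases[ins], bases[ins])
  out[del] <- ""
  paste(out, collapse = "")
}

#' Simulate an experimental (optical-map) restriction map
#'
#' The true in-silico digest is perturbed multiplicatively per fragment by
#' `Normal(1, sizing_error)`; fragments smaller than `min_frag` are merged
#' into their left neighbour (small fragments go unobserved in optical
#' maps).
#'
#' @param genome DNA string.
#' @param enz An [enzyme()] (default [kpnI()]).
#' @param sizing_error Relative sizing error SD (default 0.03).
#' @param min_frag Minimum observable fragment in bp (default 500).
#' @param circular Is the molecule circular (default `TRUE`).
#' @param seed Integer RNG seed.
#' @return A [restriction_map()].
#' @export
simulate_restriction_map <- function(genome, enz = kpnI(), sizing_error = 0.03,
                                     min_frag = 500L, circular = TRUE,
                                     seed = 1L) {
  true <- digest_sequence(genome, enz, circular = circular)
  with_seed(seed, {
    sizes <- true$sizes
    if (sizing_error > 0) {
      sizes <- pmax(1, round(sizes * rnorm(length(sizes), 1, sizing_error)))
    }
    if (min_frag > 0 && length(sizes) > 1L) {
      out <- numeric(0)
      for (s in sizes) {
        if (s < min_frag && length(out)) {
          out[length(out)] <- out[length(out)] + s
        } else {
          out <- c(out, s)
        }
      }
      # a small leading fragment merges rightward
      while (length(out) > 1L && out[1] < min_frag) {
        out[2] <- out[2] + out[1]
        out <- out[-1]
      }
      sizes <- out
    }
    restriction_map(true$enzyme, sizes, circular = circular)
  })
}

#' Write a complete synthetic fixture directory
#'
#' Emits `genome.fasta`, `contigs.fasta`, `reads.fastq`, `map.tsv` and
#' `truth.json` under `dir`, using the generators above.
#'
#' @param dir Output directory (created if needed).
#' @param genome_len Genome length (default 50000).
#' @param n_contigs Number of contigs (default 8).
#' @param coverage Read coverage (default 30).
#' @param p_overlap,p_revcomp,gap_range,overlap_range Passed to
#'   [fragment_genome()].
#' @param seed Integer RNG seed.
#' @return The `fragmentation_truth` object, invisibly.
#' @export
write_fixture <- function(dir, genome_len = 50000L, n_contigs = 8L,
                          coverage = 30, p_overlap = 0, p_revcomp = 0.4,
                          gap_range = c(200L, 800L),
                          overlap_range = c(50L, 300L), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(genome_len, seed = seed)
  truth <- fragment_genome(genome, n_contigs, gap_range = gap_range,
                           overlap_range = overlap_range,
                           p_overlap = p_overlap, p_revcomp = p_revcomp,
                           seed = seed + 1L)
  reads <- simulate_reads(genome, coverage, seed = seed + 2L)
  map <- simulate_restriction_map(genome, seed = seed + 3L)
  write_fasta(data.frame(id = "genome", seq = genome), file.path(dir, "genome.fasta"))
  write_fasta(truth$contigs, file.path(dir, "contigs.fasta"))
  write_fastq(reads, file.path(dir, "reads.fastq"))
  write_restriction_map(map, file.path(dir, "map.tsv"))
  jsonlite::write_json(
    list(genome_len = genome_len, n_contigs = n_contigs, coverage = coverage,
         seed = seed,
         true_placements = truth$true_placements,
         true_gap_lengths = vapply(truth$true_gaps,
                                   function(g) nchar(g$gap_seq), integer(1))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
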