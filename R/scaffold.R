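# Ordering and orienting contigs along a reference genome or an optical-map
# placement report, and assembling the ordered contigs into N-gapped
# scaffolds.

new_scaffold <- function(id, components, contigs, circular = FALSE) {
  stopifnot(all(c("contig_id", "strand", "gap_after") %in% names(components)))
  if (anyDuplicated(components$contig_id)) {
    stop("duplicate contig in scaffold: ",
         components$contig_id[duplicated(components$contig_id)][1])
  }
  seqs <- contig_seq(contigs, components$contig_id)
  seqs[components$strand == "-"] <- revcomp(seqs[components$strand == "-"])
  components$length <- nchar(seqs)
  n <- nrow(components)
  gaps <- components$gap_after
  gaps[n] <- NA_integer_
  parts <- character(2L * n - 1L)
  parts[seq(1L, 2L * n - 1L, by = 2L)] <- seqs
  if (n > 1L) {
    parts[seq(2L, 2L * n - 2L, by = 2L)] <-
      vapply(gaps[-n], function(g) strrep("N", g), character(1))
  }
  structure(list(id = id, components = components,
                 sequence = paste(parts, collapse = ""),
                 circular = isTRUE(circular)),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("<scaffold> %s: %d contig(s), %d bp%s\n", x$id,
              nrow(x$components), nchar(x$sequence),
              if (x$circular) ", circular" else ""))
  invisible(x)
}

#' Order and orient contigs along a reference genome
#'
#' Each contig is aligned to the reference with [local_align()]; its hits are
#' chained by subject locality and strand. A contig is placed iff its best
#' chain covers at least `min_coverage_frac` of its length and no rival chain
#' at a distinct locus scores within `ambiguity_margin` of the best
#' (repeat-ambiguous contigs are not placed). Contigs that fail are returned
#' as `unplaced`, never dropped.
#'
#' @param contigs Contig table (`id`, `seq`).
#' @param reference Reference genome sequence (single DNA string).
#' @param min_coverage_frac Minimum aligned fraction of the contig (default
#'   0.4).
#' @param min_contig_len Contigs shorter than this are left unplaced
#'   (default 200).
#' @param word_size,min_identity Passed to [local_align()].
#' @param ambiguity_margin Relative chain-score margin for ambiguity
#'   rejection (default 0.05).
#' @return `list(placements, unplaced)`: `placements` is a `data.frame` with
#'   `contig_id`, `axis`, `start`, `end`, `strand`, `rank`, `coverage_frac`
#'   (ranks by ascending reference start); `unplaced` is a character vector
#'   of contig ids.
#' @export
order_contigs_by_reference <- function(contigs, reference,
                                       min_coverage_frac = 0.4,
                                       min_contig_len = 200L,
                                       word_size = 11L, min_identity = 0.8,
                                       ambiguity_margin = 0.05) {
  stopifnot(nchar(reference) > 0L, min_coverage_frac > 0, min_coverage_frac <= 1)
  contigs <- as_contig_set(contigs)
  placements <- list()
  unplaced <- character(0)
  for (i in seq_len(nrow(contigs))) {
    id <- contigs$id[i]
    seq <- contigs$seq[i]
    len <- nchar(seq)
    if (len < min_contig_len) { unplaced <- c(unplaced, id); next }
    hits <- local_align(seq, reference, word_size = word_size,
                        min_identity = min_identity,
                        min_length = max(2L * word_size, 50L))
    if (nrow(hits) == 0L) { unplaced <- c(unplaced, id); next }
    ch <- chain_hits(hits, locality = max(len, 2000L))
    best <- ch[[1]]
    if (length(ch) >= 2L &&
        ch[[2]]$score >= (1 - ambiguity_margin) * best$score &&
        ch[[2]]$s_start != best$s_start) {
      unplaced <- c(unplaced, id)
      next
    }
    if (best$q_cov / len < min_coverage_frac) { unplaced <- c(unplaced, id); next }
    # project the full contig extent from the chain's dominant hit: robust
    # against short spurious repeat hits swept into the chain
    top <- best$top
    if (top$strand == "+") {
      start <- top$s_start - top$q_start
      end <- top$s_end + (len - top$q_end)
    } else {
      start <- top$s_start - (len - top$q_end)
      end <- top$s_end + top$q_start
    }
    placements[[length(placements) + 1L]] <- data.frame(
      contig_id = id, axis = "reference",
      start = max(0L, start), end = min(nchar(reference), end),
      strand = best$strand, rank = NA_integer_,
      coverage_frac = best$q_cov / len)
  }
  if (length(placements) == 0L) stop("no placements - wrong reference?")
  pl <- do.call(rbind, placements)
  pl <- pl[order(pl$start, pl$contig_id), ]
  pl$rank <- seq_len(nrow(pl))
  rownames(pl) <- NULL
  list(placements = pl, unplaced = unplaced)
}

# Chain hits of one contig: same strand, nearby on the subject.
# Returns a list of chains sorted by total score descending.
chain_hits <- function(hits, locality) {
  chains <- list()
  for (strand in c("+", "-")) {
    h <- hits[hits$strand == strand, ]
    if (nrow(h) == 0L) next
    h <- h[order(h$s_start), ]
    grp <- cumsum(c(1L, diff(h$s_start) > locality))
    for (g in unique(grp)) {
      m <- h[grp == g, ]
      qiv <- IRanges::reduce(IRanges::IRanges(m$q_start + 1L, m$q_end))
      chains[[length(chains) + 1L]] <- list(
        strand = strand, s_start = min(m$s_start), s_end = max(m$s_end),
        score = sum(m$score), q_cov = sum(IRanges::width(qiv)),
        top = m[which.max(m$score), ])
    }
  }
  chains[order(-vapply(chains, `[[`, numeric(1), "score"))]
}

#' Order contigs according to an optical-map placement report
#'
#' @param report Placement-report table (see [read_placement_report()]).
#' @param contigs Contig table; every reported `contig_id` must be present.
#' @return `list(placements, unplaced)` as in
#'   [order_contigs_by_reference()], with `axis = "optical_map"` and ranks
#'   normalized to `1..n`.
#' @export
order_contigs_by_map_report <- function(report, contigs) {
  contigs <- as_contig_set(contigs)
  missing <- setdiff(report$contig_id, contigs$id)
  if (length(missing)) stop("unknown contig ", missing[1])
  report <- report[order(report$rank), ]
  pl <- data.frame(contig_id = report$contig_id, axis = "optical_map",
                   start = report$map_start, end = report$map_end,
                   strand = report$strand, rank = seq_len(nrow(report)),
                   coverage_frac = NA_real_)
  list(placements = pl, unplaced = setdiff(contigs$id, report$contig_id))
}

#' Build an N-gapped scaffold from ranked placements
#'
#' Under the `axis_distance` policy the gap after placement i is
#' `max(start(i+1) - end(i), min_gap)`; an apparent overlap (negative axis
#' distance) yields a `min_gap` spacer and is flagged as a candidate merge
#' for the curation step. The `fixed` policy inserts `fixed_gap` Ns at every
#' junction (the NCBI unknown-gap convention is 100 N).
#'
#' @param placements Placement table with `contig_id`, `start`, `end`,
#'   `strand`, `rank`.
#' @param contigs Contig table.
#' @param gap_policy `"axis_distance"` or `"fixed"`.
#' @param fixed_gap Gap size for the `fixed` policy (default 100).
#' @param min_gap Gap floor for `axis_distance` (default 1).
#' @param circular Mark the scaffold circular.
#' @param id Scaffold identifier.
#' @return A `scaffold` object; junctions flagged as apparent overlaps are in
#'   `attr(, "candidate_merges")`.
#' @export
build_scaffold <- function(placements, contigs,
                           gap_policy = c("axis_distance", "fixed"),
                           fixed_gap = 100L, min_gap = 1L, circular = FALSE,
                           id = "scaffold_1") {
  gap_policy <- match.arg(gap_policy)
  contigs <- as_contig_set(contigs)
  pl <- placements[order(placements$rank), ]
  if (anyDuplicated(pl$contig_id)) {
    stop("duplicate contig in placements: ",
         pl$contig_id[duplicated(pl$contig_id)][1])
  }
  n <- nrow(pl)
  gaps <- rep(NA_integer_, n)
  merge_flags <- integer(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (gap_policy == "fixed") {
        gaps[i] <- as.integer(fixed_gap)
      } else {
        d <- pl$start[i + 1L] - pl$end[i]
        if (d < min_gap) merge_flags <- c(merge_flags, i)
        gaps[i] <- as.integer(max(d, min_gap))
      }
    }
  }
  comp <- data.frame(contig_id = pl$contig_id, strand = pl$strand,
                     gap_after = gaps)
  sc <- new_scaffold(id, comp, contigs, circular = circular)
  attr(sc, "candidate_merges") <- merge_flags
  sc
}
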