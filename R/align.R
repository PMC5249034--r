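# Seed-and-extend local alignment: the engine behind contig ordering,
# dovetail overlap detection, flank anchoring and syntenic comparison.

#' blastn-like alignment scoring scheme
#'
#' A gap of length L costs `gap_open + L * gap_ext`.
#'
#' @param match Match reward (default +2).
#' @param mismatch Mismatch penalty, negative (default -3).
#' @param gap_open Gap opening penalty, positive (default 5).
#' @param gap_ext Per-base gap extension penalty, positive (default 2).
#' @return A named list used by the alignment functions.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = 5L, gap_ext = 2L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_ext > 0)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext))
}

# One-strand call into the C++ core.
align_one_strand <- function(query, subject, word_size, scoring,
                             diag_tol = 100L, chain_gap = 1000L,
                             pad = 100L, band_pad = 50L,
                             max_occ = 5000L, max_clusters = 5000L) {
  cpp_local_align(query, subject, as.integer(word_size),
                  scoring$match, scoring$mismatch,
                  scoring$gap_open, scoring$gap_ext,
                  as.integer(diag_tol), as.integer(chain_gap),
                  as.integer(pad), as.integer(band_pad),
                  as.integer(max_occ), as.integer(max_clusters))
}

#' Local alignment of a query against a subject, both strands
#'
#' Maximal exact word matches of length `>= word_size` seed diagonal
#' clusters; each cluster is extended by a banded affine-gap local
#' Smith-Waterman. Hits below `min_identity` or `min_length` are discarded.
#' Subject coordinates are always on the subject forward strand; `strand`
#' records the query orientation. Homology without any shared word of
#' `word_size` bases is, by design, invisible.
#'
#' @param query,subject DNA strings over `{A,C,G,T,N}`.
#' @param word_size Seed word length (default 11, minimum 4).
#' @param min_identity Minimum hit identity in `[0,1]` (default 0.7).
#' @param min_length Minimum alignment length in bp (default 20).
#' @param scoring An [align_scoring()] list.
#' @param word_max_occ Seed words occurring more often than this in the
#'   subject are skipped (repeat guard).
#' @return A `data.frame` of hits with columns `q_start`, `q_end`, `s_start`,
#'   `s_end` (0-based half-open), `strand`, `identity`, `aln_length`,
#'   `matches`, `score`; sorted by score descending with deterministic
#'   tie-breaks (lower `s_start`, then lower `q_start`, then `+` before `-`).
#' @export
local_align <- function(query, subject, word_size = 11L, min_identity = 0.7,
                        min_length = 20L, scoring = align_scoring(),
                        word_max_occ = 5000L) {
  stopifnot(is.character(query), is.character(subject),
            nchar(query) > 0L, nchar(subject) > 0L)
  if (word_size < 4L) stop("word_size must be >= 4")
  fw <- align_one_strand(query, subject, word_size, scoring,
                         max_occ = word_max_occ)
  fw$strand <- rep("+", nrow(fw))
  rc <- align_one_strand(revcomp(query), subject, word_size, scoring,
                         max_occ = word_max_occ)
  rc$strand <- rep("-", nrow(rc))
  if (nrow(rc)) {
    qlen <- nchar(query)
    qs <- qlen - rc$q_end
    rc$q_end <- qlen - rc$q_start
    rc$q_start <- qs
  }
  hits <- rbind(fw, rc)
  if (nrow(hits) == 0L) return(empty_hits())
  hits$identity <- hits$matches / hits$aln_length
  hits <- hits[hits$identity >= min_identity & hits$aln_length >= min_length, ]
  if (nrow(hits) == 0L) return(empty_hits())
  hits <- dedupe_hits(hits)
  ord <- order(-hits$score, hits$s_start, hits$q_start,
               match(hits$strand, c("+", "-")))
  hits <- hits[ord, c("q_start", "q_end", "s_start", "s_end", "strand",
                      "identity", "aln_length", "matches", "score")]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(q_start = integer(0), q_end = integer(0), s_start = integer(0),
             s_end = integer(0), strand = character(0), identity = numeric(0),
             aln_length = integer(0), matches = integer(0), score = integer(0))
}

# Drop duplicate cluster extensions: hits whose query AND subject intervals
# mutually overlap a higher-scoring kept hit almost entirely. Containment
# alone is not enough (a repeat copy is contained in a self-identity hit
# but is a distinct alignment).
dedupe_hits <- function(hits, frac = 0.9) {
  ord <- order(-hits$score, hits$s_start, hits$q_start)
  hits <- hits[ord, ]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    dup <- FALSE
    for (j in which(keep)) {
      if (hits$strand[i] != hits$strand[j]) next
      qo <- min(hits$q_end[i], hits$q_end[j]) - max(hits$q_start[i], hits$q_start[j])
      so <- min(hits$s_end[i], hits$s_end[j]) - max(hits$s_start[i], hits$s_start[j])
      qi <- hits$q_end[i] - hits$q_start[i]
      qj <- hits$q_end[j] - hits$q_start[j]
      si <- hits$s_end[i] - hits$s_start[i]
      sj <- hits$s_end[j] - hits$s_start[j]
      if (qo > frac * max(qi, qj) && so > frac * max(si, sj)) {
        dup <- TRUE
        break
      }
    }
    keep[i] <- !dup
  }
  hits[keep, ]
}

#' Best unambiguous anchor of a flank on a subject
#'
#' Returns the top-scoring [local_align()] hit, or `NULL` when no hit
#' survives or when the top two hits at distinct subject loci score within
#' `ambiguity_margin` of each other: an ambiguous anchor (e.g. a repeat) is
#' not an anchor.
#'
#' @inheritParams local_align
#' @param flank The query flank sequence.
#' @param ambiguity_margin Relative score margin below which two
#'   distinct-locus hits count as ambiguous (default 0.05).
#' @return A one-row hit `data.frame`, or `NULL`.
#' @export
best_anchor <- function(flank, subject, min_identity = 0.8, min_length = 50L,
                        word_size = 11L, scoring = align_scoring(),
                        ambiguity_margin = 0.05) {
  stopifnot(nchar(flank) >= min_length)
  hits <- local_align(flank, subject, word_size = word_size,
                      min_identity = min_identity, min_length = min_length,
                      scoring = scoring)
  if (nrow(hits) == 0L) return(NULL)
  top <- hits[1, ]
  if (nrow(hits) >= 2L) {
    challenger <- hits[2, ]
    distinct <- challenger$s_start != top$s_start || challenger$strand != top$strand
    if (distinct && challenger$score >= (1 - ambiguity_margin) * top$score) {
      return(NULL)
    }
  }
  top
}

#' Chained syntenic blocks between two assemblies
#'
#' Aligns `asm_a` against `asm_b` and reports non-overlapping high-identity
#' blocks of at least `min_block` bp, for assembly-to-assembly comparison.
#' Blocks never overlap on either axis, so their total length is bounded by
#' the shorter assembly.
#'
#' @param asm_a,asm_b DNA strings (single sequences).
#' @param min_block Minimum block length in bp (default 1000, minimum 100).
#' @param word_size Seed word length for the block search (default 15:
#'   whole-genome comparison needs longer, quieter seeds).
#' @param min_identity Minimum block identity (default 0.7).
#' @return A `data.frame` with columns `a_start`, `a_end`, `b_start`,
#'   `b_end`, `strand`, `identity`, `length`, sorted by `a_start`.
#' @export
syntenic_blocks <- function(asm_a, asm_b, min_block = 1000L, word_size = 15L,
                            min_identity = 0.7) {
  if (min_block < 100L) stop("min_block must be >= 100")
  hits <- local_align(asm_a, asm_b, word_size = word_size,
                      min_identity = min_identity, min_length = min_block,
                      scoring = align_scoring(), word_max_occ = 200L)
  if (nrow(hits) == 0L) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      length = integer(0)))
  }
  # greedy by score: small boundary overlaps (extension overhang into a
  # neighbouring block) are tolerated here and clipped away below
  slack <- 200L
  keep <- integer(0)
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in keep) {
      qo <- min(hits$q_end[i], hits$q_end[j]) - max(hits$q_start[i], hits$q_start[j])
      so <- min(hits$s_end[i], hits$s_end[j]) - max(hits$s_start[i], hits$s_start[j])
      if (qo > slack || so > slack) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  hits <- hits[keep, ]
  out <- data.frame(a_start = hits$q_start, a_end = hits$q_end,
                    b_start = hits$s_start, b_end = hits$s_end,
                    strand = hits$strand, identity = hits$identity,
                    length = hits$aln_length)
  # clip to strictly disjoint intervals on both axes
  out <- out[order(out$a_start), ]
  if (nrow(out) > 1L) {
    for (i in 2:nrow(out)) {
      out$a_start[i] <- max(out$a_start[i], max(out$a_end[seq_len(i - 1L)]))
    }
  }
  out <- out[out$a_start < out$a_end, ]
  out <- out[order(out$b_start), ]
  if (nrow(out) > 1L) {
    for (i in 2:nrow(out)) {
      out$b_start[i] <- max(out$b_start[i], max(out$b_end[seq_len(i - 1L)]))
    }
  }
  out <- out[out$b_start < out$b_end, ]
  out$length <- pmin(out$length, out$a_end - out$a_start,
                     out$b_end - out$b_start)
  out <- out[out$length >= 1L, ]
  out <- out[order(out$a_start), ]
  rownames(out) <- NULL
  out
}

#' Write syntenic blocks as a 7-column TSV
#'
#' @param blocks Output of [syntenic_blocks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_syntenic_blocks <- function(blocks, path) {
  write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
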