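# Finishing operations on a scaffold: replication-start correction,
# supercontig merging by dovetail flank overlap, and flank-anchored gap
# closing backed by a read-pileup consensus.

#' Rotate a circular genome so it starts at the reference's replication start
#'
#' A probe of `probe_len` bases from the start of the reference is located
#' on the (circular) genome with [best_anchor()]; the genome is rotated so
#' the probe's first base becomes position 0. If the probe anchors on the
#' reverse strand the genome is reverse-complemented first. The result is a
#' pure rotation/reflection of the input. Applying the operation twice
#' equals applying it once.
#'
#' @param genome Circular genome sequence (DNA string).
#' @param reference Reference genome whose position 0 is the desired start.
#' @param probe_len Probe length in bp (default 2000).
#' @param min_identity Minimum anchor identity (default 0.8).
#' @return The rotated (and possibly reflected) genome string.
#' @export
set_origin <- function(genome, reference, probe_len = 2000L,
                       min_identity = 0.8) {
  len <- nchar(genome)
  probe_len <- min(as.integer(probe_len), nchar(reference), len)
  probe <- substring(reference, 1L, probe_len)
  anc <- origin_anchor(probe, genome)
  if (is.null(anc)) stop("origin not found")
  if (anc$strand == "-") {
    genome <- revcomp(genome)
    anc <- origin_anchor(probe, genome)
    if (is.null(anc) || anc$strand != "+") stop("origin not found")
  }
  p <- anc$s_start %% len
  # the anchor may start a few bases into the probe; shift accordingly
  p <- (p - anc$q_start) %% len
  if (p == 0L) return(genome)
  paste0(substring(genome, p + 1L, len), substring(genome, 1L, p))
}

# Anchor a probe on a circular genome: search the doubled genome and treat
# positions equal modulo the genome length as one locus for the ambiguity
# rule.
origin_anchor <- function(probe, genome, ambiguity_margin = 0.05) {
  len <- nchar(genome)
  doubled <- paste0(genome, substring(genome, 1L, min(len, nchar(probe))))
  hits <- local_align(probe, doubled, min_identity = 0.8,
                      min_length = min(50L, nchar(probe)))
  if (nrow(hits) == 0L) return(NULL)
  hits$locus <- hits$s_start %% len
  top <- hits[1, ]
  rival <- hits[hits$locus != top$locus | hits$strand != top$strand, ]
  if (nrow(rival) && rival$score[1] >= (1 - ambiguity_margin) * top$score) {
    stop("origin not found: ambiguous anchor (repeat at origin?)")
  }
  top
}

#' Merge neighbouring scaffold contigs that share a dovetail overlap
#'
#' For each adjacent contig pair the last `flank_len` bases of the left
#' contig are aligned against the first `flank_len` bases of the right
#' contig (both after orientation). A merge requires a dovetail hit: the
#' alignment must reach the left contig's end and the right contig's start
#' within `end_slack` bases, span at least `min_overlap` bases and have
#' identity at least `min_identity`. The merged supercontig keeps the left
#' contig's copy of the overlap verbatim. Merging iterates until no pair
#' qualifies. Overlaps shorter than `word_size` cannot seed an alignment and
#' are therefore never detected.
#'
#' @param scaffold A `scaffold` object.
#' @param contigs Contig table backing the scaffold.
#' @param min_overlap Minimum overlap length in bp (default 20).
#' @param min_identity Minimum overlap identity (default 0.95).
#' @param flank_len Flank window per side in bp (default 3000).
#' @param word_size Seed word length (default 11).
#' @param end_slack Dovetail end tolerance in bp (default 10).
#' @return `list(scaffold, contigs, merges)`: the rebuilt scaffold, the
#'   contig table with supercontigs added, and a `data.frame` describing
#'   each merge.
#' @export
merge_neighbor_contigs <- function(scaffold, contigs, min_overlap = 20L,
                                   min_identity = 0.95, flank_len = 3000L,
                                   word_size = 11L, end_slack = 10L) {
  stopifnot(inherits(scaffold, "scaffold"))
  contigs <- as_contig_set(contigs)
  comp <- scaffold$components
  # work on oriented sequences; merged products are '+' by construction
  work <- data.frame(
    contig_id = comp$contig_id,
    seq = ifelse(comp$strand == "-",
                 revcomp(contig_seq(contigs, comp$contig_id)),
                 contig_seq(contigs, comp$contig_id)),
    gap_after = comp$gap_after,
    stringsAsFactors = FALSE)
  merges <- data.frame(left = character(0), right = character(0),
                       overlap_len = integer(0), identity = numeric(0))
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(work)) {
      left <- work$seq[i]
      right <- work$seq[i + 1L]
      lf <- substring(left, max(1L, nchar(left) - flank_len + 1L), nchar(left))
      rf <- substring(right, 1L, min(flank_len, nchar(right)))
      hit <- dovetail_hit(lf, rf, min_overlap, min_identity, word_size,
                          end_slack)
      if (!is.null(hit)) {
        overlap_len <- nchar(lf) - hit$s_start
        new_id <- paste0(work$contig_id[i], "+", work$contig_id[i + 1L])
        new_seq <- paste0(left, substring(right, hit$q_end + 1L))
        merges <- rbind(merges, data.frame(
          left = work$contig_id[i], right = work$contig_id[i + 1L],
          overlap_len = overlap_len, identity = hit$identity))
        work$contig_id[i] <- new_id
        work$seq[i] <- new_seq
        work$gap_after[i] <- work$gap_after[i + 1L]
        work <- work[-(i + 1L), ]
        merged_any <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged_any) break
  }
  new_contigs <- data.frame(id = work$contig_id, seq = work$seq,
                            source = "merge_neighbor_contigs")
  comp2 <- data.frame(contig_id = work$contig_id, strand = "+",
                      gap_after = work$gap_after)
  sc <- new_scaffold(scaffold$id, comp2, new_contigs,
                     circular = scaffold$circular)
  list(scaffold = sc, contigs = new_contigs, merges = merges)
}

# A dovetail hit: right-contig prefix (query) against left-contig suffix
# (subject), reaching the subject's end and the query's start.
dovetail_hit <- function(left_flank, right_flank, min_overlap, min_identity,
                         word_size, end_slack) {
  hits <- local_align(right_flank, left_flank, word_size = word_size,
                      min_identity = min_identity,
                      min_length = max(min_overlap, word_size))
  hits <- hits[hits$strand == "+" &
                 hits$q_start <= end_slack &
                 hits$s_end >= nchar(left_flank) - end_slack &
                 hits$aln_length >= min_overlap &
                 hits$identity >= min_identity, ]
  if (nrow(hits) == 0L) return(NULL)
  hits[1, ]
}

#' Map reads onto a template and build a pileup consensus
#'
#' Each read is placed at its best seed-supported location on either strand
#' and locally aligned to the template window it covers. The consensus base
#' of each template column is the majority over aligned bases (ties resolve
#' to the template base); columns whose majority vote is a deletion are
#' dropped; insertions relative to the template are accepted when supported
#' by more than half of the reads spanning the junction. Columns with no
#' coverage emit the template base with depth 0.
#'
#' @param reads A `read_set` (see [read_fastq()]) or character vector of
#'   read sequences.
#' @param template Template DNA string.
#' @param seed_len Seed length for read placement (default 15).
#' @param min_read_identity Minimum alignment identity for a read to be used
#'   (default 0.8).
#' @param scoring An [align_scoring()] list.
#' @return `list(consensus, depth, col_map, n_mapped)`: `depth[i]` is the
#'   number of reads aligned over consensus column i, and `col_map[i]` the
#'   0-based template column it derives from (`NA` for inserted columns).
#' @export
map_reads_to_template <- function(reads, template, seed_len = 15L,
                                  min_read_identity = 0.8,
                                  scoring = align_scoring()) {
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  stopifnot(nchar(template) > 0L)
  if (length(seqs) == 0L) {
    return(list(consensus = template, depth = rep(0L, nchar(template)),
                col_map = seq_len(nchar(template)) - 1L, n_mapped = 0L))
  }
  res <- cpp_map_reads(seqs, template, as.integer(seed_len),
                       min_read_identity, 0.5,
                       scoring$match, scoring$mismatch, scoring$gap_open,
                       scoring$gap_ext, 40L)
  res$col_map[res$col_map < 0L] <- NA_integer_
  res
}

#' Close one inter-contig gap by flank anchoring and consensus extraction
#'
#' The last `flank_len` bases of the left contig and the first `flank_len`
#' bases of the right contig are anchored on the reference (targets A and
#' B). The reference is trimmed to the window spanning both anchors plus
#' `pad` bases of context, reads are mapped into the window, and the flanks
#' are re-anchored on the resulting consensus (targets C and D). The
#' consensus between C's end and D's start is extracted as the gap fill.
#' The gap is `closed` when every fill base has read depth at least
#' `min_depth` and no N remains; `partial` when a depth-failing sub-interval
#' had to be N-masked; `unresolved` when an anchor is missing, ambiguous,
#' discordant, or the anchors are out of order.
#'
#' @param left,right Oriented contig sequences flanking the gap (left's end
#'   abuts the gap; right's start abuts it).
#' @param reference Reference genome sequence.
#' @param reads A `read_set` or character vector of read sequences.
#' @param flank_len Flank length in bp (default 3000).
#' @param pad Reference context around the anchors in bp (default 500).
#' @param min_depth Minimum read depth for a closed base (default 3).
#' @param min_identity Minimum anchor identity (default 0.8).
#' @param end_slack Tolerated anchor overlap in bp (default 10).
#' @return A list of class `gap_resolution`: `status` (`closed`, `partial`,
#'   `unresolved`), `fill_seq`, `support` (minimum depth across the fill),
#'   `method`, `reason`, and the four targets.
#' @export
close_gap <- function(left, right, reference, reads, flank_len = 3000L,
                      pad = 500L, min_depth = 3L, min_identity = 0.8,
                      end_slack = 10L) {
  unresolved <- function(reason) {
    structure(list(status = "unresolved", fill_seq = "", support = 0L,
                   method = "consensus_extraction", reason = reason,
                   target_a = NULL, target_b = NULL,
                   target_c = NULL, target_d = NULL),
              class = "gap_resolution")
  }
  lf <- substring(left, max(1L, nchar(left) - flank_len + 1L), nchar(left))
  rf <- substring(right, 1L, min(flank_len, nchar(right)))
  a <- best_anchor(lf, reference, min_identity = min_identity)
  b <- best_anchor(rf, reference, min_identity = min_identity)
  if (is.null(a)) return(unresolved("ambiguous or missing anchor for left flank"))
  if (is.null(b)) return(unresolved("ambiguous or missing anchor for right flank"))
  if (a$strand != "+" || b$strand != "+") {
    return(unresolved("anchors not co-oriented on reference forward strand"))
  }
  if (a$s_end > b$s_start + nchar(lf)) {
    return(unresolved("anchors out of order on reference"))
  }
  wlo <- max(0L, a$s_start - pad)
  whi <- min(nchar(reference), b$s_end + pad)
  if (whi <= wlo) return(unresolved("empty or reversed reference window"))
  window <- substring(reference, wlo + 1L, whi)

  mp <- map_reads_to_template(reads, window)
  cons <- mp$consensus
  cc <- best_anchor(lf, cons, min_identity = min_identity)
  d <- best_anchor(rf, cons, min_identity = min_identity)
  if (is.null(cc)) return(unresolved("left flank not anchored on consensus"))
  if (is.null(d)) return(unresolved("right flank not anchored on consensus"))
  if (cc$strand != "+" || d$strand != "+") {
    return(unresolved("consensus anchors not co-oriented"))
  }
  if (d$s_start < cc$s_end - end_slack) {
    return(unresolved("consensus anchors overlap beyond slack"))
  }
  res <- structure(list(status = "closed", fill_seq = "",
                        support = as.integer(min_depth),
                        method = "consensus_extraction", reason = "",
                        target_a = a, target_b = b,
                        target_c = cc, target_d = d),
                   class = "gap_resolution")
  if (d$s_start <= cc$s_end) {
    # contigs abut (or overlap within slack): nothing to fill
    return(res)
  }
  fill <- substring(cons, cc$s_end + 1L, d$s_start)
  depth <- mp$depth[(cc$s_end + 1L):d$s_start]
  res$support <- as.integer(min(depth))
  low <- depth < min_depth
  bases <- strsplit(fill, "")[[1]]
  if (any(low) || any(bases == "N")) {
    bases[low] <- "N"
    res$fill_seq <- paste(bases, collapse = "")
    res$status <- "partial"
    res$reason <- "insufficient read depth across part of the fill"
  } else {
    res$fill_seq <- fill
  }
  res
}

#' @export
print.gap_resolution <- function(x, ...) {
  cat(sprintf("<gap_resolution> %s (%s): fill %d bp, min depth %d%s\n",
              x$status, x$method, nchar(x$fill_seq), x$support,
              if (nzchar(x$reason)) paste0(" [", x$reason, "]") else ""))
  invisible(x)
}
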