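# In-silico restriction digestion and concordance scoring against an
# experimental (optical / whole-genome mapping) restriction map.

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param site Recognition site over `{A,C,G,T}`.
#' @param cut_offset Cut position within the site, `0 <= cut_offset <=
#'   nchar(site)`.
#' @return An object of class `enzyme`.
#' @export
#' @examples
#' enzyme("KpnI", "GGTACC", 1L)
enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (nchar(site) < 1L || grepl("[^ACGT]", site)) {
    stop("enzyme site must be a non-empty string over {A,C,G,T}")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(site)) {
    stop("cut_offset must lie within the site")
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "enzyme")
}

#' The built-in default enzyme, KpnI (GGTACC, cut after the first base)
#'
#' @return An [enzyme()] object.
#' @export
kpnI <- function() enzyme("KpnI", "GGTACC", 1L)

# 0-based site start positions on the forward strand (overlaps allowed).
site_starts <- function(seq, enz) {
  m <- Biostrings::matchPattern(enz$site, Biostrings::DNAString(seq))
  sort(BiocGenerics::start(m) - 1L)
}

# 0-based cut positions. Linear: cuts strictly inside (0, len).
# Circular: cuts in [0, len), including wrap-around site occurrences.
digest_cuts <- function(seq, enz, circular) {
  len <- nchar(seq)
  w <- nchar(enz$site)
  if (circular) {
    ext <- paste0(seq, substring(seq, 1L, min(len, w - 1L)))
    starts <- site_starts(ext, enz)
    starts <- starts[starts < len]
    sort(unique((starts + enz$cut_offset) %% len))
  } else {
    cuts <- site_starts(seq, enz) + enz$cut_offset
    cuts[cuts > 0L & cuts < len]
  }
}

#' In-silico restriction digestion
#'
#' Cut positions are every forward-strand occurrence of the site (overlapping
#' occurrences included), offset by the enzyme's cut offset. A linear
#' molecule with n cuts yields n+1 fragments (terminal fragments included); a
#' circular molecule yields n fragments, listed starting from the smallest
#' cut position. Fragment sizes always sum to `nchar(seq)`.
#'
#' @param seq DNA string.
#' @param enz An [enzyme()] (default [kpnI()]).
#' @param circular Is the molecule circular?
#' @return A [restriction_map()].
#' @export
digest_sequence <- function(seq, enz = kpnI(), circular = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  len <- nchar(seq)
  cuts <- digest_cuts(seq, enz, circular)
  if (length(cuts) == 0L) {
    return(restriction_map(enz$name, len, circular = circular))
  }
  sizes <- if (circular) {
    diff(c(cuts, cuts[1] + len))
  } else {
    diff(c(0L, cuts, len))
  }
  restriction_map(enz$name, sizes, circular = circular)
}

# Lexicographically minimal rotation of an integer vector (circular maps),
# returned as the index order realizing it.
canonical_order <- function(sizes) {
  n <- length(sizes)
  if (n <= 1L) return(seq_len(n))
  keys <- vapply(seq_len(n), function(k) {
    ord <- c(k:n, seq_len(k - 1L))
    paste(sprintf("%012d", sizes[ord]), collapse = ",")
  }, character(1))
  k <- which(keys == min(keys))[1]
  c(k:n, seq_len(k - 1L))
}

canonical_rotation <- function(sizes) sizes[canonical_order(sizes)]

#' Concordance between a scaffold's in-silico digest and an experimental map
#'
#' The scaffold is digested in silico and its fragment list is matched in
#' order, pairwise, against the experimental list. Two fragments match when
#' `|a - b| / max(a, b) <= size_tolerance`; in-silico fragments that span an
#' N gap are matched with doubled tolerance (their true size is uncertain
#' because the gap estimate is). Circular maps are canonicalized to their
#' lexicographically minimal rotation before matching, so the score is
#' rotation-invariant.
#'
#' @param scaffold A `scaffold` object (or any list with `$sequence` and
#'   `$circular`).
#' @param enz An [enzyme()] (default [kpnI()]).
#' @param experimental A [restriction_map()].
#' @param size_tolerance Relative size tolerance (default 0.10).
#' @return `list(score, matched_pairs)`: `score` = matched fragments /
#'   max(list lengths); `matched_pairs` a `data.frame` of matched positions
#'   and sizes.
#' @export
map_concordance <- function(scaffold, enz = kpnI(), experimental,
                            size_tolerance = 0.10) {
  stopifnot(inherits(experimental, "restriction_map"))
  if (length(experimental$sizes) == 0L) stop("empty map")
  seq <- scaffold$sequence
  circ <- isTRUE(scaffold$circular)
  len <- nchar(seq)
  insil <- digest_sequence(seq, enz, circular = circ)

  # flag in-silico fragments spanning an N run
  cuts <- digest_cuts(seq, enz, circ)
  starts <- if (circ) {
    if (length(cuts)) cuts else 0L
  } else {
    c(0L, cuts)
  }
  runs <- n_runs(seq)
  spans_n <- vapply(seq_along(insil$sizes), function(i) {
    if (nrow(runs) == 0L) return(FALSE)
    s <- starts[i]
    e <- s + insil$sizes[i]  # may wrap past len when circular
    any(runs$start < e & runs$end > s) ||
      (e > len && any(runs$start < (e - len)))
  }, logical(1))

  a <- insil$sizes
  b <- experimental$sizes
  if (insil$circular) {
    ord <- canonical_order(a)
    a <- a[ord]
    spans_n <- spans_n[ord]
  }
  if (experimental$circular) b <- canonical_rotation(b)

  n <- min(length(a), length(b))
  matched <- logical(n)
  for (i in seq_len(n)) {
    tol <- if (spans_n[i]) 2 * size_tolerance else size_tolerance
    matched[i] <- abs(a[i] - b[i]) / max(a[i], b[i]) <= tol
  }
  idx <- which(matched)
  pairs <- data.frame(insilico_index = idx, experimental_index = idx,
                      insilico_size = a[idx], experimental_size = b[idx])
  list(score = sum(matched) / max(length(a), length(b)),
       matched_pairs = pairs)
}

#' Write a concordance report as TSV
#'
#' @param concordance Output of [map_concordance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concordance_report <- function(concordance, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# concordance_score\t%.6f", concordance$score), con)
  write.table(concordance$matched_pairs, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
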