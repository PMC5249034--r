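# Low-level DNA string helpers. Sequences are plain uppercase character
# strings over {A,C,G,T,N}; all coordinates are 0-based half-open.

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# Uppercase and squash anything outside {A,C,G,T,N} to N.
# Returns list(seq, n_replaced).
normalize_dna <- function(x) {
  up <- toupper(x)
  bad <- nchar(gsub("[ACGTN]", "", up))
  list(seq = gsub("[^ACGTN]", "N", up), n_replaced = sum(bad))
}

# GC fraction over called bases (N excluded from the denominator).
gc_fraction <- function(seq) {
  n_gc <- nchar(gsub("[^GC]", "", seq))
  n_at <- nchar(gsub("[^AT]", "", seq))
  tot <- sum(n_gc) + sum(n_at)
  if (tot == 0L) return(NA_real_)
  sum(n_gc) / tot
}

# Runs of N in one sequence as a data.frame(start, end), 0-based half-open.
n_runs <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- as.integer(m) - 1L
  data.frame(start = start, end = start + attr(m, "match.length"))
}

# Evaluate code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validated contig table shared by most operations.
as_contig_set <- function(contigs) {
  stopifnot(is.data.frame(contigs), all(c("id", "seq") %in% names(contigs)))
  if (!"source" %in% names(contigs)) contigs$source <- ""
  if (anyDuplicated(contigs$id)) {
    stop("duplicate id ", contigs$id[duplicated(contigs$id)][1])
  }
  if (any(grepl("[[:space:]]", contigs$id))) stop("contig id contains whitespace")
  if (any(nchar(contigs$seq) < 1L)) stop("empty contig sequence")
  if (any(grepl("[^ACGTN]", contigs$seq))) stop("contig sequence outside {A,C,G,T,N}")
  contigs[, c("id", "seq", "source")]
}

contig_seq <- function(contigs, id) {
  i <- match(id, contigs$id)
  if (anyNA(i)) stop("unknown contig ", id[which(is.na(i))[1]])
  contigs$seq[i]
}
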