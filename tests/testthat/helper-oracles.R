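# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive implementations, kept free of any code
# path they are used to check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Full Smith-Waterman score under the package's default scoring scheme
# (match +2, mismatch -3, gap of length L costs 5 + 2L), via Biostrings.
sw_score <- function(q, s) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)))
}

# Global percent identity between two sequences (alignment columns).
global_pid <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  Biostrings::pid(Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)) / 100
}

# Exhaustive k-mer intersection check: do a and b share any k-mer?
shares_kmer <- function(a, b, k) {
  ka <- substring(a, seq_len(nchar(a) - k + 1L), seq_len(nchar(a) - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(nchar(b) - k + 1L), seq_len(nchar(b) - k + 1L) + k - 1L)
  length(intersect(ka, kb)) > 0L
}

# Generate a pair of unrelated sequences verified (by the oracle above) to
# share no k-mer on either strand.
unrelated_pair <- function(n, k) {
  repeat {
    a <- random_dna(n)
    b <- random_dna(n)
    if (!shares_kmer(a, b, k) && !shares_kmer(finishr::revcomp(a), b, k)) {
      return(list(a = a, b = b))
    }
  }
}

# Naive O(n*m) restriction digest: compare the site against every position.
naive_digest <- function(seq, site, cut_offset, circular) {
  len <- nchar(seq)
  m <- nchar(site)
  scan_seq <- if (circular) paste0(seq, substring(seq, 1L, m - 1L)) else seq
  idx <- seq_len(min(nchar(scan_seq) - m + 1L, len))
  starts <- idx[substring(scan_seq, idx, idx + m - 1L) == site] - 1L
  cuts <- starts + cut_offset
  if (circular) {
    cuts <- sort(unique(cuts %% len))
    if (length(cuts) == 0L) return(len)
    return(diff(c(cuts, cuts[1] + len)))
  }
  cuts <- cuts[cuts > 0L & cuts < len]
  if (length(cuts) == 0L) return(len)
  diff(c(0L, cuts, len))
}

# Brute-force Nx: the largest L such that contigs >= L sum to >= frac*total.
naive_nx <- function(lens, frac) {
  total <- sum(as.numeric(lens))
  best <- NA_integer_
  for (L in sort(unique(lens), decreasing = TRUE)) {
    if (sum(as.numeric(lens[lens >= L])) >= frac * total) {
      best <- L
      break
    }
  }
  best
}

# Point-mutate a sequence at given 1-based positions (deterministic cycle).
mutate_at <- function(seq, positions) {
  bases <- strsplit(seq, "")[[1]]
  for (p in positions) {
    bases[p] <- setdiff(c("A", "C", "G", "T"), bases[p])[1]
  }
  paste(bases, collapse = "")
}

# A pair with a planted homologous segment inside random flanks: the regime
# the seed-and-extend aligner is built for.
homologous_pair <- function(max_len = 600L) {
  slen <- sample(300:max_len, 1L)
  subj <- random_dna(slen)
  a <- sample.int(slen - 150L, 1L)
  b <- a + sample(100:149, 1L)
  seg <- strsplit(substring(subj, a, b), "")[[1]]
  for (m in which(runif(length(seg)) < 0.05)) {
    seg[m] <- sample(setdiff(c("A", "C", "G", "T"), seg[m]), 1L)
  }
  seg <- paste(seg, collapse = "")
  if (runif(1) < 0.3) {  # occasionally plant a short indel
    p <- sample(20:(nchar(seg) - 20L), 1L)
    if (runif(1) < 0.5) {
      seg <- paste0(substring(seg, 1, p), random_dna(sample(1:3, 1L)),
                    substring(seg, p + 1L))
    } else {
      seg <- paste0(substring(seg, 1, p), substring(seg, p + sample(1:3, 1L) + 1L))
    }
  }
  list(query = paste0(random_dna(30L), seg, random_dna(30L)), subject = subj)
}
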