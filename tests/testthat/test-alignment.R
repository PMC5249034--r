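# The seed-and-extend local aligner against a full Smith-Waterman oracle,
# plus anchoring and syntenic-block behaviour.

test_that("aligning a sequence to itself yields one full-span perfect hit", {
  set.seed(101)
  s <- random_dna(500)
  h <- local_align(s, s)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(0L, 500L, 0L, 500L))
  expect_equal(h$strand, "+")
})

test_that("a reverse-complement query is found on the minus strand", {
  set.seed(102)
  s <- random_dna(400)
  h <- local_align(revcomp(s), s)
  expect_equal(h$strand[1], "-")
  expect_equal(h$identity[1], 1)
  expect_equal(c(h$s_start[1], h$s_end[1]), c(0L, 400L))
})

test_that("pairs sharing no seed word produce no hits", {
  set.seed(103)
  for (i in 1:5) {
    pr <- unrelated_pair(100L, 11L)  # oracle-verified: no shared 11-mer
    expect_equal(nrow(local_align(pr$a, pr$b)), 0L)
  }
})

test_that("a mutated substring is located exactly with SW-optimal score", {
  set.seed(104)
  s <- random_dna(1500)
  q <- mutate_at(substring(s, 1001, 1300), c(60, 150, 240))
  h <- local_align(q, s)
  expect_equal(h$s_start[1], 1000L)
  expect_equal(h$s_end[1], 1300L)
  expect_equal(h$identity[1], 297 / 300)
  expect_equal(h$score[1], sw_score(q, s))
})

test_that("top hit score equals the full Smith-Waterman optimum on homologous pairs", {
  set.seed(105)
  for (i in 1:40) {
    pr <- homologous_pair()
    h <- local_align(pr$query, pr$subject)
    expect_gt(nrow(h), 0L)
    expect_equal(h$score[1], sw_score(pr$query, pr$subject))
  }
})

test_that("hits are antisymmetric under query reverse-complement", {
  set.seed(106)
  s <- random_dna(2000)
  q <- paste0(substring(s, 201, 700), random_dna(50),
              revcomp(substring(s, 1201, 1500)))
  a <- local_align(q, s)
  b <- local_align(revcomp(q), s)
  expect_equal(nrow(a), nrow(b))
  key <- function(h, qlen) {
    sort(paste(h$s_start, h$s_end, h$score, qlen - h$q_end, qlen - h$q_start,
               ifelse(h$strand == "+", "-", "+"), sep = ":"))
  }
  keyb <- sort(paste(b$s_start, b$s_end, b$score, b$q_start, b$q_end, b$strand,
                     sep = ":"))
  expect_equal(key(a, nchar(q)), keyb)
})

test_that("an extra mismatch never increases the top score", {
  set.seed(107)
  s <- random_dna(800)
  q <- substring(s, 101, 500)
  base <- local_align(q, s)$score[1]
  for (p in c(50, 150, 250, 350)) {
    worse <- local_align(mutate_at(q, p), s)$score[1]
    expect_lte(worse, base)
  }
})

test_that("best_anchor returns the unique locus and rejects ambiguity", {
  set.seed(108)
  subj <- random_dna(5000)
  flank <- substring(subj, 2001, 2500)
  a <- best_anchor(flank, subj)
  expect_equal(a$s_start, 2000L)

  # the same flank planted twice: ambiguous, so no anchor
  rep2 <- paste0(random_dna(500), flank, random_dna(500), flank, random_dna(500))
  expect_null(best_anchor(flank, rep2))

  # no match at all
  pr <- unrelated_pair(200L, 11L)
  expect_null(best_anchor(paste0(pr$a, pr$a, pr$a), pr$b))
})

test_that("syntenic blocks recover identity, inversions, and nothing for unrelated pairs", {
  set.seed(109)
  a <- generate_genome(30000, seed = 31)
  blocks <- syntenic_blocks(a, a, min_block = 1000L)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$length, 30000L)
  expect_equal(blocks$strand, "+")

  # invert the central 10 kb
  b <- paste0(substring(a, 1, 10000), revcomp(substring(a, 10001, 20000)),
              substring(a, 20001, 30000))
  blocks <- syntenic_blocks(a, b, min_block = 1000L)
  expect_equal(nrow(blocks), 3L)
  expect_equal(blocks$strand, c("+", "-", "+"))
  expect_lte(sum(blocks$length), 30000L)

  # oracle-verified unrelated pair (no shared 15-mer on either strand)
  pr <- unrelated_pair(1200L, 15L)
  expect_equal(nrow(syntenic_blocks(pr$a, pr$b, min_block = 100L)), 0L)
})
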