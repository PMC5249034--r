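# Seeded generators: determinism, composition contracts, and the
# self-checked fragmentation truth.

test_that("generators are pure functions of their parameters and seed", {
  expect_identical(generate_genome(2000, seed = 7), generate_genome(2000, seed = 7))
  expect_false(identical(generate_genome(2000, seed = 7),
                         generate_genome(2000, seed = 8)))
  g <- generate_genome(5000, seed = 9)
  r1 <- simulate_reads(g, 5, seed = 10)
  r2 <- simulate_reads(g, 5, seed = 10)
  expect_identical(r1$seq, r2$seq)
  m1 <- simulate_restriction_map(g, seed = 11)
  expect_identical(m1$sizes, simulate_restriction_map(g, seed = 11)$sizes)
  f1 <- fragment_genome(g, 4, seed = 12)
  expect_identical(f1$contigs, fragment_genome(g, 4, seed = 12)$contigs)
})

test_that("generated GC content tracks the request", {
  g <- generate_genome(100000, gc = 0.5, seed = 13)
  gc <- nchar(gsub("[^GC]", "", g)) / nchar(g)
  expect_lt(abs(gc - 0.5), 0.02)
  g2 <- generate_genome(100000, gc = 0.65, seed = 14)
  gc2 <- nchar(gsub("[^GC]", "", g2)) / nchar(g2)
  expect_lt(abs(gc2 - 0.65), 0.02)
})

test_that("planted repeats occur the requested number of times", {
  g <- generate_genome(30000, repeat_spec = list(c(2000, 2)), seed = 15)
  # find the duplicated 2 kb unit: it aligns to two loci
  hits <- local_align(g, g)
  expect_gte(nrow(hits[hits$aln_length >= 1900 & hits$q_start != hits$s_start, ]), 1L)
  expect_error(generate_genome(1000, repeat_spec = list(c(400, 5)), seed = 16),
               "exceed")
})

test_that("fragmentation truth reassembles the genome for varied parameters", {
  g <- generate_genome(20000, seed = 17)
  grid <- expand.grid(p_overlap = c(0, 0.5, 1), p_revcomp = c(0, 0.5, 1))
  for (i in seq_len(nrow(grid))) {
    fr <- fragment_genome(g, 5, p_overlap = grid$p_overlap[i],
                          p_revcomp = grid$p_revcomp[i], seed = 18 + i)
    # check_reassembly ran at generation; re-verify the placements map back
    for (j in seq_len(nrow(fr$true_placements))) {
      pl <- fr$true_placements[j, ]
      s <- finishr:::contig_seq(fr$contigs, pl$contig_id)
      if (pl$strand == "-") s <- revcomp(s)
      expect_equal(s, substring(g, pl$start + 1L, pl$end))
    }
  }
})

test_that("gap-only fragmentation concatenates to the genome minus gaps", {
  g <- generate_genome(20000, seed = 30)
  fr <- fragment_genome(g, 4, p_overlap = 0, p_revcomp = 0, shuffle = FALSE,
                        seed = 31)
  gap_total <- sum(vapply(fr$true_gaps, function(x) nchar(x$gap_seq), integer(1)))
  expect_equal(sum(nchar(fr$contigs$seq)) + gap_total, nchar(g))
})

test_that("every contig appears in the genome when all are reverse-complemented", {
  g <- generate_genome(15000, seed = 32)
  fr <- fragment_genome(g, 4, p_revcomp = 1, seed = 33)
  for (s in fr$contigs$seq) expect_true(grepl(revcomp(s), g, fixed = TRUE))
})

test_that("error-free reads are exact substrings and coverage is honoured", {
  g <- generate_genome(50000, seed = 34)
  reads <- simulate_reads(g, 30, indel_rate = 0, sub_rate = 0, seed = 35)
  doubled <- paste0(g, g)
  set.seed(36)
  for (s in sample(reads$seq, 25)) {
    expect_true(grepl(s, doubled, fixed = TRUE) ||
                  grepl(revcomp(s), doubled, fixed = TRUE))
  }
  total <- sum(nchar(reads$seq))
  expect_gte(total, 0.95 * 30 * 50000)
  expect_lte(total, 1.05 * 30 * 50000)
})

test_that("simulated maps reduce to the true digest in the noise-free limit", {
  g <- generate_genome(40000, seed = 37)
  noiseless <- simulate_restriction_map(g, sizing_error = 0, min_frag = 0,
                                        seed = 38)
  expect_equal(noiseless$sizes, digest_sequence(g, kpnI(), circular = TRUE)$sizes)

  coarse <- simulate_restriction_map(g, sizing_error = 0, min_frag = 5000L,
                                     seed = 39)
  expect_lte(length(coarse$sizes), length(noiseless$sizes))
  expect_equal(sum(coarse$sizes), sum(noiseless$sizes))
  expect_true(all(coarse$sizes >= 5000L) || length(coarse$sizes) == 1L)
})
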