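# Origin correction, dovetail merging, read mapping/consensus, and the
# flank-anchored gap-closing procedure.

test_that("set_origin undoes rotation and reflection exactly", {
  g <- generate_genome(15000, seed = 61)
  rot <- paste0(substring(g, 12346), substring(g, 1, 12345))
  expect_equal(set_origin(rot, g), g)
  refl <- revcomp(paste0(substring(g, 501), substring(g, 1, 500)))
  expect_equal(set_origin(refl, g), g)
})

test_that("set_origin is idempotent and errors without an anchor", {
  g <- generate_genome(15000, seed = 62)
  rot <- paste0(substring(g, 7001), substring(g, 1, 7000))
  once <- set_origin(rot, g)
  expect_equal(set_origin(once, g), once)

  # a reference whose start (the probe region) is foreign to the genome
  set.seed(63)
  alien_ref <- paste0(random_dna(2000), substring(g, 2001))
  expect_error(set_origin(g, alien_ref), "origin not found")
})

test_that("exact dovetail overlaps merge with exact length arithmetic", {
  set.seed(64)
  a <- random_dna(4000)
  b <- paste0(substring(a, 3851), random_dna(4000))  # 150 bp shared dovetail
  ctg <- data.frame(id = c("a", "b"), seq = c(a, b))
  pl <- data.frame(contig_id = c("a", "b"), start = c(0L, 3850L),
                   end = c(4000L, 7850L), strand = "+", rank = 1:2)
  sc <- build_scaffold(pl, ctg)
  mg <- merge_neighbor_contigs(sc, ctg)
  expect_equal(nrow(mg$merges), 1L)
  expect_equal(mg$merges$overlap_len, 150L)
  expect_equal(nchar(mg$contigs$seq[1]), 4000L + 4150L - 150L)
  # merge conserves sequence: left + right[overlap:] exactly
  expect_equal(mg$contigs$seq[1], paste0(a, substring(b, 151)))
})

test_that("overlaps shorter than the seed word length are never merged", {
  set.seed(65)
  a <- random_dna(3000)
  b <- paste0(substring(a, 2993), random_dna(3000))  # 8 bp < word_size 11
  ctg <- data.frame(id = c("a", "b"), seq = c(a, b))
  pl <- data.frame(contig_id = c("a", "b"), start = c(0L, 2992L),
                   end = c(3000L, 6000L), strand = "+", rank = 1:2)
  mg <- merge_neighbor_contigs(build_scaffold(pl, ctg), ctg)
  expect_equal(nrow(mg$merges), 0L)
  expect_equal(nrow(mg$contigs), 2L)
})

test_that("an internal repeat shared by neighbours does not license a merge", {
  set.seed(66)
  rep200 <- random_dna(200)
  a <- paste0(random_dna(1400), rep200, random_dna(1400))  # repeat mid-contig
  b <- paste0(random_dna(1400), rep200, random_dna(1400))
  ctg <- data.frame(id = c("a", "b"), seq = c(a, b))
  pl <- data.frame(contig_id = c("a", "b"), start = c(0L, 3100L),
                   end = c(3000L, 6100L), strand = "+", rank = 1:2)
  mg <- merge_neighbor_contigs(build_scaffold(pl, ctg), ctg)
  expect_equal(nrow(mg$merges), 0L)
})

test_that("error-free tiled reads reproduce the template exactly", {
  g <- generate_genome(6000, seed = 67)
  starts <- c(seq(1, 5801, by = 20), 5801)  # 10x tiling incl. both ends
  reads <- substring(g, starts, starts + 199)
  mp <- map_reads_to_template(reads, g)
  expect_equal(mp$consensus, g)
  expect_gte(min(mp$depth), 1L)
  expect_equal(length(mp$depth), nchar(mp$consensus))
  expect_equal(length(mp$col_map), nchar(mp$consensus))
})

test_that("a unanimous SNP in the reads overrides the template base", {
  set.seed(69)
  truth <- random_dna(1000)
  template <- mutate_at(truth, 500)  # template disagrees with all reads
  starts <- seq(1, 801, by = 40)
  reads <- substring(truth, starts, starts + 199)
  mp <- map_reads_to_template(reads, template)
  expect_equal(mp$consensus, truth)
})

test_that("consensus from noisy reads recovers a mutated truth", {
  g <- generate_genome(8000, seed = 70)
  set.seed(71)
  truth <- mutate_at(g, sample.int(8000, 20))  # template is 20 SNPs away
  reads <- simulate_reads(truth, 30, indel_rate = 0.01, sub_rate = 0.002,
                          circular = FALSE, seed = 72)
  mp <- map_reads_to_template(reads, g)
  expect_gte(global_pid(mp$consensus, truth), 0.995)
})

test_that("an empty read set yields the template with zero depth", {
  g <- generate_genome(2000, seed = 73)
  mp <- map_reads_to_template(character(0), g)
  expect_equal(mp$consensus, g)
  expect_equal(mp$depth, rep(0L, nchar(g)))
})

test_that("a gap flanked by anchored contigs is closed with the true sequence", {
  g <- generate_genome(30000, seed = 74)
  reads <- simulate_reads(g, 30, seed = 75)
  res <- close_gap(substring(g, 1, 12000), substring(g, 14001, 26000), g, reads)
  expect_equal(res$status, "closed")
  expect_gte(res$support, 3L)
  expect_gte(global_pid(res$fill_seq, substring(g, 12001, 14000)), 0.99)
})

test_that("without read coverage a gap is never closed", {
  g <- generate_genome(20000, seed = 76)
  res <- close_gap(substring(g, 1, 8000), substring(g, 9001, 18000), g,
                   character(0))
  expect_true(res$status %in% c("partial", "unresolved"))
  # every fill base is N-masked, none fabricated
  expect_equal(gsub("N", "", res$fill_seq), "")
})

test_that("a repeat at the flank makes the gap unresolved, not guessed", {
  set.seed(77)
  rep3k <- random_dna(3000)
  ref <- paste0(random_dna(2000), rep3k, random_dna(3000), rep3k,
                random_dna(2000))
  left <- paste0(random_dna(2000), rep3k)  # flank == the duplicated repeat
  right <- substring(ref, 11001, 13000)
  reads <- simulate_reads(ref, 20, circular = FALSE, seed = 78)
  res <- close_gap(left, right, ref, reads)
  expect_equal(res$status, "unresolved")
  expect_match(res$reason, "ambiguous")
})

test_that("closed fills are depth-supported at every base", {
  g <- generate_genome(25000, seed = 79)
  reads <- simulate_reads(g, 30, seed = 80)
  res <- close_gap(substring(g, 1, 10000), substring(g, 10501, 22000), g,
                   reads, min_depth = 3L)
  expect_equal(res$status, "closed")
  expect_gte(res$support, 3L)
  expect_false(grepl("N", res$fill_seq))
})
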