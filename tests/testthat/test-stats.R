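# Assembly metrics, the unknown-nucleotide report, and assembly comparison.

test_that("metrics match hand-checked cases", {
  m <- assembly_metrics(data.frame(id = "a", seq = random_dna(100)))
  expect_equal(m$n50, 100L)
  expect_equal(m$largest, 100L)
  expect_equal(m$total_len, 100L)

  ctg <- data.frame(id = sprintf("c%d", 1:5),
                    seq = vapply(c(50, 40, 30, 20, 10), random_dna, character(1)))
  m <- assembly_metrics(ctg)
  expect_equal(m$n50, naive_nx(c(50, 40, 30, 20, 10), 0.5))
  expect_equal(m$n50, 40L)
  expect_gte(m$n50, m$n90)

  m <- assembly_metrics(data.frame(id = "n", seq = strrep("N", 10)))
  expect_equal(m$n_count, 10L)
  expect_equal(nrow(m$gap_intervals), 1L)
  expect_equal(c(m$gap_intervals$start, m$gap_intervals$end), c(0L, 10L))
})

test_that("N50/N90 agree with the brute-force cumulative-sum oracle", {
  set.seed(81)
  for (i in 1:200) {
    lens <- sample.int(5000, sample(1:30, 1), replace = TRUE)
    expect_equal(finishr:::nx_length(lens, 0.5), naive_nx(lens, 0.5))
    expect_equal(finishr:::nx_length(lens, 0.9), naive_nx(lens, 0.9))
  }
})

test_that("unknown-nucleotide report counts runs and conserves totals", {
  rep1 <- unknown_nucleotide_report(data.frame(id = "s1", seq = "ACGTNNNACGT"))
  expect_equal(rep1$summary$n_count[1], 3L)
  expect_equal(rep1$summary$n_frac[1], 3 / 11)
  expect_equal(nrow(rep1$runs), 1L)
  expect_equal(rep1$runs$length, 3L)

  clean <- unknown_nucleotide_report(data.frame(id = "s1", seq = "ACGT"))
  expect_equal(nrow(clean$runs), 0L)

  two <- unknown_nucleotide_report(data.frame(
    id = c("s1", "s2"), seq = c("ANNGT", "NNNNACGTN")))
  tot <- two$summary[two$summary$id == "TOTAL", ]
  expect_equal(tot$n_count, sum(two$summary$n_count[two$summary$id != "TOTAL"]))
  expect_equal(tot$n_run_count, nrow(two$runs))
})

test_that("identical genomes compare as one full block with zero difference", {
  g <- generate_genome(20000, seed = 82)
  cmp <- compare_assemblies(g, g)
  expect_equal(nrow(cmp$blocks), 1L)
  expect_equal(cmp$length_diff, 0L)
  expect_equal(nrow(cmp$uncovered_new), 0L)
  expect_equal(nrow(cmp$candidate_misassemblies), 0L)
})

test_that("an insertion in the new assembly is reported as uncovered length", {
  g <- generate_genome(30000, seed = 83)
  set.seed(84)
  ins <- random_dna(5000)
  new <- paste0(substring(g, 1, 15000), ins, substring(g, 15001))
  cmp <- compare_assemblies(g, new)
  expect_equal(cmp$length_diff, 5000L)
  unc <- sum(cmp$uncovered_new$end - cmp$uncovered_new$start)
  expect_gte(unc, 4000L)
  expect_lte(unc, 6000L)
  # conservation: covered + uncovered == new length exactly
  cov <- sum(cmp$blocks$b_end - cmp$blocks$b_start)
  expect_equal(cov + unc, nchar(new))
})

test_that("an inverted segment is flagged as a candidate mis-assembly", {
  g <- generate_genome(30000, seed = 85)
  new <- paste0(substring(g, 1, 10000), revcomp(substring(g, 10001, 20000)),
                substring(g, 20001))
  cmp <- compare_assemblies(g, new)
  expect_true(any(cmp$candidate_misassemblies$inversion))
  expect_equal(cmp$length_diff, 0L)
})
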