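# Contig ordering along both axes, scaffold construction arithmetic,
# in-silico digestion, and restriction-map concordance.

test_that("contigs cut from a reference are re-ordered and re-oriented exactly", {
  g <- generate_genome(20000, seed = 41)
  fr <- fragment_genome(g, 5, p_revcomp = 0.4, shuffle = TRUE, seed = 42)
  ord <- order_contigs_by_reference(fr$contigs, g)
  pl <- ord$placements
  tr <- fr$true_placements
  expect_equal(pl$contig_id[order(pl$rank)], tr$contig_id[order(tr$rank)])
  expect_equal(pl$strand[match(tr$contig_id, pl$contig_id)], tr$strand)
  expect_length(ord$unplaced, 0L)
})

test_that("a random contig absent from the reference is reported unplaced", {
  g <- generate_genome(10000, seed = 43)
  fr <- fragment_genome(g, 3, shuffle = FALSE, seed = 44)
  set.seed(45)
  repeat {  # oracle: the alien contig must share no seed word with g
    alien <- random_dna(500)
    if (!shares_kmer(alien, g, 11L) && !shares_kmer(revcomp(alien), g, 11L)) break
  }
  ctg <- rbind(fr$contigs, data.frame(id = "alien", seq = alien, source = "x"))
  ord <- order_contigs_by_reference(ctg, g)
  expect_true("alien" %in% ord$unplaced)
  expect_equal(nrow(ord$placements), 3L)
})

test_that("no placement at all is a hard error", {
  set.seed(46)
  pr <- unrelated_pair(300L, 11L)
  expect_error(
    order_contigs_by_reference(data.frame(id = "c1", seq = pr$a), pr$b),
    "no placements")
})

test_that("map-report ordering copies the report and flags unknown contigs", {
  ctg <- data.frame(id = c("c1", "c2", "c3"),
                    seq = c(random_dna(300), random_dna(300), random_dna(300)))
  rep <- data.frame(contig_id = c("c2", "c1"), map_start = c(0L, 600L),
                    map_end = c(400L, 900L), strand = c("+", "-"), rank = 1:2)
  ord <- order_contigs_by_map_report(rep, ctg)
  expect_equal(ord$placements$contig_id, c("c2", "c1"))
  expect_equal(ord$placements$axis, rep("optical_map", 2))
  expect_equal(ord$unplaced, "c3")

  rep$contig_id[1] <- "cX"
  expect_error(order_contigs_by_map_report(rep, ctg), "unknown contig cX")
})

test_that("scaffold gaps follow the axis-distance arithmetic", {
  ctg <- data.frame(id = c("a", "b", "c"),
                    seq = vapply(rep(100, 3), random_dna, character(1)))
  pl <- data.frame(contig_id = c("a", "b", "c"), start = c(0L, 150L, 300L),
                   end = c(100L, 250L, 400L), strand = "+", rank = 1:3)
  sc <- build_scaffold(pl, ctg)
  expect_equal(sc$components$gap_after[1:2], c(50L, 50L))
  expect_equal(nchar(sc$sequence), 400L)

  # apparent overlap: floored gap plus a candidate-merge flag
  pl2 <- pl[1:2, ]
  pl2$start[2] <- 80L
  pl2$end[2] <- 180L
  sc2 <- build_scaffold(pl2, ctg)
  expect_equal(sc2$components$gap_after[1], 1L)
  expect_equal(attr(sc2, "candidate_merges"), 1L)

  # single placement: scaffold is that contig
  sc3 <- build_scaffold(pl[1, ], ctg)
  expect_equal(sc3$sequence, ctg$seq[1])

  expect_error(build_scaffold(rbind(pl, pl[1, ]), ctg), "duplicate contig")
})

test_that("fixed gap policy inserts the configured spacer", {
  ctg <- data.frame(id = c("a", "b"), seq = c(random_dna(50), random_dna(50)))
  pl <- data.frame(contig_id = c("a", "b"), start = c(0L, 60L),
                   end = c(50L, 110L), strand = "+", rank = 1:2)
  sc <- build_scaffold(pl, ctg, gap_policy = "fixed", fixed_gap = 100L)
  expect_equal(nchar(sc$sequence), 200L)
  expect_equal(nchar(gsub("[^N]", "", sc$sequence)), 100L)
})

test_that("digestion matches hand-computed cuts and conserves length", {
  # KpnI GGTACC with cut offset 1: site at 0-based 2 cuts at 3
  m <- digest_sequence("AAGGTACCAA", kpnI(), circular = FALSE)
  expect_equal(m$sizes, c(3L, 7L))

  g <- generate_genome(5000, seed = 47)
  expect_equal(digest_sequence(gsub("GGTACC", "GGTACA", g), kpnI(),
                               circular = TRUE)$sizes,
               nchar(gsub("GGTACC", "GGTACA", g)))

  # three planted circular sites: three fragments summing to the length
  set.seed(48)
  base <- random_dna(3000)
  base <- gsub("GGTACC", "ATATAT", base)
  s <- paste0(substring(base, 1, 1000), "GGTACC", substring(base, 1001, 2000),
              "GGTACC", substring(base, 2001, 2500), "GGTACC",
              substring(base, 2501, 3000))
  mc <- digest_sequence(s, kpnI(), circular = TRUE)
  expect_length(mc$sizes, 3L)
  expect_equal(sum(mc$sizes), nchar(s))
})

test_that("digestion agrees with the naive site-scan oracle", {
  set.seed(49)
  enzymes <- list(kpnI(), enzyme("EcoRI", "GAATTC", 1L),
                  enzyme("HpaII", "CCGG", 1L), enzyme("polyA", "AAAA", 2L))
  for (i in 1:60) {
    seq <- random_dna(sample(200:1500, 1), gc = runif(1, 0.3, 0.7))
    enz <- enzymes[[sample.int(4, 1)]]
    circ <- i %% 2 == 0
    got <- digest_sequence(seq, enz, circular = circ)
    expect_equal(got$sizes, as.integer(naive_digest(seq, enz$site,
                                                    enz$cut_offset, circ)))
    expect_equal(sum(got$sizes), nchar(seq))
  }
})

test_that("concordance is perfect for the true genome and rotation-invariant", {
  set.seed(50)
  g <- generate_genome(40000, seed = 51)
  sc <- list(sequence = g, circular = TRUE)
  exp_map <- digest_sequence(g, kpnI(), circular = TRUE)
  res <- map_concordance(sc, kpnI(), exp_map)
  expect_equal(res$score, 1.0)

  # rotate the experimental fragment list: score unchanged
  n <- length(exp_map$sizes)
  if (n > 1L) {
    for (k in c(2L, n)) {
      rot <- restriction_map(exp_map$enzyme,
                             exp_map$sizes[c(k:n, seq_len(k - 1L))],
                             circular = TRUE)
      expect_equal(map_concordance(sc, kpnI(), rot)$score, res$score)
    }
  }
})

test_that("a single perturbed fragment costs exactly one match", {
  set.seed(52)
  g <- generate_genome(40000, seed = 53)
  sc <- list(sequence = g, circular = FALSE)
  exp_map <- digest_sequence(g, kpnI(), circular = FALSE)
  n <- length(exp_map$sizes)
  expect_gt(n, 2L)
  sizes <- exp_map$sizes
  sizes[2] <- round(sizes[2] * 1.25)
  res <- map_concordance(sc, kpnI(),
                         restriction_map("KpnI", sizes, circular = FALSE))
  expect_equal(res$score, (n - 1) / n)
})

test_that("an unrelated experimental map scores low", {
  g1 <- generate_genome(100000, seed = 54)
  g2 <- generate_genome(100000, seed = 55)
  sc <- list(sequence = g1, circular = TRUE)
  unrelated <- digest_sequence(g2, kpnI(), circular = TRUE)
  expect_lt(map_concordance(sc, kpnI(), unrelated)$score, 0.3)
})
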