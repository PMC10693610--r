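# NG86 site/difference counting, Ka/Ks, block summaries, mixture peaks.

test_that("site counting matches brute-force enumeration of mutational neighbors", {
  # brute-force oracle values for hand-picked codons
  expect_equal(countSites("TTT")$s_sites, bf_sites("TTT")[["s"]])
  expect_equal(countSites("TTT")$s_sites, 1 / 3)
  expect_equal(countSites("TTT")$n_sites, 8 / 3)
  expect_equal(countSites("ATG")$s_sites, 0)   # Met: single-codon amino acid
  expect_equal(countSites("ATG")$n_sites, 3)
  # stop-neighbor handling (Trp): mutations to stops are nonsynonymous
  expect_equal(countSites("TGG")$s_sites, bf_sites("TGG")[["s"]])
  # totals are sums over codons, and n + s = 3L
  set.seed(41)
  gene <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  cs <- countSites(gene)
  expect_equal(cs$n_sites + cs$s_sites, 3 * cs$codons_counted)
  # N-containing and gap codons are skipped
  expect_equal(countSites("ATGNNN---")$codons_counted, 1L)
  expect_error(countSites("ATGA"), "multiple of 3")
})

test_that("codon difference counting averages over stop-free pathways", {
  expect_equal(countDifferences("TTT", "TTC"), c(nd = 0, sd = 1))
  expect_equal(countDifferences("AAA", "AAA"), c(nd = 0, sd = 0))
  d <- countDifferences("TTT", "ATG")
  expect_equal(unname(d), unname(bf_diffs("TTT", "ATG")))
  expect_equal(sum(d), 2)  # two differing positions
  # a triple-difference pair, averaged over the 6 orderings
  d3 <- countDifferences("AAA", "CCC")
  expect_equal(unname(d3), unname(bf_diffs("AAA", "CCC")))
  expect_equal(sum(d3), 3)
  # stop codon input is a skip signal, not an error
  expect_true(all(is.na(countDifferences("TAA", "AAA"))))
  expect_error(countDifferences("ANA", "AAA"), "ambiguous")
})

test_that("computeKaKs agrees with the brute-force NG86 oracle", {
  set.seed(7)
  for (i in 1:100) {
    p <- random_codon_pair(40)
    got <- computeKaKs(p[1], p[2])
    if (!got@usable) next
    want <- bf_kaks(p[1], p[2])
    expect_equal(got@nSites, want$n_sites, tolerance = 1e-12)
    expect_equal(got@sSites, want$s_sites, tolerance = 1e-12)
    expect_equal(got@nd, want$nd, tolerance = 1e-12)
    expect_equal(got@sd, want$sd, tolerance = 1e-12)
    expect_equal(ksValue(got), want$ks, tolerance = 1e-12)
    expect_equal(kaValue(got), want$ka, tolerance = 1e-12)
  }
})

test_that("computeKaKs is symmetric and conserves site totals", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_codon_pair(40)
    a <- computeKaKs(p[1], p[2])
    b <- computeKaKs(p[2], p[1])
    expect_identical(ksValue(a), ksValue(b))
    expect_identical(kaValue(a), kaValue(b))
    expect_equal(a@nSites + a@sSites, 3 * a@usableCodons, tolerance = 1e-9)
  }
})

test_that("identical sequences give Ka = Ks = 0", {
  s <- strrep("ATGGCTTGC", 12)
  r <- computeKaKs(s, s)
  expect_equal(ksValue(r), 0)
  expect_equal(kaValue(r), 0)
  expect_false(r@saturated)
})

test_that("synonymous saturation (pS >= 3/4) flags the result and voids Ks", {
  # every codon a synonymous difference: pS = 1/ (1/3 sites) = 3
  r <- computeKaKs(strrep("TTT", 40), strrep("TTC", 40))
  expect_true(r@saturated)
  expect_true(is.na(ksValue(r)))
  expect_false(is.na(kaValue(r)))
})

test_that("alignments with fewer than 30 comparable codons are flagged unusable", {
  r <- computeKaKs(strrep("ATG", 10), strrep("ATG", 10))
  expect_false(r@usable)
  expect_true(is.na(ksValue(r)))
  # no exception raised
  expect_s4_class(r, "KsResult")
})

test_that("the Jukes-Cantor correction is strictly increasing below saturation", {
  p <- seq(0, 0.74, by = 0.01)
  d <- allopolykit:::.jcCorrect(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d[-1] > p[-1]))  # correction inflates observed proportions
  expect_true(is.na(allopolykit:::.jcCorrect(0.75)))
})

test_that("block summaries average usable pairs and flag thin blocks", {
  anchors <- data.frame(
    gene_a = sprintf("a%d", 1:7), gene_b = sprintf("b%d", 1:7),
    block_id = c(rep("blk1", 3), rep("blk2", 4)),
    chr_a = "chr01", chr_b = "chr01", stringsAsFactors = FALSE)
  results <- data.frame(
    gene_a = sprintf("a%d", 1:7), gene_b = sprintf("b%d", 1:7),
    ks = c(0.1, 0.2, 0.3, 0.1, 0.2, 10, 0.4),
    usable = c(rep(TRUE, 5), FALSE, TRUE), stringsAsFactors = FALSE)
  out <- blockSummary(anchors, results, minPairs = 3L)
  expect_equal(out$ks[out$block_id == "blk1"], 0.2)
  expect_equal(out$n_usable[out$block_id == "blk2"], 3L)
  # saturated pair excluded from the median as well
  med <- blockSummary(anchors, results, stat = "median", minPairs = 3L)
  expect_equal(med$ks[med$block_id == "blk2"], 0.2)
  # default threshold: blocks with fewer than 5 usable pairs are flagged
  expect_true(all(blockSummary(anchors, results)$flagged))
  expect_false(any(out$flagged))
  # a pair without a Ks result is an error
  expect_error(blockSummary(anchors, results[-1, ], minPairs = 3L),
               "no Ks result")
})

test_that("mixture fitting recovers a single Gaussian Ks peak", {
  set.seed(31)
  v <- rnorm(2000, 0.3, 0.05)
  pm <- fitKsPeaks(v, kMax = 4, seed = 13)
  expect_equal(nPeaks(pm), 1L)
  expect_equal(peakMeans(pm), 0.3, tolerance = 0.01 / 0.3)
  expect_equal(sum(pm@weights), 1, tolerance = 1e-9)
})

test_that("mixture fitting rejects degenerate or insufficient input", {
  expect_error(fitKsPeaks(rep(0.2, 100)), "degenerate")
  expect_error(fitKsPeaks(rnorm(20, 0.3, 0.05)), "at least")
  # values outside (0, cap] are filtered before the count check
  expect_error(fitKsPeaks(c(rep(-1, 100), rnorm(10, 0.3, 0.01))), "at least")
})
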