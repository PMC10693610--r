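# Fractionation statistics, DE calling, HEB classification, ortholog-DEG
# concordance, tandem-duplicate summaries.

test_that("retention profiles count retained copies per chromosome", {
  anchors <- data.frame(
    gene_a = c(sprintf("a%d", 1:13), rep(NA, 2)),
    gene_b = c(sprintf("b%d", 1:10), rep(NA, 3), "b14", "b15"),
    chr_a = "chr01", chr_b = "chr01", stringsAsFactors = FALSE)
  prof <- retentionProfile(anchors)
  g <- prof[prof$chromosome == "global", ]
  expect_equal(g$retained_a, 13)
  expect_equal(g$retained_b, 12)
  expect_equal(g$pairs, 10)
  expect_equal(g$lost_a, 2)
  expect_equal(g$lost_b, 3)
  expect_error(retentionProfile(anchors[0, ]), "empty")
  bad <- anchors; bad$gene_a[1] <- NA; bad$gene_b[1] <- NA
  expect_error(retentionProfile(bad), "at least one")
})

test_that("fractionation bias test matches the exact binomial tail", {
  mk <- function(la, lb) data.frame(
    chromosome = c("chr01", "global"), retained_a = 0, retained_b = 0,
    lost_a = la, lost_b = lb, pairs = 0)
  even <- fractionationBiasTest(mk(50, 50))
  expect_equal(even$global$p, 1.0)
  skew <- fractionationBiasTest(mk(75, 25))
  # oracle: direct summation of the two-sided exact binomial tail
  probs <- dbinom(0:100, 100, 0.5)
  p_direct <- sum(probs[probs <= dbinom(75, 100, 0.5) + 1e-12])
  expect_equal(skew$global$p, p_direct, tolerance = 1e-9)
  expect_lt(skew$global$p, 0.01)
  # degenerate single singleton: two-sided p = 1, flagged low power
  one <- fractionationBiasTest(mk(1, 0))
  expect_equal(one$per_chromosome$p, 1.0)
  expect_true(one$per_chromosome$flagged)
  zero <- fractionationBiasTest(mk(0, 0))
  expect_true(is.na(zero$global$p))
})

test_that("fractionation simulation and test cohere under null and bias", {
  null <- simulateFractionation(10000, 0.2, 0.2, seed = 91)
  p_null <- fractionationBiasTest(retentionProfile(null))$global$p
  expect_gt(p_null, 0.05)
  biased <- simulateFractionation(10000, 0.3, 0.1, seed = 92)
  res <- fractionationBiasTest(retentionProfile(biased))
  expect_lt(res$global$p, 1e-6)
  prof <- retentionProfile(biased)
  g <- prof[prof$chromosome == "global", ]
  expect_lt(g$retained_a, g$retained_b)
})

test_that("row-wise Welch tests agree with stats::t.test", {
  set.seed(71)
  a <- matrix(rnorm(80, 5), 20)
  b <- matrix(rnorm(80, 5.5), 20)
  rw <- allopolykit:::.rowWelch(a, b)
  for (i in c(1, 7, 20)) {
    tt <- t.test(a[i, ], b[i, ])
    expect_equal(rw$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(rw$delta[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("DE calling applies both the fold-change gate and the FDR gate", {
  set.seed(5)
  n <- 1000; spike <- 1:100
  mu <- matrix(rnorm(n, 5, 1.5), n, 8)
  mu[spike, 1:4] <- mu[spike, 1:4] + 2  # 4-fold induction
  tpm <- 2^(mu + matrix(rnorm(n * 8, 0, 0.35), n))
  rownames(tpm) <- sprintf("g%04d", 1:n)
  se <- makeExpressionSet(tpm, rep(c("trt", "ctl"), each = 4))
  de <- callDE(se, "trt", "ctl")
  expect_gte(sum(de$de[spike]), 95)
  expect_lte(sum(de$de[-spike]), ceiling(0.05 * sum(de$de)))
  expect_true(all(de$direction[de$de & de$log2fc > 0] == "up"))

  # identical replicate sets: no DE at all
  same <- makeExpressionSet(cbind(tpm[, 1:4], tpm[, 1:4]),
                            rep(c("x", "y"), each = 4))
  expect_equal(sum(callDE(same, "x", "y")$de), 0)
  expect_error(callDE(se, "missing", "ctl"), "condition not found")
})

test_that("a sub-threshold fold change is not DE no matter how small its p", {
  set.seed(9)
  base <- rnorm(200, 8, 0.002)
  tpm <- 2^cbind(matrix(base, 50), matrix(base + 0.926, 50))  # 1.9-fold
  rownames(tpm) <- sprintf("g%d", 1:50)
  se <- makeExpressionSet(tpm, rep(c("a", "b"), each = 4))
  de <- callDE(se, "b", "a")
  expect_lt(min(de$padj), 1e-6)   # overwhelmingly significant...
  expect_equal(sum(de$de), 0)     # ...but gated by the 2-fold requirement
})

test_that("HEB classification is unbiased on equal copies and flips on swap", {
  se <- fixture_expression(mu_a = rep(5, 50), mu_b = rep(5, 50), seed = 3)
  calls <- hebClassify(se)
  expect_true(all(calls$call %in% c("UNBIASED", "UNTESTABLE")))

  se2 <- fixture_expression(mu_a = c(rep(3, 20), rep(6, 30)),
                            mu_b = c(rep(6, 20), rep(3, 30)), seed = 4)
  calls2 <- hebClassify(se2)
  # swapping the copy annotation turns every A-biased call into B-biased
  rd <- SummarizedExperiment::rowData(se2)
  pairs_swapped <- data.frame(
    pair_id = rd$pair_id[rd$copy == "A"],
    gene_a = rownames(se2)[rd$copy == "B"],
    gene_b = rownames(se2)[rd$copy == "A"])
  calls_sw <- hebClassify(se2, pairs = pairs_swapped)
  map <- c(A_BIASED = "B_BIASED", B_BIASED = "A_BIASED",
           UNBIASED = "UNBIASED", UNTESTABLE = "UNTESTABLE")
  expect_identical(unname(map[calls2$call]), calls_sw$call)
  expect_identical(calls2$log2_ratio, -calls_sw$log2_ratio)
})

test_that("pairs below the expression filter are untestable", {
  se <- fixture_expression(mu_a = rep(-6, 30), mu_b = rep(-6, 30), seed = 6)
  calls <- hebClassify(se, minTpm = 1)
  expect_true(all(calls$call == "UNTESTABLE"))
  expect_error(hebClassify(se, pairs = data.frame(
    pair_id = "x", gene_a = "nope_A", gene_b = "nope_B")), "not in expression")
})

test_that("HEB summaries respect counting identities", {
  calls <- rbind(
    data.frame(pair_id = "p1", condition = c("c1", "c2"),
               call = c("B_BIASED", "B_BIASED")),
    data.frame(pair_id = "p2", condition = c("c1", "c2"),
               call = c("A_BIASED", "UNBIASED")),
    data.frame(pair_id = "p3", condition = c("c1", "c2"),
               call = c("UNBIASED", "UNBIASED")),
    data.frame(pair_id = "p4", condition = c("c1", "c2"),
               call = c("A_BIASED", "B_BIASED")))
  calls$log2_ratio <- 0; calls$padj <- NA_real_
  s <- hebSummary(calls)
  expect_equal(s$biased_any, 3)
  expect_equal(s$biased_all, 1)        # p4 flips direction, p1 is consistent
  expect_lte(s$biased_all, s$biased_any)
  expect_lte(s$biased_any, s$n_pairs)
  s2 <- hebSummary(calls, requireSameDirection = FALSE)
  expect_equal(s2$biased_all, 2)
  # single condition: "any" and "all" coincide
  one <- calls[calls$condition == "c1", ]
  s1 <- hebSummary(one)
  expect_equal(s1$biased_any, s1$biased_all)
  # all-unbiased input
  calls0 <- fixture_heb_calls(100, 0)
  expect_equal(hebSummary(calls0)$percent_b_biased, 0)
})

test_that("ortholog DEG concordance compares tissue-direction patterns", {
  fx <- fixture_concordance(99, 52)
  res <- orthologDegConcordance(fx$deg1, fx$deg2, fx$map)
  expect_equal(res$summary$n, 99)
  expect_equal(res$summary$conserved, 52)
  expect_equal(res$summary$percent_conserved, 53)
  # all identical patterns: 100% conserved
  all_same <- fixture_concordance(20, 20)
  expect_equal(orthologDegConcordance(all_same$deg1, all_same$deg2,
                                      all_same$map)$summary$percent_conserved,
               100)
  # identical genes, opposite directions: 0%
  none <- fixture_concordance(20, 0)
  expect_equal(orthologDegConcordance(none$deg1, none$deg2,
                                      none$map)$summary$percent_conserved, 0)
  dup_map <- rbind(fx$map, fx$map[1, ])
  expect_error(orthologDegConcordance(fx$deg1, fx$deg2, dup_map), "collision")
})

test_that("concordance requires the full pattern to match, not just one tissue", {
  deg1 <- data.frame(gene = c("g1", "g1"), treatment = "cold",
                     tissue = c("shoot", "root"), direction = c("up", "ns"))
  deg2 <- data.frame(gene = c("h1", "h1"), treatment = "cold",
                     tissue = c("shoot", "root"), direction = c("up", "down"))
  map <- data.frame(gene_s1 = "g1", gene_s2 = "h1")
  res <- orthologDegConcordance(deg1, deg2, map)
  expect_equal(res$calls$verdict, "DIVERGENT")
})

test_that("tandem duplicate summaries count genes and clusters", {
  fx <- fixture_tandem(1993, 902, 755, 236)
  s <- tandemDegSummary(fx$clusters, fx$de_genes)
  expect_equal(s$n_de, 755)
  expect_equal(s$percent_de, 37.9)
  expect_equal(s$clusters_ge2_de, 236)
  expect_equal(s$percent_clusters_ge2_de, 26.2)
  # no DE flags at all
  s0 <- tandemDegSummary(fx$clusters, character(0))
  expect_equal(s0$n_de, 0)
  expect_equal(s0$percent_de, 0)
  dup <- rbind(fx$clusters, fx$clusters[1, ])
  expect_error(tandemDegSummary(dup, fx$de_genes), "more than one")
})
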