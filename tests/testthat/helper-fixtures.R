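# Fixture builders used by unit and acceptance tests. All counts are
# constructed programmatically; summaries must recompute percentages from
# them exactly.

# HEB calls table: `n_b` B-biased comparisons out of `n_total` (one condition)
fixture_heb_calls <- function(n_total, n_b) {
  data.frame(
    pair_id = sprintf("p%05d", seq_len(n_total)),
    condition = "cond01",
    call = c(rep("B_BIASED", n_b), rep("UNBIASED", n_total - n_b)),
    log2_ratio = 0, padj = NA_real_, stringsAsFactors = FALSE
  )
}

# ortholog DEG tables for one treatment: `n` pairs DE in both species,
# `n_same` of them with the identical tissue-direction pattern
fixture_concordance <- function(n, n_same, treatment = "drought") {
  g1 <- sprintf("sp1g%04d", seq_len(n))
  g2 <- sprintf("sp2g%04d", seq_len(n))
  deg1 <- data.frame(gene = g1, treatment = treatment, tissue = "root",
                     direction = "up", stringsAsFactors = FALSE)
  deg2 <- data.frame(gene = g2, treatment = treatment, tissue = "root",
                     direction = c(rep("up", n_same), rep("down", n - n_same)),
                     stringsAsFactors = FALSE)
  list(deg1 = deg1, deg2 = deg2,
       map = data.frame(gene_s1 = g1, gene_s2 = g2, stringsAsFactors = FALSE))
}

# tandem cluster partition with the given totals:
# n_genes genes in n_clusters clusters, n_de of them DE, n_cl2 clusters
# holding exactly two DE copies (the remaining DE genes spread one per
# cluster over clusters that have none)
fixture_tandem <- function(n_genes, n_clusters, n_de, n_cl2) {
  stopifnot(2 * n_cl2 <= n_de, n_de - 2 * n_cl2 <= n_clusters - n_cl2)
  gene <- sprintf("t%04d", seq_len(n_genes))
  cluster <- integer(n_genes)
  de <- logical(n_genes)
  i <- 0L
  # clusters with exactly two DE copies
  for (cl in seq_len(n_cl2)) {
    cluster[i + 1:2] <- cl; de[i + 1:2] <- TRUE; i <- i + 2L
  }
  # singleton-DE clusters
  n_single <- n_de - 2L * n_cl2
  for (cl in n_cl2 + seq_len(n_single)) {
    cluster[i + 1L] <- cl; de[i + 1L] <- TRUE; i <- i + 1L
  }
  # remaining clusters get one non-DE gene each
  rest_cl <- n_cl2 + n_single + seq_len(n_clusters - n_cl2 - n_single)
  for (cl in rest_cl) {
    cluster[i + 1L] <- cl; i <- i + 1L
  }
  # pad leftover genes (non-DE) into the last cluster
  if (i < n_genes) cluster[(i + 1L):n_genes] <- n_clusters
  list(clusters = data.frame(gene = gene,
                             cluster = sprintf("cl%04d", cluster),
                             stringsAsFactors = FALSE),
       de_genes = gene[de])
}

# expression SummarizedExperiment from explicit per-copy log2 means
fixture_expression <- function(mu_a, mu_b, n_rep = 4, sd = 0.3,
                               conditions = "c1", seed = 1) {
  set.seed(seed)
  np <- length(mu_a)
  nc <- length(conditions)
  m <- matrix(0, 2 * np, nc * n_rep)
  for (ci in seq_len(nc)) {
    cols <- (ci - 1) * n_rep + seq_len(n_rep)
    m[seq_len(np) * 2 - 1, cols] <- 2^(mu_a + rnorm(np * n_rep, sd = sd))
    m[seq_len(np) * 2, cols] <- 2^(mu_b + rnorm(np * n_rep, sd = sd))
  }
  pair_id <- sprintf("pair%04d", seq_len(np))
  rownames(m) <- paste0(rep(pair_id, each = 2), c("_A", "_B"))
  se <- makeExpressionSet(m, rep(conditions, each = n_rep))
  SummarizedExperiment::rowData(se)$pair_id <- rep(pair_id, each = 2)
  SummarizedExperiment::rowData(se)$copy <- rep(c("A", "B"), np)
  se
}
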