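# Subgenome fractionation statistics, homoeolog expression-bias (HEB)
# classification, DE calling, cross-species orthologous-DEG concordance, and
# tandem-duplicate DE summaries.

# Row-wise Welch t-test on two matrices (rows = features, cols = replicates).
# Degenerate rows (both groups constant) get p = 1 when the means agree and
# p = 0 otherwise. Vectorized because HEB classification runs tens of
# thousands of per-pair, per-condition tests.
.rowWelch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * pt(-abs(t), df)
  deg <- !is.finite(p)
  p[deg] <- ifelse(abs(ma[deg] - mb[deg]) < 1e-12, 1, 0)
  list(delta = ma - mb, p = p)
}

.tpmAssay <- function(expr) {
  if (is(expr, "SummarizedExperiment")) {
    list(tpm = SummarizedExperiment::assay(expr, "tpm"),
         condition = as.character(SummarizedExperiment::colData(expr)$condition))
  } else {
    stop("expr must be a SummarizedExperiment with a 'tpm' assay ",
         "(see simulateExpression or makeExpressionSet)")
  }
}

#' Assemble an expression SummarizedExperiment from a TPM matrix
#'
#' @param tpm non-negative numeric matrix, genes x samples.
#' @param condition condition label per sample.
#' @param replicate replicate index per sample.
#' @return A `SummarizedExperiment` with assay `tpm`.
#' @export
makeExpressionSet <- function(tpm, condition,
                              replicate = ave(seq_along(condition), condition,
                                              FUN = seq_along)) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (length(condition) != ncol(tpm)) {
    stop("one condition label per sample is required")
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = tpm),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   replicate = as.integer(replicate)))
}

#' Per-chromosome gene retention of the two subgenomes
#'
#' @param anchors anchor `data.frame` with columns `gene_a`, `gene_b` (NA for
#'   a lost copy) and a chromosome column (`chr_a`, falling back to `chr_b`
#'   where A is absent; chromosome labels are assumed matched between
#'   subgenomes).
#' @return `data.frame` with one row per chromosome plus a `global` row:
#'   `retained_a`, `retained_b`, `lost_a`, `lost_b` (the two singleton
#'   classes), `pairs`.
#' @export
retentionProfile <- function(anchors) {
  if (is.null(anchors) || nrow(anchors) == 0L) stop("empty anchor table")
  if (any(is.na(anchors$gene_a) & is.na(anchors$gene_b))) {
    stop("anchor rows must retain at least one subgenome copy")
  }
  chrom <- ifelse(is.na(anchors$gene_a), anchors$chr_b, anchors$chr_a)
  one <- function(i) {
    a <- !is.na(anchors$gene_a[i]); b <- !is.na(anchors$gene_b[i])
    data.frame(retained_a = sum(a), retained_b = sum(b),
               lost_a = sum(!a), lost_b = sum(!b), pairs = sum(a & b))
  }
  per <- do.call(rbind, lapply(split(seq_len(nrow(anchors)), chrom), one))
  out <- data.frame(chromosome = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(chromosome = "global", one(seq_len(nrow(anchors)))))
}

#' Exact binomial test for biased fractionation
#'
#' Among singletons (anchors that lost one copy), tests whether A losses and
#' B losses deviate from the 50:50 expected under unbiased fractionation —
#' per chromosome (BH-adjusted across chromosomes) and pooled.
#'
#' @param profile output of [retentionProfile()].
#' @param minSingletons chromosomes with fewer singletons are flagged as
#'   low-power (their p-value is still reported; zero singletons gives `NA`).
#' @return A list: `per_chromosome` (`data.frame` with `lost_a`, `lost_b`,
#'   `p`, `padj`, `flagged`) and `global` (list with `lost_a`, `lost_b`,
#'   `p`).
#' @export
fractionationBiasTest <- function(profile, minSingletons = 10L) {
  per <- profile[profile$chromosome != "global", , drop = FALSE]
  glob <- profile[profile$chromosome == "global", , drop = FALSE]
  if (nrow(glob) != 1L) stop("profile must contain a 'global' row")
  btest <- function(la, lb) {
    if (la + lb == 0L) return(NA_real_)
    binom.test(la, la + lb, p = 0.5)$p.value
  }
  p <- mapply(btest, per$lost_a, per$lost_b)
  res <- data.frame(chromosome = per$chromosome, lost_a = per$lost_a,
                    lost_b = per$lost_b, p = p,
                    padj = p.adjust(p, method = "BH"),
                    flagged = per$lost_a + per$lost_b < minSingletons,
                    stringsAsFactors = FALSE)
  list(per_chromosome = res,
       global = list(lost_a = glob$lost_a, lost_b = glob$lost_b,
                     p = btest(glob$lost_a, glob$lost_b)))
}

#' Call differentially expressed genes between two conditions
#'
#' Per-gene Welch test on `log2(TPM + 1)` with Benjamini-Hochberg adjustment;
#' a gene is DE when it changes at least `fcThreshold`-fold
#' (`|log2FC| >= log2(fcThreshold)`) at adjusted p below `fdr`.
#'
#' @param expr a `SummarizedExperiment` with assay `tpm` and `colData`
#'   column `condition`.
#' @param conditionA treatment condition label.
#' @param conditionB control condition label.
#' @param fcThreshold fold-change gate (default 2).
#' @param fdr FDR level (default 0.05).
#' @return `data.frame`: `gene`, `log2fc` (A relative to B), `p`, `padj`,
#'   `de` (logical), `direction` (`up`/`down`/`ns`).
#' @export
callDE <- function(expr, conditionA, conditionB, fcThreshold = 2,
                   fdr = 0.05) {
  ex <- .tpmAssay(expr)
  ia <- ex$condition == conditionA
  ib <- ex$condition == conditionB
  if (!any(ia)) stop("condition not found: ", conditionA)
  if (!any(ib)) stop("condition not found: ", conditionB)
  if (sum(ia) < 2L || sum(ib) < 2L) stop("each condition needs >= 2 replicates")
  la <- log2(ex$tpm[, ia, drop = FALSE] + 1)
  lb <- log2(ex$tpm[, ib, drop = FALSE] + 1)
  wt <- .rowWelch(la, lb)
  padj <- p.adjust(wt$p, method = "BH")
  de <- abs(wt$delta) >= log2(fcThreshold) & padj < fdr
  data.frame(gene = rownames(ex$tpm), log2fc = wt$delta, p = wt$p,
             padj = padj, de = de,
             direction = ifelse(!de, "ns", ifelse(wt$delta > 0, "up", "down")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify homoeolog expression bias per pair and condition
#'
#' Within each condition the A and B copies of a pair are compared across
#' replicates exactly as in [callDE()] (Welch test on `log2(TPM + 1)`, BH
#' across pairs, fold-change gate). A pair is `B_BIASED` when the B copy is
#' significantly higher, `A_BIASED` when A is, `UNBIASED` otherwise, and
#' `UNTESTABLE` when neither copy reaches `minTpm` mean TPM in the condition.
#'
#' @param expr a `SummarizedExperiment` with assay `tpm` (e.g. from
#'   [simulateExpression()]).
#' @param pairs `data.frame` with columns `pair_id`, `gene_a`, `gene_b`
#'   mapping pairs to row names of `expr`; defaults to the pairing encoded in
#'   `rowData(expr)` when present.
#' @param fcThreshold,fdr thresholds as in [callDE()].
#' @param minTpm expression filter (mean TPM in the condition).
#' @return `data.frame`: `pair_id`, `condition`, `call`, `log2_ratio`
#'   (B over A), `padj`.
#' @export
hebClassify <- function(expr, pairs = NULL, fcThreshold = 2, fdr = 0.05,
                        minTpm = 1) {
  ex <- .tpmAssay(expr)
  if (is.null(pairs)) {
    rd <- SummarizedExperiment::rowData(expr)
    if (!all(c("pair_id", "copy") %in% colnames(rd))) {
      stop("supply `pairs` or an expr with rowData columns pair_id/copy")
    }
    ga <- rownames(expr)[rd$copy == "A"]
    gb <- rownames(expr)[rd$copy == "B"]
    pairs <- data.frame(pair_id = rd$pair_id[rd$copy == "A"],
                        gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
  }
  missing <- c(setdiff(pairs$gene_a, rownames(ex$tpm)),
               setdiff(pairs$gene_b, rownames(ex$tpm)))
  if (length(missing)) {
    stop("homoeolog pair gene(s) not in expression table: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  a <- ex$tpm[pairs$gene_a, , drop = FALSE]
  b <- ex$tpm[pairs$gene_b, , drop = FALSE]
  out <- lapply(unique(ex$condition), function(cond) {
    ic <- ex$condition == cond
    la <- log2(a[, ic, drop = FALSE] + 1)
    lb <- log2(b[, ic, drop = FALSE] + 1)
    wt <- .rowWelch(lb, la)               # delta = B - A
    testable <- pmax(rowMeans(a[, ic, drop = FALSE]),
                     rowMeans(b[, ic, drop = FALSE])) >= minTpm
    padj <- rep(NA_real_, nrow(pairs))
    padj[testable] <- p.adjust(wt$p[testable], method = "BH")
    sig <- testable & padj < fdr & abs(wt$delta) >= log2(fcThreshold)
    call <- ifelse(!testable, "UNTESTABLE",
                   ifelse(sig & wt$delta > 0, "B_BIASED",
                          ifelse(sig & wt$delta < 0, "A_BIASED", "UNBIASED")))
    data.frame(pair_id = pairs$pair_id, condition = cond, call = call,
               log2_ratio = wt$delta, padj = padj, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize homoeolog expression-bias calls
#'
#' @param calls output of [hebClassify()] (or any `data.frame` with
#'   `pair_id`, `condition`, `call`).
#' @param requireSameDirection should "biased in all conditions" require the
#'   same direction throughout (default TRUE)?
#' @return A list: `n_pairs`, `n_comparisons` (testable pair x condition
#'   comparisons), `biased_any` (pairs biased in >= 1 condition),
#'   `biased_all` (pairs biased in every condition),
#'   `b_biased_comparisons`, `percent_b_biased` (share of comparisons
#'   B-biased, one decimal), and `per_condition` (`data.frame` with the
#'   B-share among biased calls).
#' @export
hebSummary <- function(calls, requireSameDirection = TRUE) {
  biased <- calls$call %in% c("A_BIASED", "B_BIASED")
  by_pair <- split(calls$call, calls$pair_id)
  any_b <- vapply(by_pair, function(x) any(x %in% c("A_BIASED", "B_BIASED")),
                  logical(1))
  all_b <- vapply(by_pair, function(x) {
    b <- x %in% c("A_BIASED", "B_BIASED")
    if (!all(b)) return(FALSE)
    if (requireSameDirection) length(unique(x)) == 1L else TRUE
  }, logical(1))
  n_comp <- sum(calls$call != "UNTESTABLE")
  nb <- sum(calls$call == "B_BIASED")
  per_cond <- do.call(rbind, lapply(split(calls, calls$condition), function(d) {
    bi <- d$call %in% c("A_BIASED", "B_BIASED")
    data.frame(condition = d$condition[1L], n_biased = sum(bi),
               b_share = if (any(bi)) mean(d$call[bi] == "B_BIASED") else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(n_pairs = length(by_pair), n_comparisons = n_comp,
       biased_any = sum(any_b), biased_all = sum(all_b),
       b_biased_comparisons = nb,
       percent_b_biased = round(100 * nb / n_comp, 1L),
       per_condition = data.frame(per_cond, row.names = NULL))
}

# tissue-direction pattern strings per gene x treatment, e.g. "shoot:up|root:ns"
.degPatterns <- function(deg, tissues) {
  key <- paste(deg$gene, deg$treatment, sep = "\r")
  out <- lapply(split(deg, key), function(d) {
    dir <- setNames(rep("ns", length(tissues)), tissues)
    dir[d$tissue] <- d$direction
    data.frame(gene = d$gene[1L], treatment = d$treatment[1L],
               pattern = paste(paste0(tissues, ":", dir), collapse = "|"),
               any_de = any(d$direction != "ns"), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-species concordance of orthologous differentially expressed genes
#'
#' Restricted, per treatment, to ortholog pairs differentially expressed in
#' both species (in shoot, root, or both); a pair is `CONSERVED` when the two
#' species show the identical tissue-direction pattern (same tissue(s), same
#' direction, including non-significance in the other tissue) and `DIVERGENT`
#' otherwise.
#'
#' @param degS1,degS2 per-species DE tables: `data.frame` with columns
#'   `gene`, `treatment`, `tissue`, `direction` (`up`/`down`/`ns`; genes
#'   absent for a tissue count as `ns`).
#' @param orthologMap `data.frame` with columns `gene_s1`, `gene_s2`
#'   (one-to-one; duplicates raise an error).
#' @param tissues tissue panel assayed in both species.
#' @return A list: `calls` (`data.frame` with `gene_s1`, `gene_s2`,
#'   `treatment`, `pattern_s1`, `pattern_s2`, `verdict`) and `summary`
#'   (per-treatment `n`, `conserved`, `percent_conserved` rounded to the
#'   nearest integer).
#' @export
orthologDegConcordance <- function(degS1, degS2, orthologMap,
                                   tissues = c("shoot", "root")) {
  if (anyDuplicated(orthologMap$gene_s1) || anyDuplicated(orthologMap$gene_s2)) {
    stop("ortholog map contains collisions (duplicated genes)")
  }
  p1 <- .degPatterns(degS1, tissues)
  p2 <- .degPatterns(degS2, tissues)
  treatments <- union(p1$treatment, p2$treatment)
  calls <- do.call(rbind, lapply(treatments, function(tr) {
    a <- p1[p1$treatment == tr & p1$any_de, , drop = FALSE]
    b <- p2[p2$treatment == tr & p2$any_de, , drop = FALSE]
    m <- orthologMap[orthologMap$gene_s1 %in% a$gene &
                     orthologMap$gene_s2 %in% b$gene, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    pa <- a$pattern[match(m$gene_s1, a$gene)]
    pb <- b$pattern[match(m$gene_s2, b$gene)]
    data.frame(gene_s1 = m$gene_s1, gene_s2 = m$gene_s2, treatment = tr,
               pattern_s1 = pa, pattern_s2 = pb,
               verdict = ifelse(pa == pb, "CONSERVED", "DIVERGENT"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) stop("no ortholog pairs DE in both species")
  summ <- do.call(rbind, lapply(split(calls, calls$treatment), function(d) {
    data.frame(treatment = d$treatment[1L], n = nrow(d),
               conserved = sum(d$verdict == "CONSERVED"),
               percent_conserved = round(100 * mean(d$verdict == "CONSERVED")),
               stringsAsFactors = FALSE)
  }))
  list(calls = calls, summary = data.frame(summ, row.names = NULL))
}

#' Differential expression among tandemly duplicated genes
#'
#' @param clusters `data.frame` with columns `gene` and `cluster` partitioning
#'   the tandem gene set; a gene in two clusters raises an error.
#' @param deGenes character vector of genes differentially expressed in at
#'   least one tissue or treatment.
#' @return A list: `n_genes`, `n_de`, `percent_de` (one decimal),
#'   `n_clusters`, `clusters_ge2_de`, `percent_clusters_ge2_de` (one
#'   decimal).
#' @export
tandemDegSummary <- function(clusters, deGenes) {
  if (anyDuplicated(clusters$gene)) {
    stop("gene(s) assigned to more than one tandem cluster: ",
         paste(head(unique(clusters$gene[duplicated(clusters$gene)]), 3L),
               collapse = ", "))
  }
  de <- clusters$gene %in% deGenes
  per_cluster <- tapply(de, clusters$cluster, sum)
  list(n_genes = nrow(clusters), n_de = sum(de),
       percent_de = round(100 * mean(de), 1L),
       n_clusters = length(per_cluster),
       clusters_ge2_de = sum(per_cluster >= 2L),
       percent_clusters_ge2_de = round(100 * mean(per_cluster >= 2L), 1L))
}
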