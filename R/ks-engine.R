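# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, per-block Ks
# summaries, and Gaussian-mixture fitting of Ks distributions.

#' Count synonymous and nonsynonymous sites of a coding sequence
#'
#' NG86 fractional site counting: each codon contributes one third of its
#' synonymous single-nucleotide neighbors as synonymous sites, the remainder
#' (including changes to stop codons) as nonsynonymous sites. Codons
#' containing `N` or `-`, and stop codons, are skipped.
#'
#' @param sequence an in-frame nucleotide string (or `DNAString`), length a
#'   multiple of 3.
#' @return A list with `n_sites`, `s_sites`, and `codons_counted`.
#' @examples
#' countSites("TTTATG")  # Phe + Met
#' @export
countSites <- function(sequence) {
  tab <- .codonTables()
  codons <- .toCodons(sequence)
  if (any(!.validNucleotides(codons))) {
    stop("sequence contains characters other than A/C/G/T/N/-")
  }
  ci <- tab$index[codons]          # NA for codons with N or -
  keep <- !is.na(ci) & !tab$is_stop[ifelse(is.na(ci), 1L, ci)]
  ci <- ci[keep]
  list(n_sites = sum(tab$n_sites[ci]), s_sites = sum(tab$s_sites[ci]),
       codons_counted = length(ci))
}

#' Pathway-averaged difference counts between two codons
#'
#' Differences are partitioned into synonymous and nonsynonymous by averaging
#' uniformly over all minimal mutational pathways between the codons; pathways
#' passing through a stop codon are excluded (if every pathway is blocked, all
#' are kept). `nd + sd` equals the number of differing positions.
#'
#' @param codonA,codonB three-letter codon strings, neither a stop codon nor
#'   ambiguous. A stop codon yields `c(NA, NA)` (a skip signal, not an error).
#' @return Named numeric vector `c(nd = ..., sd = ...)`.
#' @examples
#' countDifferences("TTT", "TTC")  # one synonymous difference
#' @export
countDifferences <- function(codonA, codonB) {
  tab <- .codonTables()
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  ia <- tab$index[codonA]; ib <- tab$index[codonB]
  if (is.na(ia) || is.na(ib)) stop("ambiguous or invalid codon")
  if (tab$is_stop[ia] || tab$is_stop[ib]) {
    return(c(nd = NA_real_, sd = NA_real_))
  }
  c(nd = tab$nd[ia, ib], sd = tab$sd[ia, ib])
}

.ksResultUnusable <- function(usable_codons) {
  new("KsResult", ka = NA_real_, ks = NA_real_, nSites = NA_real_,
      sSites = NA_real_, nd = NA_real_, sd = NA_real_, saturated = FALSE,
      usableCodons = as.integer(usable_codons), usable = FALSE)
}

#' NG86 Ka/Ks for a pairwise codon alignment
#'
#' Sites are counted on each sequence and averaged; differences are
#' pathway-averaged per codon pair; proportions `pN = Nd/N` and `pS = Sd/S`
#' are Jukes-Cantor corrected, `d = -(3/4) log(1 - 4p/3)`. A proportion at or
#' above 3/4 is saturated and leaves the corresponding rate undefined. Codon
#' columns containing a gap, `N`, or a stop codon in either sequence are
#' skipped symmetrically; alignments with fewer than 30 comparable codons are
#' flagged unusable rather than raising an error.
#'
#' @param seqA,seqB aligned in-frame nucleotide strings (or `DNAString`s) of
#'   equal length divisible by 3, alphabet `A/C/G/T/N/-`.
#' @return A [KsResult-class].
#' @examples
#' r <- computeKaKs(strrep("ATGACC", 30), strrep("ATGACT", 30))
#' ksValue(r)
#' @export
computeKaKs <- function(seqA, seqB) {
  tab <- .codonTables()
  ca <- .toCodons(seqA)
  cb <- .toCodons(seqB)
  if (length(ca) != length(cb)) stop("sequences must be aligned to equal length")
  if (any(!.validNucleotides(ca)) || any(!.validNucleotides(cb))) {
    stop("sequences contain characters other than A/C/G/T/N/-")
  }
  ia <- tab$index[ca]
  ib <- tab$index[cb]
  keep <- !is.na(ia) & !is.na(ib)
  keep[keep] <- !tab$is_stop[ia[keep]] & !tab$is_stop[ib[keep]]
  ia <- ia[keep]; ib <- ib[keep]
  usable_codons <- length(ia)
  if (usable_codons < 30L) return(.ksResultUnusable(usable_codons))

  s_sites <- (sum(tab$s_sites[ia]) + sum(tab$s_sites[ib])) / 2
  n_sites <- (sum(tab$n_sites[ia]) + sum(tab$n_sites[ib])) / 2
  nd <- sum(tab$nd[cbind(ia, ib)])
  sd <- sum(tab$sd[cbind(ia, ib)])
  pN <- nd / n_sites
  pS <- sd / s_sites
  ka <- .jcCorrect(pN)
  ks <- .jcCorrect(pS)
  new("KsResult", ka = ka, ks = ks, nSites = n_sites, sSites = s_sites,
      nd = nd, sd = sd, saturated = is.na(ks) && pS >= 0.75,
      usableCodons = as.integer(usable_codons), usable = TRUE)
}

#' Summarize Ks per syntenic block
#'
#' Averages the per-pair Ks values of each collinearity block, the statistic
#' plotted in whole-genome Ks dotplot analyses. Saturated and unusable pairs
#' are excluded; blocks with fewer than 5 usable pairs are flagged.
#'
#' @param anchors an anchor table (see [readAnchors()]) with columns `gene_a`,
#'   `gene_b`, `block_id`.
#' @param results a `data.frame` with columns `gene_a`, `gene_b`, `ks`, and
#'   logical `usable` — e.g. built from [computeKaKs()] output. Every anchor
#'   pair (both copies present) must appear.
#' @param stat `"mean"` (default, the "average Ks per block" convention) or
#'   `"median"`.
#' @param minPairs blocks with fewer usable pairs than this are flagged.
#' @return `data.frame` with `block_id`, `n_pairs`, `n_usable`, `ks`,
#'   `flagged`.
#' @export
blockSummary <- function(anchors, results, stat = c("mean", "median"),
                         minPairs = 5L) {
  stat <- match.arg(stat)
  pairs <- anchors[!is.na(anchors$gene_a) & !is.na(anchors$gene_b), , drop = FALSE]
  if (nrow(pairs) == 0L) stop("anchor table contains no retained pairs")
  key <- paste(pairs$gene_a, pairs$gene_b)
  rkey <- paste(results$gene_a, results$gene_b)
  hit <- match(key, rkey)
  if (anyNA(hit)) {
    stop("no Ks result for anchor pair(s): ",
         paste(head(key[is.na(hit)], 3L), collapse = ", "))
  }
  ks <- results$ks[hit]
  usable <- results$usable[hit] & !is.na(ks)
  fun <- if (stat == "mean") mean else median
  out <- lapply(split(seq_len(nrow(pairs)), pairs$block_id), function(i) {
    ok <- i[usable[i]]
    data.frame(n_pairs = length(i), n_usable = length(ok),
               ks = if (length(ok)) fun(ks[ok]) else NA_real_,
               flagged = length(ok) < minPairs)
  })
  res <- do.call(rbind, out)
  data.frame(block_id = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit Gaussian mixture peaks to a Ks distribution
#'
#' Fits unequal-variance Gaussian mixtures for `k = 1..kMax` by EM and selects
#' `k` by BIC (via \pkg{mclust}), the standard way of resolving WGD and
#' speciation peaks in a Ks distribution.
#'
#' @param values numeric Ks values; non-finite values and values outside
#'   `(0, ksCap]` are dropped before fitting.
#' @param kMax maximum number of components.
#' @param seed integer seed.
#' @param ksCap saturation cap; Ks beyond it is uninformative for dating.
#' @param minValues minimum values required after filtering.
#' @return A [PeakModel-class].
#' @examples
#' set.seed(1)
#' fitKsPeaks(rnorm(500, 0.3, 0.05), kMax = 3, seed = 1)
#' @export
fitKsPeaks <- function(values, kMax = 4L, seed = 1L, ksCap = 3.0,
                       minValues = 50L) {
  values <- values[is.finite(values) & values > 0 & values <= ksCap]
  if (length(values) < minValues) {
    stop("need at least ", minValues, " usable Ks values, got ", length(values))
  }
  if (stats::sd(values) < 1e-12) {
    stop("degenerate input: Ks values are (numerically) constant")
  }
  set.seed(seed)
  fit <- mclust::Mclust(values, G = seq_len(kMax), modelNames = c("E", "V"),
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture fitting failed")
  means <- as.numeric(fit$parameters$mean)
  sds <- sqrt(rep_len(as.numeric(fit$parameters$variance$sigmasq), fit$G))
  wts <- as.numeric(fit$parameters$pro)
  ord <- order(means)
  bic <- apply(fit$BIC, 1L, max, na.rm = TRUE)
  new("PeakModel", k = as.integer(fit$G), means = means[ord], sds = sds[ord],
      weights = wts[ord] / sum(wts), bic = bic)
}
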