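# Seeded generators with known ground truth for every downstream stage:
# codon sequences along tetraploidy scenarios, expression matrices with
# controllable homoeolog bias, fractionated anchor tables, and LTR pairs.

# Evolve codon-index vector along one branch. `d` is the expected number of
# synonymous substitutions per synonymous site on the branch: nucleotide
# positions propose uniform changes at intensity d per site, a synonymous
# proposal is always accepted, a nonsynonymous one with probability omega,
# and one creating a stop codon never — which makes the realized synonymous
# clock equal d independently of omega.
.evolveBranch <- function(idx, d, omega, tab) {
  L <- length(idx)
  n_events <- rpois(1L, 3 * d * L)
  if (n_events == 0L) return(idx)
  codon <- sample.int(L, n_events, replace = TRUE)
  off <- (sample.int(3L, n_events, replace = TRUE) - 1L) * 64L +
         (sample.int(3L, n_events, replace = TRUE) - 1L) * 192L
  u <- runif(n_events)
  nb <- tab$neighbor_flat
  syn <- tab$syn_flat
  stp <- tab$to_stop_flat
  for (e in seq_len(n_events)) {
    slot <- idx[codon[e]] + off[e]
    if (stp[slot]) next
    if (syn[slot] || u[e] < omega) idx[codon[e]] <- nb[slot]
  }
  idx
}

.randomRootCodons <- function(n, tab) {
  sample(which(!tab$is_stop), n, replace = TRUE)
}

.codonIdxToString <- function(idx, tab) {
  paste(tab$codons[idx], collapse = "")
}

# Branch plan for the 5-taxon scenario tree. Durations in Ma; the outgroup
# diverges at twice the oldest in-group event so the quartet is rootable.
.scenarioBranches <- function(config) {
  ma <- 1e6 * config@rateR  # per-Ma synonymous branch divergence
  if (config@wgdMode == "SHARED") {
    t_old <- config@tWgd
    list(
      root_to_out = 2 * t_old * ma,
      stem = t_old * ma,                      # root of ingroup -> WGD
      split1 = (config@tWgd - config@tSpeciation) * ma,  # WGD -> speciation
      tip = config@tSpeciation * ma,
      pairs = list(c("A1", "B1"), c("A2", "B2"))
    )
  } else {
    t_old <- config@tSpeciation
    list(
      root_to_out = 2 * t_old * ma,
      stem = t_old * ma,                      # root of ingroup -> speciation
      split1 = (config@tSpeciation - config@tWgd) * ma,  # speciation -> WGD
      tip = config@tWgd * ma,
      pairs = list(c("A1", "A2"), c("B1", "B2"))
    )
  }
}

#' Simulate collinear gene quartets under a tetraploidy scenario
#'
#' Evolves five in-frame coding sequences (`A1`, `A2`, `B1`, `B2`, `OUT`)
#' along the scenario's species tree by a codon-wise substitution process
#' whose synonymous clock equals `2 r t` between lineages separated for time
#' `t`. Under `SHARED`, the duplication predates speciation so each A copy is
#' sister to a B copy; under `INDEPENDENT`, each species duplicates after
#' speciation so copies are sister within species. The outgroup diverges at
#' twice the oldest in-group event.
#'
#' @param config a [ScenarioConfig-class].
#' @param nGenes number of quartets.
#' @return A list of [SimulatedQuartet-class] objects; deterministic given
#'   `config@seed`.
#' @examples
#' q <- simulateQuartets(scenarioConfig("SHARED", 18.19, 10, nCodons = 100), 2)
#' trueTopology(q[[1]])
#' @export
simulateQuartets <- function(config, nGenes) {
  stopifnot(is(config, "ScenarioConfig"))
  validObject(config)
  tab <- .codonTables()
  br <- .scenarioBranches(config)
  set.seed(config@seed)
  lapply(seq_len(nGenes), function(g) {
    root <- .randomRootCodons(config@nCodons, tab)
    out <- .evolveBranch(root, br$root_to_out, config@omega, tab)
    anc <- .evolveBranch(root, br$stem, config@omega, tab)
    seqs <- vector("list", 5L)
    names(seqs) <- c(unlist(br$pairs), "OUT")
    for (p in 1:2) {
      mid <- .evolveBranch(anc, br$split1, config@omega, tab)
      for (lab in br$pairs[[p]]) {
        seqs[[lab]] <- .evolveBranch(mid, br$tip, config@omega, tab)
      }
    }
    seqs[["OUT"]] <- out
    dna <- Biostrings::DNAStringSet(
      vapply(seqs[c("A1", "A2", "B1", "B2", "OUT")], .codonIdxToString,
             character(1), tab = tab))
    new("SimulatedQuartet", sequences = dna, trueTopology = config@wgdMode,
        geneId = sprintf("gene%04d", g))
  })
}

#' Simulate one pair of coding sequences diverged for a given time
#'
#' Two lineages evolve independently from a common ancestor for `t` Ma, so the
#' expected synonymous divergence (pre-saturation) is `Ks = 2 r t`.
#'
#' @param t divergence time in Ma (>= 0).
#' @param config a [ScenarioConfig-class]; supplies `rateR`, `omega`,
#'   `nCodons`.
#' @param seed seed for this pair (defaults to `config@seed`).
#' @return A named `DNAStringSet` of length 2 (`seq1`, `seq2`).
#' @export
simulateSequencePair <- function(t, config, seed = config@seed) {
  stopifnot(is(config, "ScenarioConfig"))
  if (!isTRUE(t >= 0)) stop("divergence time t must be >= 0")
  tab <- .codonTables()
  set.seed(seed)
  d <- config@rateR * t * 1e6
  root <- .randomRootCodons(config@nCodons, tab)
  a <- .evolveBranch(root, d, config@omega, tab)
  b <- .evolveBranch(root, d, config@omega, tab)
  Biostrings::DNAStringSet(c(seq1 = .codonIdxToString(a, tab),
                             seq2 = .codonIdxToString(b, tab)))
}

#' Simulate a homoeolog expression matrix with known bias
#'
#' TPM values are log-normal: each pair draws a baseline log2 mean, biased
#' pairs shift the designated copy by `effectLog2fc` in every condition, and
#' replicates add Gaussian noise of sd `dispersion` on the log2 scale.
#'
#' @param spec a [BiasSpec-class].
#' @param seed integer seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `tpm`
#'   (rows `pair0001_A`, `pair0001_B`, ...), `colData` columns `condition`
#'   and `replicate`, `rowData` columns `pair_id` and `copy`, and the truth
#'   labels in `metadata(x)$truth` (`pair_id`, `bias` in `A`/`B`/`none`).
#' @export
simulateExpression <- function(spec, seed = 1L) {
  stopifnot(is(spec, "BiasSpec"))
  validObject(spec)
  set.seed(seed)
  np <- spec@nPairs
  n_b <- round(spec@fracBBiased * np)
  n_a <- round(spec@fracABiased * np)
  bias <- rep("none", np)
  lab <- sample.int(np)           # which pairs carry the bias
  if (n_b > 0) bias[lab[seq_len(n_b)]] <- "B"
  if (n_a > 0) bias[lab[n_b + seq_len(n_a)]] <- "A"

  n_samp <- spec@nConditions * spec@nReplicates
  condition <- rep(sprintf("cond%02d", seq_len(spec@nConditions)),
                   each = spec@nReplicates)
  replicate <- rep(seq_len(spec@nReplicates), spec@nConditions)

  base <- matrix(rnorm(np * spec@nConditions, mean = 5, sd = 1.5),
                 nrow = np)                      # per-pair, per-condition mean
  mu_a <- base + ifelse(bias == "A", spec@effectLog2fc / 2, 0) -
    ifelse(bias == "B", spec@effectLog2fc / 2, 0)
  mu_b <- base + ifelse(bias == "B", spec@effectLog2fc / 2, 0) -
    ifelse(bias == "A", spec@effectLog2fc / 2, 0)

  expand <- rep(seq_len(spec@nConditions), each = spec@nReplicates)
  m <- matrix(0, nrow = 2L * np, ncol = n_samp)
  noise <- function() matrix(rnorm(np * n_samp, sd = spec@dispersion), np)
  m[seq_len(np) * 2L - 1L, ] <- 2^(mu_a[, expand] + noise())
  m[seq_len(np) * 2L, ] <- 2^(mu_b[, expand] + noise())

  pair_id <- sprintf("pair%05d", seq_len(np))
  rownames(m) <- paste0(rep(pair_id, each = 2L), c("_A", "_B"))
  colnames(m) <- paste0(condition, "_r", replicate)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = m),
    rowData = S4Vectors::DataFrame(pair_id = rep(pair_id, each = 2L),
                                   copy = rep(c("A", "B"), np)),
    colData = S4Vectors::DataFrame(condition = condition,
                                   replicate = replicate),
    metadata = list(truth = data.frame(pair_id = pair_id, bias = bias),
                    seed = seed)
  )
}

#' Simulate a fractionated anchor table
#'
#' Each ancestral anchor loses its subgenome-A copy with probability `lossA`
#' and its B copy with probability `lossB`, conditioned on never losing both
#' (joint-loss mass is renormalized onto the retained-pair outcome).
#'
#' @param nAnchors number of ancestral anchors.
#' @param lossA,lossB per-copy loss probabilities in `[0, 1)`.
#' @param nChromosomes anchors are spread evenly over this many chromosomes.
#' @param seed integer seed.
#' @param blockSize anchors per syntenic block.
#' @return An anchor `data.frame` with columns `gene_a`, `gene_b` (NA when
#'   lost), `block_id`, `chr_a`, `chr_b`, `status`
#'   (`pair`/`a_lost`/`b_lost`).
#' @export
simulateFractionation <- function(nAnchors, lossA, lossB, nChromosomes = 10L,
                                  seed = 1L, blockSize = 50L) {
  if (any(c(lossA, lossB) < 0) || any(c(lossA, lossB) >= 1)) {
    stop("loss probabilities must be in [0, 1)")
  }
  set.seed(seed)
  chr <- sprintf("chr%02d", rep_len(seq_len(nChromosomes), nAnchors))
  chr <- sort(chr)
  block <- paste0(chr, "_b",
                  ave(seq_len(nAnchors), chr,
                      FUN = function(i) (seq_along(i) - 1L) %/% blockSize + 1L))
  # conditional on not losing both copies
  p_pair <- (1 - lossA) * (1 - lossB) + lossA * lossB
  p_alost <- lossA * (1 - lossB)
  p_blost <- lossB * (1 - lossA)
  status <- sample(c("pair", "a_lost", "b_lost"), nAnchors, replace = TRUE,
                   prob = c(p_pair, p_alost, p_blost))
  id <- sprintf("%05d", seq_len(nAnchors))
  data.frame(
    gene_a = ifelse(status == "a_lost", NA_character_, paste0("geneA_", id)),
    gene_b = ifelse(status == "b_lost", NA_character_, paste0("geneB_", id)),
    block_id = block, chr_a = chr, chr_b = chr, status = status,
    stringsAsFactors = FALSE
  )
}

#' Simulate 5'/3' LTR pairs with known insertion times
#'
#' At insertion the two long terminal repeats of a retrotransposon are
#' identical; each then accumulates substitutions independently at rate
#' `rateR`, so the expected divergence of a pair inserted `t` Ma ago is
#' `K = 2 r t`.
#'
#' @param n number of elements.
#' @param insertionTimes true insertion times in Ma, recycled to length `n`.
#' @param rateR substitution rate per site per year.
#' @param seed integer seed.
#' @param ltrLength LTR length in bp.
#' @return A list with `pairs` (list of length-2 `DNAStringSet`s, names
#'   `ltr5`/`ltr3`) and `true_times` (Ma).
#' @export
simulateLtrPairs <- function(n, insertionTimes, rateR, seed = 1L,
                             ltrLength = 1000L) {
  if (any(insertionTimes < 0)) stop("insertion times must be >= 0")
  if (!isTRUE(rateR > 0)) stop("rateR must be > 0")
  set.seed(seed)
  times <- rep_len(insertionTimes, n)
  bases <- c("A", "C", "G", "T")
  mutate <- function(x, d) {
    k <- rpois(1L, d * length(x))
    if (k > 0L) {
      pos <- sample.int(length(x), k, replace = TRUE)
      for (i in seq_len(k)) {
        x[pos[i]] <- sample(bases[bases != x[pos[i]]], 1L)
      }
    }
    x
  }
  pairs <- lapply(seq_len(n), function(i) {
    anc <- sample(bases, ltrLength, replace = TRUE)
    d <- rateR * times[i] * 1e6
    Biostrings::DNAStringSet(c(
      ltr5 = paste(mutate(anc, d), collapse = ""),
      ltr3 = paste(mutate(anc, d), collapse = "")))
  })
  list(pairs = pairs, true_times = times)
}
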