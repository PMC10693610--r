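# Format readers/writers (FASTA, Newick, anchors TSV) and the end-to-end
# pipeline runner. All writers round-trip through their readers.

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased; duplicate record ids, empty files, and
#' characters outside `A/C/G/T/N/-` are errors.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @return A named `DNAStringSet`.
#' @export
readFastaFile <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  if (anyDuplicated(names(x))) {
    stop("duplicate FASTA ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  s <- toupper(as.character(x))
  bad <- !.validNucleotides(s)
  if (any(bad)) {
    stop("illegal characters in record(s): ",
         paste(names(x)[bad], collapse = ", "))
  }
  Biostrings::DNAStringSet(setNames(s, names(x)))
}

#' Write sequences to FASTA
#'
#' @param sequences a named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaFile <- function(sequences, path) {
  if (!is(sequences, "XStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read trees from a Newick file
#'
#' @param path Newick file; branch lengths and internal-node support values
#'   are optional and preserved.
#' @return A `phylo` (single tree) or `multiPhylo`.
#' @export
readNewickFile <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' Write trees to a Newick file
#'
#' @param tree a `phylo` or `multiPhylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewickFile <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a syntenic anchor table
#'
#' Tab-separated with header
#' `gene_a gene_b block_id chr_a chr_b [status]`; `.` or an empty field marks
#' a lost copy. Rows missing both copies, rows with the wrong number of
#' fields, and (when `chromosomes` is given) unknown chromosome labels are
#' errors reporting the offending line.
#'
#' @param path TSV path.
#' @param chromosomes optional declared set of valid chromosome labels.
#' @return An anchor `data.frame` (`gene_a`, `gene_b` with `NA` for absent
#'   copies, `block_id`, `chr_a`, `chr_b`, `status`).
#' @export
readAnchors <- function(path, chromosomes = NULL) {
  need <- c("gene_a", "gene_b", "block_id", "chr_a", "chr_b")
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) < 2L) stop("anchor table has no data rows: ", path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (!all(need %in% header)) {
    stop("anchor table must have columns: ", paste(need, collapse = ", "))
  }
  nf <- lengths(fields[-1L])
  if (any(nf != length(header))) {
    stop("malformed anchor row at line ",
         paste(which(nf != length(header))[1L] + 1L))
  }
  tab <- as.data.frame(do.call(rbind, fields[-1L]), stringsAsFactors = FALSE)
  names(tab) <- header
  absent <- function(x) ifelse(x %in% c(".", ""), NA_character_, x)
  tab$gene_a <- absent(tab$gene_a)
  tab$gene_b <- absent(tab$gene_b)
  both <- which(is.na(tab$gene_a) & is.na(tab$gene_b))
  if (length(both)) {
    stop("both copies absent at line ", both[1L] + 1L)
  }
  if (!is.null(chromosomes)) {
    bad <- setdiff(c(tab$chr_a, tab$chr_b), chromosomes)
    if (length(bad)) stop("unknown chromosome label(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!"status" %in% names(tab)) {
    tab$status <- ifelse(is.na(tab$gene_a), "a_lost",
                         ifelse(is.na(tab$gene_b), "b_lost", "pair"))
  }
  tab
}

#' Write an anchor table
#'
#' @param anchors anchor `data.frame`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAnchors <- function(anchors, path) {
  out <- anchors
  out$gene_a[is.na(out$gene_a)] <- "."
  out$gene_b[is.na(out$gene_b)] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param scenario a [ScenarioConfig-class] driving the sequence stages.
#' @param nGenes quartets to simulate.
#' @param bias a [BiasSpec-class] for the expression stage.
#' @param nAnchors,lossA,lossB fractionation stage settings.
#' @param ltrTimesMa,nLtr LTR stage settings.
#' @param ksCap,fcThreshold,fdr,alpha,minEffect analysis thresholds.
#' @param seed master seed; each stage derives its own stream from it.
#' @return A named list of validated settings.
#' @export
runConfig <- function(scenario, nGenes = 100L, bias = biasSpec(500L),
                      nAnchors = 2000L, lossA = 0.2, lossB = 0.2,
                      ltrTimesMa = 0.8, nLtr = 200L, ksCap = 3.0,
                      fcThreshold = 2, fdr = 0.05, alpha = 0.05,
                      minEffect = 0.05, seed = scenario@seed) {
  stopifnot(is(scenario, "ScenarioConfig"), is(bias, "BiasSpec"),
            fdr > 0, fdr < 1, alpha > 0, alpha < 1, ksCap > 0,
            fcThreshold >= 1, minEffect >= 0)
  list(scenario = scenario, nGenes = as.integer(nGenes), bias = bias,
       nAnchors = as.integer(nAnchors), lossA = lossA, lossB = lossB,
       ltrTimesMa = ltrTimesMa, nLtr = as.integer(nLtr), ksCap = ksCap,
       fcThreshold = fcThreshold, fdr = fdr, alpha = alpha,
       minEffect = minEffect, seed = as.integer(seed))
}

.stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full simulated analysis workflow
#'
#' Simulates a tetraploidy scenario and pushes it through every stage:
#' quartet simulation, NG86 Ks on the homoeologous (A1-B1) and cross-copy
#' (A1-A2) pairs, mixture peaks, rate-calibrated dating, quartet topology
#' and Ks-asymmetry tests, LTR insertion-time dating, fractionation-bias and
#' homoeolog expression-bias statistics. A JSON report with the seed and all
#' thresholds is written when `outDir` is given.
#'
#' @param config a list from [runConfig()].
#' @param outDir optional output directory for `report.json`.
#' @return The report, invisibly when written, otherwise visibly.
#' @export
runPipeline <- function(config, outDir = NULL) {
  sc <- config$scenario
  quartets <- .stageTry("simulate", simulateQuartets(sc, config$nGenes))

  ks_tab <- .stageTry("ks", {
    do.call(rbind, lapply(quartets, function(q) {
      s <- quartetSequences(q)
      homo <- computeKaKs(s[["A1"]], s[["B1"]])
      cross <- computeKaKs(s[["A1"]], s[["A2"]])
      data.frame(gene_id = q@geneId,
                 ks_a1b1 = ksValue(homo), usable_a1b1 = isUsable(homo),
                 ks_a1a2 = ksValue(cross), usable_a1a2 = isUsable(cross))
    }))
  })

  ks_vals <- ks_tab$ks_a1b1[ks_tab$usable_a1b1]
  peaks <- .stageTry("peaks", {
    if (length(ks_vals) >= 50L) {
      fitKsPeaks(ks_vals, kMax = 3L, seed = config$seed, ksCap = config$ksCap)
    } else NULL
  })

  cal <- rateCalibration(sc@rateR, "simulation true rate")
  dating <- .stageTry("dating", {
    list(ks_peak_ages_ma = if (!is.null(peaks)) {
      round(divergenceTime(peakMeans(peaks), cal), 3L)
    } else divergenceTime(mean(ks_vals), cal))
  })

  calls <- .stageTry("quartet-test", {
    do.call(rbind, lapply(quartets, classifyQuartetSequences))
  })
  support <- sharedWgdSupport(calls)

  asym <- .stageTry("allo-test", {
    ok <- ks_tab$usable_a1b1 & ks_tab$usable_a1a2
    alloAutoTest(ks_tab$ks_a1b1[ok], ks_tab$ks_a1a2[ok],
                 alpha = config$alpha, minEffect = config$minEffect)
  })

  ltr <- .stageTry("ltr", {
    sim <- simulateLtrPairs(config$nLtr, config$ltrTimesMa, sc@rateR,
                            seed = config$seed + 1L)
    est <- vapply(sim$pairs, ltrInsertionTime, numeric(1), cal = cal)
    list(mode_ma = round(.densityMode(est[is.finite(est)]), 3L),
         n = length(est))
  })

  anchors <- .stageTry("fractionation", {
    simulateFractionation(config$nAnchors, config$lossA, config$lossB,
                          seed = config$seed + 2L)
  })
  frac <- fractionationBiasTest(retentionProfile(anchors))

  heb <- .stageTry("heb", {
    se <- simulateExpression(config$bias, seed = config$seed + 3L)
    hebSummary(hebClassify(se, fcThreshold = config$fcThreshold,
                           fdr = config$fdr))
  })

  report <- list(
    package = "allopolykit",
    version = as.character(utils::packageVersion("allopolykit")),
    seed = config$seed,
    thresholds = config[c("ksCap", "fcThreshold", "fdr", "alpha", "minEffect")],
    scenario = list(wgd_mode = sc@wgdMode, t_wgd_ma = sc@tWgd,
                    t_speciation_ma = sc@tSpeciation, rate_r = sc@rateR,
                    omega = sc@omega, n_codons = sc@nCodons),
    quartet_test = list(counts = as.list(support$counts),
                        fraction_shared = support$fraction_shared),
    ks = list(n_usable = length(ks_vals),
              peak_means = if (!is.null(peaks)) peakMeans(peaks) else NULL,
              peak_k = if (!is.null(peaks)) nPeaks(peaks) else NULL),
    dating = dating,
    allo_auto_test = list(verdict = asymmetryVerdict(asym), p = asym@pValue,
                          delta_mode = asym@effect),
    ltr = ltr,
    fractionation = list(global_p = frac$global$p,
                         lost_a = frac$global$lost_a,
                         lost_b = frac$global$lost_b),
    heb = heb[c("n_pairs", "n_comparisons", "biased_any", "biased_all",
                "percent_b_biased")]
  )
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
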