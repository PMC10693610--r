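#' @import methods
#' @importFrom stats binom.test density median p.adjust pt rnorm rpois runif
#'   sd ave setNames t.test wilcox.test var
#' @importFrom utils head read.delim write.table
#' @importFrom Biostrings DNAStringSet width readBStringSet writeXStringSet
#' @importFrom mclust Mclust mclustBIC
#' @importClassesFrom Biostrings DNAStringSet XStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Scenario configuration for the quartet simulator
#'
#' Describes a two-species tetraploid history: either one allotetraploidy
#' event shared by both species (`SHARED`, polyploidy predates speciation) or
#' two independent events (`INDEPENDENT`, each lineage duplicates after
#' speciation). Times are in million years (Ma); the synonymous substitution
#' rate is per site per year.
#'
#' @slot wgdMode `"SHARED"` or `"INDEPENDENT"`.
#' @slot tWgd WGD time in Ma (under `INDEPENDENT`, the per-lineage event time).
#' @slot tSpeciation speciation time in Ma.
#' @slot rateR synonymous substitution rate, substitutions/site/year.
#' @slot omega acceptance probability of a nonsynonymous change, in \[0, 1\].
#' @slot nCodons number of codons per simulated gene.
#' @slot seed integer seed.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(
    wgdMode = "character", tWgd = "numeric", tSpeciation = "numeric",
    rateR = "numeric", omega = "numeric", nCodons = "integer", seed = "integer"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- character(0)
  if (!object@wgdMode %in% c("SHARED", "INDEPENDENT")) {
    msg <- c(msg, "wgdMode must be 'SHARED' or 'INDEPENDENT'")
  }
  if (!isTRUE(object@tWgd > 0) || !isTRUE(object@tSpeciation > 0)) {
    msg <- c(msg, "all times must be > 0")
  }
  if (object@wgdMode == "SHARED" && !isTRUE(object@tWgd > object@tSpeciation)) {
    msg <- c(msg, "a SHARED WGD must predate speciation (tWgd > tSpeciation)")
  }
  if (object@wgdMode == "INDEPENDENT" &&
      !isTRUE(object@tWgd < object@tSpeciation)) {
    msg <- c(msg, "INDEPENDENT WGDs must postdate speciation (tWgd < tSpeciation)")
  }
  if (!isTRUE(object@rateR > 0)) msg <- c(msg, "rateR must be > 0")
  if (!isTRUE(object@omega >= 0 && object@omega <= 1)) {
    msg <- c(msg, "omega must be in [0, 1]")
  }
  if (!isTRUE(object@nCodons >= 1L)) msg <- c(msg, "nCodons must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ScenarioConfig
#'
#' @param wgdMode `"SHARED"` or `"INDEPENDENT"`.
#' @param tWgd WGD time (Ma).
#' @param tSpeciation speciation time (Ma).
#' @param rateR synonymous substitution rate per site per year. The default,
#'   6.5e-9, is the synonymous rate conventionally used for grasses.
#' @param omega nonsynonymous acceptance probability.
#' @param nCodons codons per gene.
#' @param seed integer seed.
#' @return A [ScenarioConfig-class] object.
#' @examples
#' scenarioConfig("SHARED", tWgd = 18.19, tSpeciation = 10)
#' @export
scenarioConfig <- function(wgdMode, tWgd, tSpeciation, rateR = 6.5e-9,
                           omega = 0.2, nCodons = 500L, seed = 1L) {
  new("ScenarioConfig", wgdMode = as.character(wgdMode), tWgd = as.numeric(tWgd),
      tSpeciation = as.numeric(tSpeciation), rateR = as.numeric(rateR),
      omega = as.numeric(omega), nCodons = as.integer(nCodons),
      seed = as.integer(seed))
}

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig:", object@wgdMode,
      sprintf("| tWgd=%g Ma tSpeciation=%g Ma r=%g omega=%g nCodons=%d seed=%d\n",
              object@tWgd, object@tSpeciation, object@rateR, object@omega,
              object@nCodons, object@seed))
})

#' A simulated collinear gene quartet
#'
#' Five in-frame coding sequences: the two homoeologous copies in species A
#' (`A1`, `A2`), the two in species B (`B1`, `B2`), and an outgroup (`OUT`),
#' together with the true generating topology.
#'
#' @slot sequences a named [Biostrings::DNAStringSet] with names
#'   `A1, A2, B1, B2, OUT`.
#' @slot trueTopology `"SHARED"` or `"INDEPENDENT"`.
#' @slot geneId identifier.
#' @exportClass SimulatedQuartet
setClass("SimulatedQuartet",
  representation(sequences = "DNAStringSet", trueTopology = "character",
                 geneId = "character")
)

setValidity("SimulatedQuartet", function(object) {
  msg <- character(0)
  if (!setequal(names(object@sequences), c("A1", "A2", "B1", "B2", "OUT")) ||
      length(object@sequences) != 5L) {
    msg <- c(msg, "sequences must be named A1, A2, B1, B2, OUT (each once)")
  }
  w <- Biostrings::width(object@sequences)
  if (length(unique(w)) != 1L) msg <- c(msg, "all sequences must be equal length")
  if (any(w %% 3L != 0L)) msg <- c(msg, "sequence length must be divisible by 3")
  if (!object@trueTopology %in% c("SHARED", "INDEPENDENT")) {
    msg <- c(msg, "trueTopology must be SHARED or INDEPENDENT")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulatedQuartet-class accessor for the sequences.
#' @param x a `SimulatedQuartet`.
#' @export
quartetSequences <- function(x) x@sequences

#' @describeIn SimulatedQuartet-class accessor for the generating topology.
#' @export
trueTopology <- function(x) x@trueTopology

setMethod("show", "SimulatedQuartet", function(object) {
  cat("SimulatedQuartet", object@geneId, "|", object@trueTopology, "|",
      Biostrings::width(object@sequences)[1] / 3, "codons\n")
})

#' Homoeolog expression-bias simulation settings
#'
#' Ground-truth specification for [simulateExpression()]: how many homoeolog
#' pairs, what fraction is biased toward each subgenome, the bias magnitude,
#' and the experiment layout.
#'
#' @slot nPairs number of homoeolog pairs.
#' @slot fracBBiased fraction of pairs biased toward subgenome B.
#' @slot fracABiased fraction biased toward subgenome A.
#' @slot effectLog2fc log2 expression shift of a biased pair.
#' @slot dispersion replicate-level sd on the log2 scale.
#' @slot nConditions number of tissues/treatments.
#' @slot nReplicates biological replicates per condition.
#' @exportClass BiasSpec
setClass("BiasSpec",
  representation(nPairs = "integer", fracBBiased = "numeric",
                 fracABiased = "numeric", effectLog2fc = "numeric",
                 dispersion = "numeric", nConditions = "integer",
                 nReplicates = "integer")
)

setValidity("BiasSpec", function(object) {
  msg <- character(0)
  if (object@fracABiased < 0 || object@fracBBiased < 0 ||
      object@fracABiased + object@fracBBiased > 1) {
    msg <- c(msg, "biased fractions must be >= 0 and sum to <= 1")
  }
  if (object@nReplicates < 2L) msg <- c(msg, "need >= 2 replicates")
  if (object@effectLog2fc <= 0) msg <- c(msg, "effectLog2fc must be > 0")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@nPairs < 1L || object@nConditions < 1L) {
    msg <- c(msg, "nPairs and nConditions must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BiasSpec
#'
#' Defaults mirror a typical allopolyploid expression design: eight condition
#' groups (five tissues plus three stress treatments) with four biological
#' replicates each.
#'
#' @param nPairs,fracBBiased,fracABiased,effectLog2fc,dispersion,nConditions,nReplicates
#'   see [BiasSpec-class].
#' @return A [BiasSpec-class] object.
#' @export
biasSpec <- function(nPairs, fracBBiased = 0, fracABiased = 0,
                     effectLog2fc = 2, dispersion = 0.35,
                     nConditions = 8L, nReplicates = 4L) {
  new("BiasSpec", nPairs = as.integer(nPairs),
      fracBBiased = as.numeric(fracBBiased),
      fracABiased = as.numeric(fracABiased),
      effectLog2fc = as.numeric(effectLog2fc),
      dispersion = as.numeric(dispersion),
      nConditions = as.integer(nConditions),
      nReplicates = as.integer(nReplicates))
}

#' Pairwise NG86 Ka/Ks result
#'
#' @slot ka nonsynonymous substitutions per nonsynonymous site (NA if
#'   saturated or unusable).
#' @slot ks synonymous substitutions per synonymous site (NA if saturated or
#'   unusable).
#' @slot nSites,sSites nonsynonymous/synonymous site counts (averaged over the
#'   two sequences); they sum to 3 x `usableCodons`.
#' @slot nd,sd pathway-averaged nonsynonymous/synonymous difference counts.
#' @slot saturated TRUE when pS >= 3/4 so Ks is undefined.
#' @slot usableCodons codons comparable in both sequences (no gap/N/stop).
#' @slot usable FALSE when fewer than 30 comparable codons.
#' @exportClass KsResult
setClass("KsResult",
  representation(ka = "numeric", ks = "numeric", nSites = "numeric",
                 sSites = "numeric", nd = "numeric", sd = "numeric",
                 saturated = "logical", usableCodons = "integer",
                 usable = "logical")
)

#' @describeIn KsResult-class Ks accessor.
#' @param x a `KsResult`.
#' @export
ksValue <- function(x) x@ks

#' @describeIn KsResult-class Ka accessor.
#' @export
kaValue <- function(x) x@ka

#' @describeIn KsResult-class TRUE unless the alignment had <30 comparable
#'   codons or was synonymous-saturated.
#' @export
isUsable <- function(x) x@usable && !x@saturated

setMethod("show", "KsResult", function(object) {
  cat(sprintf(
    "KsResult: Ka=%s Ks=%s | N=%.2f S=%.2f Nd=%.2f Sd=%.2f | %d codons%s%s\n",
    format(object@ka, digits = 4), format(object@ks, digits = 4),
    object@nSites, object@sSites, object@nd, object@sd, object@usableCodons,
    if (object@saturated) " [saturated]" else "",
    if (!object@usable) " [unusable]" else ""))
})

#' Gaussian mixture fitted to a Ks distribution
#'
#' @slot k selected number of components.
#' @slot means component means, ascending.
#' @slot sds component standard deviations.
#' @slot weights mixing proportions (sum to 1).
#' @slot bic BIC score per candidate k (selection trace).
#' @exportClass PeakModel
setClass("PeakModel",
  representation(k = "integer", means = "numeric", sds = "numeric",
                 weights = "numeric", bic = "numeric")
)

setValidity("PeakModel", function(object) {
  msg <- character(0)
  if (abs(sum(object@weights) - 1) > 1e-9 || any(object@weights < 0)) {
    msg <- c(msg, "weights must be non-negative and sum to 1")
  }
  if (is.unsorted(object@means)) msg <- c(msg, "means must be sorted ascending")
  if (any(object@sds <= 0)) msg <- c(msg, "sds must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn PeakModel-class component means.
#' @param x a `PeakModel`.
#' @export
peakMeans <- function(x) x@means

#' @describeIn PeakModel-class selected number of components.
#' @export
nPeaks <- function(x) x@k

setMethod("show", "PeakModel", function(object) {
  cat("PeakModel: k =", object@k, "\n")
  print(data.frame(mean = object@means, sd = object@sds,
                   weight = object@weights))
})

#' Synonymous-rate calibration for divergence dating
#'
#' @slot rate substitutions per synonymous site per year (> 0).
#' @slot source free-text provenance of the rate.
#' @exportClass RateCalibration
setClass("RateCalibration",
  representation(rate = "numeric", source = "character"))

setValidity("RateCalibration", function(object) {
  if (!isTRUE(object@rate > 0)) "rate must be > 0" else TRUE
})

#' Construct a RateCalibration
#'
#' @param rate substitutions/site/year.
#' @param source free-text description of where the rate comes from.
#' @return A [RateCalibration-class].
#' @examples
#' rateCalibration(6.5e-9, "grass synonymous rate")
#' @export
rateCalibration <- function(rate, source = "user-supplied") {
  new("RateCalibration", rate = as.numeric(rate), source = as.character(source))
}

#' @describeIn RateCalibration-class rate accessor.
#' @param x a `RateCalibration`.
#' @export
substitutionRate <- function(x) x@rate

setMethod("show", "RateCalibration", function(object) {
  cat(sprintf("RateCalibration: r = %g subs/site/year (%s)\n",
              object@rate, object@source))
})

#' Result of the allo- vs autotetraploid Ks-asymmetry test
#'
#' For one reference chromosome and its two duplicated counterparts: the two
#' Ks samples are compared by a Mann-Whitney rank test, with the difference of
#' density modes as effect size.
#'
#' @slot statistic Mann-Whitney W.
#' @slot pValue two-sided p-value.
#' @slot mode1,mode2 density modes of the two Ks samples.
#' @slot effect `mode2 - mode1`.
#' @slot n1,n2 usable sample sizes.
#' @slot verdict `"ALLO_CONSISTENT"`, `"AUTO_CONSISTENT"` or `"INCONCLUSIVE"`.
#' @exportClass AsymmetryResult
setClass("AsymmetryResult",
  representation(statistic = "numeric", pValue = "numeric", mode1 = "numeric",
                 mode2 = "numeric", effect = "numeric", n1 = "integer",
                 n2 = "integer", verdict = "character")
)

#' @describeIn AsymmetryResult-class verdict accessor.
#' @param x an `AsymmetryResult`.
#' @export
asymmetryVerdict <- function(x) x@verdict

setMethod("show", "AsymmetryResult", function(object) {
  cat(sprintf(
    "AsymmetryResult: %s | p=%.3g, modes %.3f vs %.3f (delta %.3f), n=%d/%d\n",
    object@verdict, object@pValue, object@mode1, object@mode2, object@effect,
    object@n1, object@n2))
})
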