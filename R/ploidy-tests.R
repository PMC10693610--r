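# Allo- vs autotetraploid origin from Ks asymmetry, and shared vs independent
# WGD from collinear gene-quartet topologies.

#' Jukes-Cantor distance matrix for a set of aligned sequences
#'
#' Pairwise JC-corrected nucleotide distances over columns where both
#' sequences carry an unambiguous base.
#'
#' @param sequences a named `DNAStringSet` (or character vector) of aligned,
#'   equal-length sequences.
#' @param geneId identifier used in error messages.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
jcDistanceMatrix <- function(sequences, geneId = "") {
  s <- toupper(as.character(sequences))
  if (length(unique(nchar(s))) != 1L) stop("sequences must be equal length")
  chars <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  acgt <- chars %in% c("A", "C", "G", "T")
  dim(acgt) <- dim(chars)
  n <- length(s)
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- acgt[i, ] & acgt[j, ]
      if (!any(ok)) stop("no comparable columns between ", names(sequences)[i],
                         " and ", names(sequences)[j],
                         if (nzchar(geneId)) paste0(" (", geneId, ")"))
      jc <- .jcCorrect(mean(chars[i, ok] != chars[j, ok]))
      if (is.na(jc)) {
        stop("saturated pair ", names(sequences)[i], "-", names(sequences)[j],
             if (nzchar(geneId)) paste0(" in ", geneId))
      }
      d[i, j] <- d[j, i] <- jc
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around [ape::nj()] used as the dependency-free core of the
#' quartet topology test; externally inferred ML trees can be supplied to
#' [classifyQuartet()] instead via [readNewickFile()].
#'
#' @param distances a symmetric numeric matrix (>= 4 taxa) or `dist`.
#' @return An unrooted `phylo` tree.
#' @export
njTree <- function(distances) {
  m <- as.matrix(distances)
  if (nrow(m) < 4L) stop("neighbor joining needs at least 4 taxa")
  if (any(!is.finite(m))) stop("distance matrix contains non-finite values")
  ape::nj(m)
}

#' Classify a gene-quartet tree as supporting shared or independent WGD
#'
#' The tree over `A1`, `A2`, `B1`, `B2`, `OUT` is rooted at the outgroup; the
#' in-group must resolve into two cherries. Each A copy sistering a B copy
#' (either pairing — the copy indices carry no intrinsic meaning) supports one
#' allotetraploidy event shared by both species (`SHARED`); copies sistering
#' within species (`(A1,A2)` with `(B1,B2)`) support independent events
#' (`INDEPENDENT`). Any other arrangement, including multifurcations and
#' trees where the in-group is not monophyletic after rooting, is `OTHER`.
#'
#' @param tree a `phylo` with tip labels exactly
#'   `A1`, `A2`, `B1`, `B2`, `OUT`.
#' @param geneId identifier carried into the result.
#' @return `data.frame` with columns `gene_id` and `call`.
#' @examples
#' classifyQuartet(ape::read.tree(text = "((A1,B1),(A2,B2),OUT);"))
#' @export
classifyQuartet <- function(tree, geneId = "") {
  labels <- c("A1", "A2", "B1", "B2", "OUT")
  if (!inherits(tree, "phylo") || !setequal(tree$tip.label, labels) ||
      length(tree$tip.label) != 5L) {
    stop("tree must have exactly the tip labels A1, A2, B1, B2, OUT")
  }
  call <- tryCatch({
    rt <- ape::root(ape::unroot(tree), outgroup = "OUT", resolve.root = TRUE)
    ing <- ape::drop.tip(rt, "OUT")
    .classifyIngroup(ing)
  }, error = function(e) "OTHER")
  data.frame(gene_id = geneId, call = call, stringsAsFactors = FALSE)
}

# Rooted 4-tip in-group tree -> SHARED / INDEPENDENT / OTHER.
.classifyIngroup <- function(ing) {
  if (is.null(ing) || ape::Ntip(ing) != 4L || ing$Nnode != 3L) return("OTHER")
  root <- ape::Ntip(ing) + 1L
  kids <- ing$edge[ing$edge[, 1L] == root, 2L]
  if (length(kids) != 2L || any(kids <= 4L)) return("OTHER")
  cherry <- function(node) {
    tips <- ing$edge[ing$edge[, 1L] == node, 2L]
    if (length(tips) != 2L || any(tips > 4L)) return(NULL)
    sort(ing$tip.label[tips])
  }
  p1 <- cherry(kids[1L]); p2 <- cherry(kids[2L])
  if (is.null(p1) || is.null(p2)) return("OTHER")
  if (identical(p1, c("A1", "A2")) || identical(p1, c("B1", "B2"))) {
    return("INDEPENDENT")
  }
  "SHARED"  # both cherries mix one A copy with one B copy
}

#' Summarize topology calls across gene quartets
#'
#' @param calls a `data.frame` from [classifyQuartet()] (rows bound together)
#'   or a character vector of calls.
#' @return A list with `counts` (named), `fractions`, `fraction_shared`, and
#'   `percent_shared` (one decimal).
#' @examples
#' sharedWgdSupport(c(rep("SHARED", 748), rep("INDEPENDENT", 252)))
#' @export
sharedWgdSupport <- function(calls) {
  x <- if (is.data.frame(calls)) calls$call else as.character(calls)
  if (length(x) == 0L) stop("no topology calls supplied")
  lev <- c("SHARED", "INDEPENDENT", "OTHER")
  counts <- table(factor(x, levels = lev))
  fr <- as.numeric(counts) / length(x)
  names(fr) <- lev
  list(counts = setNames(as.integer(counts), lev), fractions = fr,
       fraction_shared = fr[["SHARED"]],
       percent_shared = round(100 * fr[["SHARED"]], 1L))
}

# density mode of a numeric sample
.densityMode <- function(x) {
  d <- density(x)
  d$x[which.max(d$y)]
}

#' Ks-asymmetry test for allo- vs autotetraploid origin
#'
#' Compares the Ks distributions between a reference chromosome and each of
#' its two duplicated counterparts. Under autotetraploidy both duplicates
#' diverged from the reference lineage at the same time and the distributions
#' coincide; under allotetraploidy the two subgenomes diverged from the
#' reference at different depths and the distributions separate. A
#' Mann-Whitney rank test supplies the p-value and the difference of density
#' modes the effect size: `ALLO_CONSISTENT` requires `p < alpha` and
#' `|delta mode| >= minEffect`; `AUTO_CONSISTENT` requires `p >= alpha` and
#' `|delta mode| < minEffect`; anything else (including fewer than 20 usable
#' values in either sample) is `INCONCLUSIVE`.
#'
#' @param ksRefVsDup1,ksRefVsDup2 numeric Ks samples (non-finite values
#'   dropped).
#' @param alpha significance level.
#' @param minEffect minimum mode difference (Ks units) considered meaningful.
#' @return An [AsymmetryResult-class].
#' @export
alloAutoTest <- function(ksRefVsDup1, ksRefVsDup2, alpha = 0.05,
                         minEffect = 0.05) {
  x <- ksRefVsDup1[is.finite(ksRefVsDup1)]
  y <- ksRefVsDup2[is.finite(ksRefVsDup2)]
  if (length(x) < 20L || length(y) < 20L) {
    return(new("AsymmetryResult", statistic = NA_real_, pValue = NA_real_,
               mode1 = NA_real_, mode2 = NA_real_, effect = NA_real_,
               n1 = length(x), n2 = length(y), verdict = "INCONCLUSIVE"))
  }
  wt <- suppressWarnings(wilcox.test(x, y))
  m1 <- .densityMode(x)
  m2 <- .densityMode(y)
  eff <- m2 - m1
  verdict <- if (wt$p.value < alpha && abs(eff) >= minEffect) {
    "ALLO_CONSISTENT"
  } else if (wt$p.value >= alpha && abs(eff) < minEffect) {
    "AUTO_CONSISTENT"
  } else {
    "INCONCLUSIVE"
  }
  new("AsymmetryResult", statistic = unname(wt$statistic),
      pValue = wt$p.value, mode1 = m1, mode2 = m2, effect = eff,
      n1 = length(x), n2 = length(y), verdict = verdict)
}

#' Infer and classify the topology of a sequence quartet
#'
#' Convenience wrapper: JC distances, neighbor joining, then
#' [classifyQuartet()].
#'
#' @param quartet a [SimulatedQuartet-class] or a named `DNAStringSet` with
#'   names `A1`, `A2`, `B1`, `B2`, `OUT`.
#' @return `data.frame` with `gene_id` and `call`; distance saturation or
#'   other failures yield an `OTHER` call rather than an error.
#' @export
classifyQuartetSequences <- function(quartet) {
  if (is(quartet, "SimulatedQuartet")) {
    seqs <- quartet@sequences
    id <- quartet@geneId
  } else {
    seqs <- quartet
    id <- ""
  }
  tryCatch(
    classifyQuartet(njTree(jcDistanceMatrix(seqs, id)), id),
    error = function(e) data.frame(gene_id = id, call = "OTHER",
                                   stringsAsFactors = FALSE)
  )
}
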