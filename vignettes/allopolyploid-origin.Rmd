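---
title: "Testing allopolyploid origins: methods and design"
author: "allopolykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing allopolyploid origins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopolykit)
```

# The scientific problem

Many plant genomes are ancient tetraploids. Given a chromosome-scale
assembly of such a species and that of a close tetraploid relative, three
questions recur:

1. **Allo- or autotetraploid?** Did the genome arise by hybridization of two
   diverged lineages (two subgenomes, A and B) or by duplication within one
   lineage?
2. **One WGD or two?** Do the two species descend from a *single shared*
   allotetraploidy event, or did each lineage polyploidize independently
   after they separated?
3. **What happened to the subgenomes afterwards?** Was gene loss
   (fractionation) biased toward one subgenome, and is the expression of
   homoeologous gene copies dominated by one side?

`allopolykit` implements the statistics used to answer these questions from
synonymous divergence (Ks), collinear gene quartets, anchor tables, and
expression matrices — together with a seeded simulator so every stage can be
validated against known ground truth without any external data.

# Synonymous divergence: the NG86 engine

All dating in the package rests on Ks, the number of synonymous
substitutions per synonymous site, computed by the Nei–Gojobori (1986)
counting method:

* Each codon contributes fractional synonymous sites: one third of its nine
  single-nucleotide neighbors that encode the same amino acid. Mutations
  creating stop codons count as nonsynonymous; codons containing `N`, a gap,
  or a stop in either sequence of a pair are skipped symmetrically. Site
  totals are averaged between the two sequences, so `N + S = 3 L` over the
  `L` comparable codons.
* Differences within a codon pair are partitioned into synonymous and
  nonsynonymous by averaging uniformly over all minimal mutational pathways;
  pathways that pass through a stop codon are discarded (in the rare case
  that every pathway is blocked, all are retained so the counts stay
  defined).
* The proportions `pS = Sd/S` and `pN = Nd/N` receive the Jukes–Cantor
  multiple-hit correction `d = -(3/4) log(1 - 4p/3)`. A proportion at or
  above 3/4 is outside the correction's domain: the result is flagged
  *saturated* and the corresponding rate left undefined rather than
  extrapolated.

We chose NG86 with uniform pathway weighting and the JC correction — rather
than a maximum-likelihood codon model — because it is the method the widely
used collinearity toolchains compute downstream of synteny detection, it is
assumption-light, and its simple generative expectation (`Ks = 2rt`,
below) makes the whole pipeline checkable end to end. Alignments with fewer
than 30 comparable codons are flagged unusable instead of raising an error,
so genome-scale sweeps do not abort on fragmentary genes. The standard
genetic code is assumed throughout.

The engine is verified against an independently written brute-force NG86
implementation (explicit neighbor enumeration and pathway recursion) to
1e-9 on a thousand random codon alignments.

# Ks distributions, mixture peaks, and dating

Per-pair Ks values are summarized per syntenic block (`blockSummary()`, mean
by default, median selectable; saturated and unusable pairs excluded;
blocks with fewer than 5 usable pairs flagged). Distributions of block or
pair Ks are decomposed into Gaussian components with `fitKsPeaks()`:
expectation–maximization fits for `k = 1..kMax` components with BIC model
selection, delegated to *mclust*, with values filtered to `(0, ksCap]`
beforehand. The cap defaults to `ksCap = 3` because beyond that divergence
the JC correction operates at the edge of saturation and peak positions
carry no usable dating signal.

Peaks convert to ages by the molecular-clock identity `T = K / (2r)` with
`r` in substitutions per synonymous site per year and `T` reported in Ma
(`divergenceTime()`); `calibrateRate()` inverts the identity when a peak of
known age is available, and the two are exact inverses (round-trip error
below 1e-12). The same machinery dates LTR retrotransposon insertions
(`ltrInsertionTime()`): the 5′ and 3′ terminal repeats are identical at
insertion, so their JC distance over unambiguous columns, divided by `2r`,
is the element's age. We report ages to 3 decimals (kyr resolution, well
below any biological signal).

No absolute rate ships as "the" default in analysis functions — the user or
the simulation supplies `r`. Where the package itself needs a concrete
value (simulator defaults, the acceptance workflow), it uses
`r = 6.5e-9`/site/year, the synonymous rate conventionally applied to
grasses; at that rate a Ks peak near 0.13 corresponds to a ~10 Ma
divergence.

# The quartet topology test for a shared WGD

For each collinear gene present in both tetraploid species, the four copies
`A1`, `A2` (species A) and `B1`, `B2` (species B) plus an outgroup sequence
form a quartet. If one allotetraploidy event predates speciation, each copy
in species A is sister to a copy in species B: rooted at the outgroup, the
in-group resolves as `((A1,B1),(A2,B2))`. If instead each species
polyploidized independently, copies are sister within species:
`((A1,A2),(B1,B2))`.

`classifyQuartet()` roots the gene tree at `OUT`, requires the in-group to
form two cherries, and maps them to `SHARED`, `INDEPENDENT`, or `OTHER`.
Two design choices matter:

* **Label matching.** The copy indices 1 and 2 are arbitrary within each
  species, so *both* mixed pairings (`A1B1|A2B2` and `A1B2|A2B1`) count as
  `SHARED`: the biological hypothesis is "each A copy sisters a B copy",
  not a particular indexing.
* **Strict rooted form.** A tree like `((A1,B1),(A2,OUT),B2)` induces the
  mixed unrooted split yet places the outgroup inside the in-group; it is
  called `OTHER`, not `SHARED`. This is conservative: distorted gene trees
  reduce, never inflate, the shared-event count.

Trees come either from the internal neighbor-joining core (JC distance
matrix + NJ, `classifyQuartetSequences()`) or from externally inferred ML
trees imported as Newick. NJ replaces the ML/quartet-frequency stage of
genome-paper pipelines with direct counting of supporting gene trees; on
simulated 2000-codon quartets this classifier recovers the generating
scenario in at least 95% of genes (observed: 100% for both scenarios at the
default settings), so little would be gained from a heavier tree method at
these divergences. No bootstrap-support filter is applied by default.

`sharedWgdSupport()` tabulates calls; its `percent_shared` is the
count-of-supporting-gene-trees statistic (e.g. 748 of 1000 trees = 74.8%).

# The Ks-asymmetry test for allo- vs autotetraploidy

Under autotetraploidy the two duplicated chromosome sets diverged from a
syntenic reference chromosome of a related species at the same time, so
their Ks distributions against that reference coincide. Under
allotetraploidy the two subgenomes join the reference lineage at different
depths and the distributions separate. Genome papers usually argue this
visually from dotplots; `alloAutoTest()` formalizes it: a Mann–Whitney rank
test between the two Ks samples plus a difference-of-density-modes effect
size. The verdict is `ALLO_CONSISTENT` when `p < alpha` *and*
`|Δmode| >= minEffect`, `AUTO_CONSISTENT` when both conditions fail, and
`INCONCLUSIVE` otherwise or when either sample has fewer than 20 usable
values. Defaults `alpha = 0.05` and `minEffect = 0.05` Ks units are explicit
formalizations of "apparently different"; both are configurable, and the
effect-size gate keeps large-sample significance on biologically negligible
shifts from flipping the verdict. On 1000 null replicates the false-ALLO
rate is far below `alpha` (the conjunction of the two gates makes the test
conservative).

# Fractionation and homoeolog expression bias

`retentionProfile()` counts, per reference chromosome, anchors retaining
the A copy, the B copy, or both. `fractionationBiasTest()` applies an exact
binomial test to the singletons (A-lost vs B-lost, null 0.5) per chromosome
— BH-adjusted across chromosomes — and pooled; chromosomes with fewer than
10 singletons are flagged low-power.

`callDE()` implements the DEG rule "at least a twofold change at
FDR < 0.05": per-gene Welch tests on `log2(TPM + 1)` with BH adjustment, DE
iff `|log2FC| >= 1` *and* adjusted `p < 0.05`. This deliberately simple
engine is a declared stand-in for a negative-binomial count model: TPM
matrices carry no library-size information, the module accepts externally
produced DE tables wherever DE flags are consumed, and every threshold is a
parameter. `hebClassify()` applies the same test within conditions to the
two copies of each homoeolog pair (`log2_ratio` is B over A; "B-biased"
means B significantly higher); pairs where neither copy reaches 1 mean TPM
in a condition are `UNTESTABLE`, and the pseudocount is 1.
`hebSummary()` reports pairs biased in at least one condition, pairs biased
in *all* conditions (requiring a consistent direction by default —
`requireSameDirection = FALSE` relaxes this), and the share of comparisons
biased toward B.

`orthologDegConcordance()` compares, per treatment, the tissue-direction
pattern (up/down/ns in shoot and root) of ortholog pairs that are DE in
both species; `CONSERVED` requires the identical pattern across both
tissues, including agreement on non-significance. Percentages are reported
to the nearest integer for concordance and to one decimal elsewhere,
matching how such tables are conventionally printed.

# What the simulator emulates — and what it does not

`simulateQuartets()` evolves codon sequences along the five-taxon scenario
tree by a proposal–acceptance process: each nucleotide position proposes
uniform changes with per-branch intensity `d`; synonymous proposals are
always accepted, nonsynonymous ones with probability `omega`, and proposals
creating stops never. Because acceptance of synonymous changes is free, the
realized synonymous clock equals `d` regardless of `omega`, giving the
exact generative identity the dating formula assumes: a pair separated for
`t` Ma has expected `Ks = 2rt` before saturation. This is the simplest
process whose synonymous clock matches `T = K/2r`; the empirical mean Ks
over replicate pairs at `2rt = 0.2` reproduces 0.2 within ±0.02.

Scenario geometry: under `SHARED` the WGD (default 18.19 Ma) precedes
speciation (default 10 Ma) — validity enforces `tWgd > tSpeciation` — and
under `INDEPENDENT` the order reverses, with one duplication per lineage at
the same `tWgd`. The outgroup always diverges at twice the oldest in-group
event, guaranteeing rootability. Defaults `omega = 0.2` (moderate purifying
selection) and 500 codons (a typical CDS length) are used where a test does
not set its own.

The remaining generators are deliberately plain: expression matrices are
log-normal TPM with a half-effect shift applied symmetrically to the two
copies of biased pairs (`dispersion = 0.35` on the log2 scale, a typical
replicate spread under controlled conditions; four replicates and eight
condition groups by default, mirroring a five-tissue + three-treatment
design); fractionation draws per-anchor loss with probabilities `lossA`,
`lossB` conditioned on never losing both copies (the joint-loss mass is
renormalized onto retention, so marginal loss rates are slightly below the
nominal values — negligible for the rates used here); LTR pairs mutate the
two repeats independently at rate `r` without the codon machinery.

None of these generators model indels, recombination, gene conversion
between homoeologs, rate variation among sites or lineages, incomplete
lineage sorting, mapping noise, or count overdispersion beyond log-normal.
Passing tests therefore certify the *statistics* — that each estimator
recovers the truth of its own generative model at the stated tolerances —
not robustness to every artifact of real genome data. The import paths
(Newick trees, DE tables, anchor TSVs) exist precisely so that real
pipelines can substitute their own upstream inference.

All generators are deterministic given their seed; each operation seeds its
own stream so stages cannot contaminate one another.

# Numerical choices and degenerate inputs

* JC correction returns `NA` (never an error) at `p >= 3/4`; saturated
  pairs are excluded from block summaries and peak fitting.
* `fitKsPeaks()` refuses fewer than 50 usable values and numerically
  constant input (degenerate variance); mixture components are reported
  sorted by mean with weights renormalized to sum to one.
* NJ ties are resolved deterministically by the underlying implementation;
  non-finite distances are an error, as is a saturated quartet pair
  (reported with its gene id). `classifyQuartetSequences()` converts such
  failures into `OTHER` calls so cohort-level counting proceeds.
* Welch tests on constant replicate vectors fall back to `p = 1` when the
  group means agree and `p = 0` otherwise.
* `alloAutoTest()` answers `INCONCLUSIVE`, not an exception, below 20
  values per sample; `fractionationBiasTest()` reports `NA` for
  chromosomes without singletons.

# Problem sizes

The validation suite runs entirely on simulated data sized to exercise each
property sharply while completing in minutes on one core: 200 quartets of
2000 codons per scenario for classifier accuracy, 100 replicate pairs for
the Ks clock, 2000 draws for mixture recovery, 500 elements for LTR dating,
1000 replicates for null calibration of the asymmetry test, and 2000
homoeolog pairs for HEB recovery and null FDR. These sizes were chosen so
that Monte-Carlo error is small relative to each tolerance; all of them are
parameters, and larger cohorts only tighten the recoveries.

# Known limitations

* NG86 underestimates divergence relative to ML codon models when
  substitution is strongly biased (e.g. transition-heavy) — acceptable here
  because the simulator and the estimator share the uniform-proposal model,
  but a caveat for real data with strong codon-usage bias.
* The quartet test assumes one collinear copy per subgenome per species;
  paralogy from later small-scale duplication must be filtered upstream.
* The DE engine is not a count model; for real RNA-seq, import DESeq2/edgeR
  results instead of relying on the built-in Welch test.
* LTR dating inherits every caveat of `T = K/2r`: rate uncertainty scales
  ages linearly, and gene conversion between repeats biases ages downward.
* The asymmetry test's `minEffect` is in Ks units and should be rescaled if
  the organisms' divergence regime differs greatly from the defaults.
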