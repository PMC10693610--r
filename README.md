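# allopolykit

Statistical tools for working out **how a tetraploid plant genome came to
be** — and what happened to its two subgenomes afterwards — from synonymous
divergence, collinear gene quartets, synteny anchor tables, and expression
matrices.

Many grasses (and plants generally) are ancient tetraploids. Given two
related tetraploid species, the recurring questions are:

* **Allo- or autotetraploid?** An autotetraploid's two duplicated
  chromosome sets show *identical* Ks distributions against a syntenic
  reference chromosome of a relative; an allotetraploid's two subgenomes
  join that reference at different depths, so the distributions separate.
  `alloAutoTest()` formalizes this with a Mann–Whitney rank test plus a
  difference-of-modes effect size.
* **One shared WGD or two independent ones?** For each collinear gene, the
  four copies A1, A2 (species A) and B1, B2 (species B) plus an outgroup
  form a quartet. Rooted at the outgroup, `((A1,B1),(A2,B2))` supports a
  single allotetraploidy event shared by both species, while
  `((A1,A2),(B1,B2))` supports independent events.
  `classifyQuartet()` / `sharedWgdSupport()` count supporting gene trees.
* **When?** Ks computed by the Nei–Gojobori (NG86) method with
  Jukes–Cantor correction (`computeKaKs()`), Gaussian-mixture peak fitting
  with BIC selection (`fitKsPeaks()`), and the molecular-clock conversion
  `T = K / 2r` (`divergenceTime()`, `calibrateRate()`), which also dates
  LTR retrotransposon insertions from 5′/3′ repeat divergence
  (`ltrInsertionTime()`).
* **Subgenome behaviour afterwards.** Exact binomial tests for biased
  fractionation (`retentionProfile()`, `fractionationBiasTest()`),
  twofold/FDR < 0.05 DE calling (`callDE()`), homoeolog expression-bias
  classification and summaries (`hebClassify()`, `hebSummary()`),
  cross-species orthologous-DEG concordance
  (`orthologDegConcordance()`), and tandem-duplicate DE summaries
  (`tandemDegSummary()`).

Every stage has a matching **seeded simulator** with known ground truth
(`simulateQuartets()`, `simulateSequencePair()`, `simulateExpression()`,
`simulateFractionation()`, `simulateLtrPairs()`), so the whole pipeline is
testable without any external data; `runPipeline()` composes the stages
end to end and writes a JSON report.

## Worked example

Simulate 50 collinear gene quartets under a shared allotetraploidy at
18.19 Ma followed by speciation at 10 Ma, classify their topologies, and
date both events from Ks:

```r
library(allopolykit)

cfg <- scenarioConfig("SHARED", tWgd = 18.19, tSpeciation = 10,
                      nCodons = 1000, seed = 7)
quartets <- simulateQuartets(cfg, 50)

calls <- do.call(rbind, lapply(quartets, classifyQuartetSequences))
support <- sharedWgdSupport(calls)
support$counts
#>      SHARED INDEPENDENT       OTHER
#>          50           0           0

ks_spec <- sapply(quartets, function(q) {   # A1 vs B1: split at speciation
  s <- quartetSequences(q); ksValue(computeKaKs(s[["A1"]], s[["B1"]]))
})
ks_wgd <- sapply(quartets, function(q) {    # A1 vs A2: split at the WGD
  s <- quartetSequences(q); ksValue(computeKaKs(s[["A1"]], s[["A2"]]))
})
cal <- rateCalibration(6.5e-9, "grass synonymous rate")
divergenceTime(mean(ks_spec), cal)  # mean Ks = 0.132 -> 10.13 Ma
divergenceTime(mean(ks_wgd), cal)   # mean Ks = 0.237 -> 18.22 Ma

alloAutoTest(ks_spec, ks_wgd)
#> AsymmetryResult: ALLO_CONSISTENT | p=7.07e-18, modes 0.134 vs 0.243
#>   (delta 0.109), n=50/50
```

All 50 gene trees support the shared event (100%); the two Ks cohorts date
the speciation to ~10.1 Ma and the WGD to ~18.2 Ma, recovering the
simulation's truth; and the asymmetry test reads the two separated Ks
distributions as allotetraploid-consistent — exactly the reasoning applied
to real genomes, here validated against known ground truth.

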