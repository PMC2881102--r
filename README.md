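# rsde — region-subtractive differential expression for two-color spotted arrays

`rsde` implements, as a tested R pipeline, a region-subtractive
differential-expression analysis for two-color spotted cDNA microarrays,
of the kind used to search for genes dysregulated in the frontal cortex of
Rett syndrome (RTT) brains while sparing the occipital cortex. It is aimed
at analysts who want the complete classical two-color workflow — stringency
QC, loess normalization, a noise-calibrated fold-change consensus, a
from-scratch one-class SAM, and four-comparison subtractive logic — as
plain, inspectable R functions, together with a synthetic study generator
that carries planted ground truth so every stage can be validated without
access to patient data. The companion validation-assay math (comparative-CT
qRT-PCR with exact Mann-Whitney tests, ChIP-qPCR enrichment over input,
first-order cytochrome c oxidase kinetics normalized to citrate synthase)
is included.

## The design and the statistics

Four comparison sets of six replicate co-hybridizations each (every one
repeated with the cyanine dyes reversed) cross disease status with brain
region:

* (a) `RTTfc_vs_CONfc` — disease vs control, frontal cortex
* (b) `RTTfc_vs_RTToc` — frontal vs occipital cortex, within disease
* (c) `CONfc_vs_CONoc` — frontal vs occipital cortex, within controls
* (d) `RTToc_vs_CONoc` — disease vs control, occipital cortex (reported,
  not used in the subtraction)

Genes *exclusive* to the disease frontal cortex are those called in (a) and
(b) but **not** in (c): the control regional comparison subtracts normal
frontal/occipital expression differences.

Per comparison, each array yields per-feature `M = log2(F635/F532)` and
`A = (log2 F635 + log2 F532)/2` after stringency filters (flagged features
removed; minimum intensity 200 in either channel; array accepted only if
the median-ratio normalization factor lies in [0.8, 1.2]) and robust
degree-1 loess detrending of `M` on `A`. Dye-swap pairs reconcile to one
replicate ratio `2^((M_fwd − M_swp)/2)`, and two arms call differential
expression:

1. **Calibrated fold-change consensus.** A self-self hybridization (same
   RNA in both channels) measures pure technical noise; with linear-ratio
   SD `σ` the thresholds are `1 + 2σ` and its two-decimal reciprocal — at
   the calibrated `σ = 0.25`, the classical `>1.5` / `<0.67` pair. A gene
   is called when at least 5 of its 6 replicate ratios pass in one
   direction (and none passes in the other).
2. **One-class SAM.** Per gene, `d_i = r̄_i / (s_i + s0)` on the replicate
   log ratios, with the fudge constant `s0` chosen by the Tusher
   coefficient-of-variation criterion. The null is the exhaustive set of
   `2^6 = 64` sign-flip permutations of the replicates; sorted observed
   `d` is compared with the permutation-expected order statistics, the
   threshold `delta` is the smallest on a scan whose estimated FDR (median
   permutation false calls ÷ observed calls) is at or below 0.05.

Per comparison the reported call set is the direction-agreeing overlap of
the two arms; the exclusive list is `(a ∩ b) \ c`.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (seed 1, 19,008 features, 140 planted effects of which 100 are
frontal-cortex-exclusive at 2-fold):

```sh
Rscript analysis/01_simulate.R      # generate arrays + ground truth
Rscript analysis/05_subtract.R      # full pipeline + subtractive step
```

`05_subtract.R` prints:

```
Region-subtractive differential-expression run
  thresholds: >1.496 / <0.67 (sigma 0.2480)
     comparison n_passed_cutoff fold_change sam overlap
 RTTfc_vs_CONfc           18967          94 107      94
 RTTfc_vs_RTToc           18963         129 139     129
 RTToc_vs_CONoc           18969          10  12      10
 CONfc_vs_CONoc           18967          30  31      30
  frontal-cortex-exclusive genes: 93
recovery: 93 / 100 planted frontal-exclusive genes (93%)
directions correct: TRUE
regional plants leaking into the exclusive list: 0
```

Reading it: ~18.9k of 19,008 features pass QC in at least 5 of 6
replicates ("passed cut-off"); the fold-change and SAM arms call
overlapping sets in every comparison; the subtraction removes the 30
planted normal regional differences (visible in `CONfc_vs_CONoc`) and
recovers 93 of the 100 planted exclusive genes, every one with the correct
direction. The same workflow in code:

```r
library(rsde)
cfg <- study_config(seed = 1)          # the full study design
run <- run_pipeline(cfg)               # QC -> loess -> FC + SAM -> subtract
run$summary                            # per-comparison counts (table above)
head(run$exclusive)                    # exclusive genes with provenance
```

`analysis/06_validation.R` exercises the assay math; e.g. a planted 2-fold
up-regulation in the disease frontal cortex at n = 6 vs 6 gives ratio 1.98
with exact Mann-Whitney p = 0.0022, and paired kinetics traces planted at
a 60% knockdown fit to a rate-constant ratio of 0.595.

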