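---
title: "Methods: region-subtractive differential expression for two-color arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-subtractive differential expression for two-color arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsde)
```

# The problem and the design

Rett syndrome pathology predominates in specific brain regions: the
frontal cortex shows the characteristic reduction in dendritic arborization
while the occipital cortex is comparatively spared. A region-subtractive
design exploits this: rather than asking only "what differs between disease
and control", it asks what differs in the affected region *and* between the
affected and spared regions of the same brains, *minus* whatever differs
between the same two regions in controls. Four comparison sets of six
replicate two-color co-hybridizations (each repeated dye-swapped) implement
this; the exclusive gene set is

$$\text{exclusive} = (a \cap b) \setminus c,$$

with $a$ = disease-vs-control frontal cortex, $b$ = frontal-vs-occipital
within disease, $c$ = frontal-vs-occipital within controls. The fourth
comparison ($d$, disease-vs-control occipital) is computed and reported but
deliberately excluded from the formula: differences there are read as
individual variation in a spared region, informative for provenance but not
for exclusivity. `run_pipeline()` orchestrates the whole procedure;
`exclusive_frontal()` is the set-algebra step, and records per-gene
provenance.

# Per-array processing

**Stringency filters** (`qc_policy()`, `apply_qc_filters()`). Flagged
features are always removed. A feature must reach a minimum absolute
intensity of 200 (arbitrary scanner units) in *either* the red (F635) or
green (F532) channel; the literal either-channel reading is the default and
a `"both"` switch is provided, because the plain-language rule is genuinely
ambiguous and the choice belongs in a visible policy object rather than in
buried code. The whole array is rejected when its normalization factor —
median F635 over median F532, unflagged features — falls outside
$[0.8, 1.2]$. We read "between 0.8 and 1.2" as a *closed* interval; the
boundary case is fixed by a test so the behavior cannot drift silently.
Rejection is a reported state (the replicate count decrements), not an
exception.

**Loess normalization** (`ma_values()`, `loess_normalize()`). Per feature
$M = \log_2(\mathrm{F635}/\mathrm{F532})$ and $A$ = mean log2 intensity;
$M$ is replaced by its residual from a robust local-linear fit of $M$ on
$A$ (tricube weights, span 0.4 as a fraction of the data, 3 robustness
iterations — conventional MA-normalization settings; the span and iteration
count are exposed as arguments). The fit uses `stats::lowess`, which is
exactly this estimator; fitted values are mapped back to input order, so
feature count and order are invariants. Degenerate inputs are guarded: a
constant $M$ is absorbed by the local intercept (tested to $10^{-6}$), and
fewer than 10 usable features is a hard normalization error.

**Dye-swap reconciliation** (`reconcile_dye_swap()`). A dye-specific bias
enters the forward and swapped $M$ with opposite sign, so the replicate
ratio is $2^{(M_f - M_s)/2}$. When only one orientation survives QC, that
single measurement is used — discarding it would shrink `usable_count`
without gaining anything; when neither survives, the replicate is missing.
We read the study's "six data sets" as six dye-swap-reconciled pairs
(not twelve individual arrays); this is the reading under which a
6-replicate consensus rule is meaningful, and it is stated here rather
than left implicit.

# Arm 1: calibrated fold-change consensus

A self-self hybridization labels two aliquots of one RNA batch; its linear
ratios spread purely by technical noise. With sample SD $\sigma$ of those
ratios, `calibrate_fold_threshold()` sets

$$\text{up} = 1 + 2\sigma, \qquad \text{down} = \mathrm{round}(1/\text{up}, 2),$$

an approximate 95% band for "no change". The $1+2\sigma$ form is fixed on
the *linear* ratio scale because it reproduces the classical calibration
pair exactly ($\sigma = 0.25 \Rightarrow 1.5$ and $0.67$); a log-scale
band does not. The two-decimal rounding of the down threshold is part of
the criterion, and the product $\text{up}\times\text{down}$ is therefore
only reciprocal to within rounding ($1.5 \times 0.67 = 1.005$) — tested as
such.

`call_de_foldchange()` calls a gene up when at least `min_support` usable
replicate ratios exceed the up threshold **and no ratio passes the down
threshold** (symmetrically for down). The zero-opposite-passes requirement
is the direction-consistency rule: it makes "called" monotone in
`min_support` (raising the support requirement can only retract calls) and
is indistinguishable from laxer readings at the study's 5-of-6 regime,
where a gene cannot pass 5 times in each direction. `min_support` defaults
to `ceiling(5/6 * n)` = 5 at $n = 6$. A gene with fewer than `min_support`
usable replicates is *non-evaluable* — reported distinctly from a definite
"none", and excluded from the per-comparison "passed cut-off" universe.

# Arm 2: one-class SAM

Each reconciled replicate ratio is already a paired test-vs-reference
contrast, so the one-class form applies to the per-gene log2 ratios
$x_{i1},\dots,x_{in}$:

$$d_i = \frac{\bar x_i}{s_i + s_0}, \qquad s_i = \frac{\mathrm{sd}(x_i)}{\sqrt{n_i}}.$$

At $s_0 = 0$, $d_i$ is the one-sample t statistic (tested against
`t.test`). $s_0$ is chosen by the Tusher criterion: candidates are
percentiles of the $s_i$ distribution; for each, the coefficient of
variation of the $d$ scores is computed across $s$-quantile windows (100
windows when $\ge 1000$ genes, else 10), and the minimizer wins. The
function's documented fallback — when the gene means needed to form $d$
are not supplied — is `median(s)`; all-equal scatters return that value
directly rather than failing.

**Permutation null.** The null distribution flips the signs of the
replicate *columns* jointly across genes: exhaustively ($2^n$ patterns, 64
at $n = 6$, including the identity) when $n \le 10$, else 1000 random
patterns from a fixed seed. Exhaustive enumeration makes the null fully
deterministic — no Monte-Carlo variance in the expected order statistics.
Genes with fewer than 4 usable replicates are excluded and reported.

**Calling convention.** Sorted observed $d$ is paired with the
permutation-expected order statistics $\bar d_{(i)}$. On the positive side
the cut point is the smallest non-negative $d$ whose excess
$d_{(i)} - \bar d_{(i)}$ reaches `delta`; *all* genes at or above it are
called (symmetrically below zero). We use this cut-point closure — the
convention under which the SAM plot is read — rather than calling
individual sorted positions, because with many strong effects the permuted
tails contain the planted genes themselves, inflating the top expected
order statistics; per-position calling would then paradoxically drop the
very strongest genes. `delta = 0` is treated as the vacuous band: every
evaluated gene is called, and the estimated FDR is 1 by construction.

**FDR and delta.** False calls are counted per permutation as permuted $d$
beyond the cut points; `estimated_fdr` is the median count over
permutations divided by the observed calls (the SAM-manual convention; the
90th-percentile variant is reported alongside, and no null-proportion
factor is applied). Zero observed calls report FDR 0 with a `no_calls`
flag. `choose_delta()` scans 101 thresholds from 0 to the largest
observed-vs-expected excess and returns the smallest whose estimated FDR
is at or below the target (default 0.05); if none qualifies the largest is
returned with `achieved = FALSE` and a warning.

# The overlap and the subtraction

Per comparison, the reported set is `overlap_calls()`: genes called by
both arms *with agreeing direction* — a direction conflict would make "up
in the disease frontal cortex" meaningless, so conflicting genes are
dropped rather than arbitrated. The per-arm 5-of-6 and FDR rules are
applied within their own arms, combined only by intersection. The
"passed cut-off" count reported per comparison is the evaluable universe:
genes with at least `min_support` usable reconciled replicates.

# What the generator emulates — and what it does not

`study_config()` + `generate_study()` produce the full design: 19,008
features per array, 4 comparison sets × 6 replicate pairs × 2 dye
orientations, one shared log2-normal baseline intensity profile (mean 11,
SD 1.2 on the log2 scale — median intensity ~2048 with a realistic dynamic
range for a 16-bit scanner), independent multiplicative per-channel noise,
uniform random flags at 2%, and planted effects applied multiplicatively
to the test sample on the linear scale.

The per-channel noise SD is *derived*, not tuned: if each channel carries
$N(0, s_c^2)$ log2 noise, the self-self linear ratio is lognormal with
variance $(e^v - 1)e^v$, $v = (2 s_c^2)(\ln 2)^2$; `channel_log2_sd()`
solves this exactly so that the generated self-self ratio SD equals the
configured 0.25. Consequently null comparison ratios match the self-self
distribution by construction (a tested invariant), and the calibration
operation applied to a generated self-self array recovers thresholds near
1.5/0.67.

Default planted truth: 100 frontal-exclusive genes at 2-fold (60 up, 40
down), 30 normal regional differences (planted in $b$ and $c$, which the
subtraction must remove), 10 occipital individual-variation genes (in $d$
only). One hundred exclusive genes keeps the binomial noise of a recovery
estimate near two percentage points; fewer genes would make sensitivity
estimates swing by the luck of single genes.

Deliberately *not* modeled: intensity-dependent (MA-curved) dye bias,
print-tip and spatial artifacts, background, biological between-subject
variance, and informative flagging. The generator's noise is homoskedastic
in log intensity, so the loess step has no trend to remove on synthetic
data — its detrending behavior is therefore tested separately on data with
a planted linear trend. Passing recovery tests on this generator show the
*procedure's* selectivity and sensitivity under calibrated technical
noise; they do not certify performance on real postmortem tissue, where
biological variance adds to the technical floor.

Reproducibility: every array derives its own substream seed
deterministically from the master seed and the array's identity, so
regeneration is order-independent and bit-identical (tested via
`identical()` on reruns).

# Validation-assay computations

*qRT-PCR* (`qpcr_relative_expression()`): technical replicates average on
the Ct scale within experiment, then across experiments; expression
relative to GAPDH from the same sample is $E^{\Delta Ct}$ with efficiency
$E = 2$ by default (no standard-curve correction; the efficiency is an
exposed parameter). The ratio is invariant to plate shifts that move both
Ct values equally. Group differences use `mann_whitney_exact()`: full
enumeration of all $\binom{n_1+n_2}{n_1}$ labelings up to combined
$n = 14$, mid-ranks for ties, two-sided tail probability
$P(U \le u_{low}) + P(U \ge n_1 n_2 - u_{low})$ capped at 1; beyond 14, a
tie-corrected normal approximation with continuity correction. No
multiple-testing correction is applied across validated genes, matching
the unadjusted reporting style of such assays.

*ChIP-qPCR* (`chip_fold_enrichment()`): comparative CT against input,
$2^{-(Ct_{IP} - (Ct_{input} - \log_2 f))}$ with $f$ the input fraction —
reserving 10% input adds $\log_2 10 \approx 3.32$ cycles of correction.
IgG background is reported alongside, never subtracted: it is a control,
not a correction term.

*COX kinetics* (`fit_first_order_rate()`): the absorbance decay at 550 nm
is log-linearized, $\ln(A(t) - A_\infty)$, and $k$ is the negated
least-squares slope divided by protein mass — the field reports this as
"rate/minute/mg protein", a first-order constant per mg, and the package
documents it as that stated unit rather than a physical claim. Points at
or below the plateau, and near-plateau points under 2% of the initial
amplitude (about 5.6 half-lives, where the log transform amplifies noise
without bound), are excluded; fewer than 3 surviving points is a fit
error. $A_\infty$ may be supplied or estimated as the mean of the trailing
10% of the trace; which was used is reported per fit. Citrate synthase
normalization (`cox_cs_ratio()`) is a guarded division.

# Problem sizes and numerical tolerances

The test suite exercises module behavior on small studies (hundreds of
features) and runs the full-scale conditions — 19,008 features, four
comparisons, six dye-swapped pairs, self-self SD 0.25, seed 1 — twice: a
planted study for recovery and a pure-null study for the false-flag rate.
These two runs take a few minutes together; the sizes are the study's own
conditions, not reduced stand-ins. Exact identities (threshold pair,
reciprocal rounding, Mann-Whitney enumerations, t-limit of $d$) are tested
to $10^{-12}$; loess fixed points to $10^{-6}$; noiseless kinetics
recovery to $10^{-6}$; stochastic checks (recovery ≥ 90%, null flags ≤
0.6%, qPCR power ≥ 80%) run at fixed seeds.

# Known limitations

* The generator's noise model is a stand-in: the original platform's
  per-channel noise process is not documented, and the homoskedastic
  log-normal choice is the simplest one consistent with the self-self
  calibration. MA-plot curvature, which loess normalization exists to
  remove, must be injected explicitly to be exercised.
* The consensus caller is deliberately count-based — no moderated-variance
  or shrinkage estimator — because the procedure under study is the
  count-based one.
* One-class SAM is the only SAM mode; two-class, multiclass and survival
  variants, and q-value curves beyond the delta scan table, are out of
  scope.
* Gene-level aggregation (`map_to_genes()`) is provided for the
  many-ESTs-per-symbol platform reality, but the pipeline operates at
  feature level; annotation-driven summaries are the caller's choice.
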