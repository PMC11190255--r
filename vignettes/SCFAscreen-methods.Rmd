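---
title: "SCFAscreen: models, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SCFAscreen: models, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SCFAscreen)
```

## The problem

Short-chain fatty acids (SCFAs — here acetic, propionic and butyric acid)
can be produced cheaply from organic waste through the carboxylate platform
and converted to microbial oils by oleaginous yeasts. Finding strains that
tolerate SCFAs at high concentration, consume them efficiently and
accumulate lipids requires screening large, taxonomically diverse strain
collections. SCFAscreen implements the analysis side of such a screen:
colony-size time courses from scanned agar plates are reduced to three
growth variables per strain and medium, neutral lipid content is quantified
from a Nile-red fluorescence plate assay, candidates are compared with a
reference strain using nonparametric statistics, a weighted-rank procedure
selects the best candidates, and liquid-fermentation experiments are
summarized into consumption, biomass and lipid-yield accounting. A
synthetic-data generator with known ground truth makes every stage testable
without access to any screening raw data.

## Growth model and the synthetic screen

The generator plants an offset logistic for every viable strain × medium
combination:

$$ s(t) = s_0 + \frac{K - s_0}{1 + e^{-r\,(t - t_{mid})}} $$

with initial size $s_0$ (a.u.), carrying capacity $K$ (a.u.), rate $r$
(1/h) and inflection time $t_{mid}$ (h). The logistic was chosen over
Gompertz or Richards because its inflection gives an unambiguous planted
"time at maximal growth" ($t_{mid}$) for recovery tests; non-viable
combinations stay flat at $s_0$. Lag is not an independent truth parameter:
it is derived from the same curve (see the lag definition below), which
keeps truth and estimator self-consistent.

Defaults mirror a time-course colony screen: sampling every 0.25 h for
96 h, three biological replicates, a glucose control plus three SCFA
compositions, plate densities 96/384/1536 with the reference strain pinned
onto every plate. Strain parameters are drawn as two groups — fast growers
($r \approx 0.25$/h, $t_{mid} \approx 42$ h) and slow growers
($r \approx 0.10$/h, $t_{mid} \approx 72$ h) — with bimodal lipid contents
(high ≈ 25 % and low ≈ 10 % of CDW), emulating the grouping of strains into
fast/slow and high-/low-lipid classes that diverse yeast panels show. On
SCFA media each strain is viable with probability 0.4 by default. No
published replicate-to-replicate variance estimates exist for these data,
so the noise defaults are the package's own and are deliberately modest.

**Noise model.** Multiplicative noise is applied as one scale factor per
colony (`noise_cv`, default CV 0.05): this is replicate-to-replicate
variability — pinning volume, inoculum density — which dominates the
variance of colony screens. Per-scan measurement noise enters as an
additive term (`noise_floor_sd`, default 1 a.u.), and sizes are truncated
at zero. Colonies are physical objects scanned every 15 min; their measured
size does not fluctuate independently by several percent between adjacent
scans, so putting the 5 % component on the per-colony scale rather than per
time point is the realistic choice. It also matters statistically: a
per-colony scale factor leaves lag and $t_{max}$ estimates invariant, while
iid 5 % per-point noise would make any sliding-window slope argmax unable
to localize the inflection to sub-hour precision (slope noise over a
window of width $W$ hours scales as $W^{-3/2}$ and would still exceed the
logistic slope curvature for any usable window).

What the generator does **not** emulate: spatial plate effects, pinning
grid artifacts, neighbor competition, pH drift, toxicity-dependent death,
or filamentous growth. Passing tests therefore demonstrate correctness of
the estimators and accounting under the stated model, not robustness to
every artifact of real plate data.

Determinism: one master seed; per-plate random streams are derived from
(seed, plate index) by a fixed affine map, so identical configurations are
byte-identical and plate subsets are reproducible.

## Growth phenotyping

`fitGrowthCurve()` reports, per colony:

* **fitness** — the smoothed size at the final time point (endpoint colony
  size, the screening fitness measure);
* **max_slope** and **t_max** — the maximum of least-squares slopes over
  sliding windows spanning 2 h (9 points at 0.25 h sampling) and the center
  time of the maximizing window; ties take the earliest window;
* **lag** — the first time the smoothed signal exceeds
  $s_0 + f\,(s_{max} - s_0)$ with $f = 0.05$;
* **s0** — the median of the first three smoothed points;
* **growth_call** — `TRUE` iff fitness ≥ 1.5 × s0 (relative threshold) and
  fitness ≥ an absolute threshold (default 0, i.e. inactive).

Smoothing is a centered rolling median of 5 points applied before all
derived quantities; it is robust to single-scan outliers and does not
distort monotone signals. The lag fraction, window width, smoothing window
and both call thresholds are exposed in `growthControl()` — the upstream
quantification tools do not publish their internal definitions, so these
are the package's own, explicit and configurable. For colonies called as
non-growers, `lag` and `t_max` are reported as `NA` rather than fabricated
numbers.

For curves that saturate within the scan window, the endpoint fitness
estimates the carrying capacity $K$; the recovery tests draw truths with
$r \in [0.12, 0.3]$/h and $t_{mid} \in [20, 55]$ h for exactly that
reason — for very slow, late-inflecting strains the endpoint is an honest
fitness readout but not an estimate of $K$.

Replicate aggregation uses medians (standard even-count rule); `lag` and
`t_max` medians include only replicates called as growers, and both the
total and growing replicate counts are recorded. Growth-call intersections
across media (`growthIntersections()`) report the number of strains
growing on ≥ 1 medium, on all media, and on each exclusive combination,
with percentages of the full screened panel computed by
`screenPercentage()` (half-up rounding at the reported precision, since
table-style percentages are conventionally rounded half away from zero).

## Normalization, RFU and statistics

* **Relative fitness** = 100 × fitness(SCFA) / fitness(glucose); undefined
  (NA) when the glucose reference is missing or non-positive.
* **Fold change** = value / reference − 1.
* **RFU** = max(0, stained − background) / OD595; negative
  background-corrected fluorescence is clamped to zero (a physically
  impossible reading treated as zero signal).
* **Max-abs scaling** divides each variable by its maximum absolute value
  (outputs in [−1, 1]); it is idempotent and scale-invariant, and all-zero
  variables are left untouched with a warning.

The statistical battery follows the screening convention: a Shapiro–Wilk /
Levene gate at α = 0.05 decides whether the nonparametric path is needed
(the package uses the Brown–Forsythe median-centered Levene variant, the
robust default of `car::leveneTest`; the centering choice is not dictated
by any published protocol). Candidate-vs-reference comparisons use the
two-sided Mann–Whitney U test: exact permutation p when
$n_1 n_2 \le 400$ and no ties are present, otherwise the normal
approximation with tie and continuity corrections. Two-sided testing is
used throughout because the screening question ("does the candidate differ
from the reference?") is directionless. Benjamini–Hochberg correction is
applied with one family per (variable, medium) across all candidate
strains; the family definition is recorded in the output table's
`bh_family` attribute and matters — pooling across variables would mix
scales of evidence. Lipid content across groups is assessed with both
one-way ANOVA (F) and Kruskal–Wallis; all-equal degenerate data take the
F = 0 path rather than erroring.

## Weighted ranking

For each variable, strains are sorted (fitness and lipid descending, t_max
ascending) and ranked so the best strain receives rank $n$ and the worst
rank 1, with average ranks on ties. Each fitness and t_max rank is
multiplied by $k_{growth} = 1.2$ and the lipid rank by $k_{lipid} = 1.6$;
the weighted ranks are summed and re-ranked so the largest score receives
the top final rank.

Three decisions the procedure's verbal description leaves open:

* **Ties** — average ranks within a variable; final-score ties are broken
  deterministically by strain id. Scores are compared at 1e-9 resolution
  so arithmetically equal scores tie regardless of floating-point
  summation order.
* **Missing values** — a strain that did not grow on a medium takes the
  worst rank for that variable (implemented by worst-value substitution,
  so a single missing strain gets exactly rank 1 and several missing
  strains share averaged worst ranks, keeping each variable's ranks a
  permutation of 1..n); the number of substituted variables is flagged per
  strain.
* **Weight semantics** — with fitness and t_max measured on three media
  plus one lipid variable (7 columns), literal multiplication gives lipid
  a share of $1.6 / (6 \times 1.2 + 1.6) \approx 18\,\%$, not the nominal
  60 %. The default mode is the literal procedure; `mode = "grouped"`
  applies the stated group importances instead (growth variables jointly
  40 %, lipid 60 %). Neither is asserted to be "the" published arithmetic.

`selectTop()` returns the requested number of best strains (default 11,
the size of the candidate set carried into fermentation).

## Media design and fermentation accounting

`designMedium()` converts a total SCFA concentration and an A:P:B ratio to
per-acid masses. In carbon mode (default — compositions like 3:1:1 are
carbon ratios) the masses solve $\sum m_i = $ total with carbon masses
$c_i m_i$ proportional to the ratio, using carbon mass fractions
$c = (2 \cdot 12.011/60.052,\ 3 \cdot 12.011/74.079,\ 4 \cdot
12.011/88.106)$ for acetic, propionic and butyric acid. Mass mode
(proportional masses) is provided for sensitivity checks.
`ammoniumSulphateForCN()` returns the ammonium sulphate setting a target
C/N mass ratio, counting SCFA carbon only and using the nitrogen fraction
$2 \cdot 14.007 / 132.14 \approx 0.212$ of ammonium sulphate.

Consumption accounting: per-acid consumption is
$100\,(C_0 - C_{end})/C_0$, clamped to [0, 100] (final readings above the
initial one are measurement noise). The **total** consumption is the
carbon-weighted mean of the per-acid percentages with weights proportional
to the A:P:B ratio (3:1:1 → 3/5, 1/5, 1/5), rounded half-up to the integer
for table-style reporting; this rule reproduces the reference-strain and
candidate "Total" cells of the published consumption tables exactly from
their printed per-acid values (a mass-weighted alternative is available
via explicit weights). Censored table entries ("<10 %") are parsed as 0 by
default (configurable to the interval midpoint 5) — the zero rule is what
reproduces the printed totals. Lipid yield is
$Y_{L/S} = (\text{lipid \%}/100) \cdot \text{biomass} / \Delta S$ (g lipid
per g SCFA consumed), with `biomassForYield()` as the inverse consistency
check for published triplets where biomass itself is not printed. The
consumption rate is $\Delta S / \Delta t$ in g/(L·h).

The fermentation generator uses sequential piecewise-linear uptake with
preference weights: while a more-preferred acid remains above zero, less
preferred acids run at 20 % of their rate (default preference acetic >
propionic > butyric, matching the observed consumption preference and the
toxicity ordering butyric > propionic > acetic). OD600 rises with
cumulative substrate consumed times the biomass yield, converted at 1 OD =
0.45 g CDW/L. Only endpoint accounting is published for such experiments,
so the simplest monotone kinetic model suffices; Monod saturation, pH
dynamics and inhibition are deliberately out of scope.

## Pipeline

`runStage()`/`runPipeline()` orchestrate simulate → phenotype → lipids →
stats → rank → ferment. Every stage writes tab-delimited tables plus a
provenance sidecar (config hash, seed, package version, output hashes);
outputs contain no timestamps, so identical configs are byte-identical —
the determinism tests compare raw file bytes. Stages validate that their
upstream stages have run and name the stage to run first otherwise. A thin
`Rscript` front end (`inst/scripts/run_pipeline.R`) exposes the same
functions with `--config/--outdir/--seed/--stage` flags; YAML configs are
read by `readPipelineConfig()`.

The growth-call aggregation in the pipeline calls a strain a grower on a
medium when the majority of its replicates are called growers.

## Problem sizes and numerical choices in the test suite

The property suites run at sizes chosen to exercise the estimators
meaningfully while staying quick on a laptop: 200 synthetic colonies for
recovery (noiseless and at CV 0.05), full Mann–Whitney enumeration up to
$n_1 n_2 \le 36$, 1000 random p-vectors for the BH oracle, all panels of
≤ 6 strains against a literal-procedure ranking oracle, 100 random media
for the carbon round-trip, and a 24-strain planted-truth screen across 20
seeds for end-to-end selection. Tolerances mirror the quantity's nature:
1e-9 for exact linear-algebraic identities (media design), 1e-12 for pure
arithmetic, one sampling interval for time estimates.

## Known limitations

* The growth-call threshold (1.5 × s0) is a package default; initial
  endpoint-only screens may need a different, absolute threshold
  (`theta_abs`) depending on scanner calibration.
* Fitness is an endpoint measure; it equals carrying capacity only for
  curves that saturate within the scan.
* The ranking reproduces the published *procedure*; reproducing published
  rank values verbatim would require the deposited raw phenotype data.
* The fermentation generator is a planning/testing tool, not a kinetic
  model of SCFA metabolism.
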