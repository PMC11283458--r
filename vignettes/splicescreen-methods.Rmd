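---
title: "Methods: normalization, gating, and simulation in splicescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, gating, and simulation in splicescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

## The measurement model

A reciprocal dual-luciferase splicing reporter expresses one luciferase
when the target microexon is included and the other when it is skipped.
In the V1 orientation inclusion yields Firefly (FLuc), skipping NanoLuc
(NLuc); the V2 orientation is the reverse. If a fraction
$p = \mathrm{PSI}/100$ of reporter transcripts include the exon, the
expected signals are linear in $p$:

$$ S_\mathrm{incl} = \kappa_\mathrm{incl}\, p, \qquad
   S_\mathrm{skip} = \kappa_\mathrm{skip}\, (1 - p), $$

with luciferase gains $\kappa$. With equal gains the *percent inclusion
luminescence* (percent FLuc for V1, percent NLuc for V2) equals PSI
exactly, which is why the luminescence fraction is a faithful linear
proxy for RT-PCR PSI; `psi_to_luminescence()` and
`percent_luminescence()` implement the two directions of this map. The
per-well readout used for screening is the ratio FLuc/NLuc (V1) or
NLuc/FLuc (V2), so in both arms a higher ratio means more inclusion, and
a genuine splicing modulator shifts both arms' ratios in the same
direction while a single-luciferase artifact shifts them in opposite
directions.

## Control-masked median polish and B-scores

Plates carry systematic row/column trends (edge evaporation, dispenser
and reader gradients). `median_polish()` decomposes each plate's ratio
matrix as

$$ v_{ij} = \mu + \alpha_i + \beta_j + r_{ij} $$

by iterated median sweeps: per iteration the overall median of the
current residuals is absorbed into $\mu$, then row medians into
$\alpha_i$, then column medians into $\beta_j$. Two properties are worth
stating precisely:

* **Masking.** Control and empty wells never contribute to any median,
  but every subtraction is applied to them, so control wells end up with
  residuals — and B-scores — on the same scale as samples. A direct
  consequence (tested exactly) is that sample-well results are invariant
  to arbitrary changes of control-well values.
* **Decomposition identity.** Because every quantity subtracted is
  credited to an effect, $v = \mu + \alpha + \beta + r$ holds to floating
  precision for every well at every iteration, independent of sweep
  order. The residuals themselves do depend on the sweep order, which is
  therefore fixed (overall, rows, columns) and documented rather than
  left to chance. On purely additive matrices the order cannot matter and
  the routine agrees with `stats::medpolish()` to 1e-9.

Convergence is declared when the sum of absolute unmasked residuals
changes by less than `tol` (default 0.01, the classic median-polish
default) relative to itself, with `max_iter = 100` as a guard; even-count
medians are the usual mean of the two central values, relevant because
384-well rows and columns have even sample counts. Missing wells
(zero-denominator ratios) are skipped in all medians and never imputed.

The **B-score** of a well divides its residual by the plate's median
absolute residual over sample wells, so every plate scales to a median
absolute sample score of exactly 1. This divisor is deliberately the
plain median absolute residual; `bscore(use_mad = TRUE)` switches to the
1.4826-scaled MAD, which makes scores comparable to z-scores (see the
null-calibration section for why this distinction matters). A plate
whose median absolute residual is zero — more than half of its sample
residuals exactly zero, as in a noise-free synthetic null plate — cannot
be scaled and is reported as a failed plate by `normalize_screen()`
without affecting other plates.

## The hyperbolic hit gate

With $x$ and $y$ the per-compound B-scores of the V1 and V2 ratios
(replicate wells within an arm collapsed by their median — multi-well
aggregation is otherwise arbitrary and the median is robust), the gate
margin is

$$ M = \frac{(x - y/(-7)) \cdot (-y + x/(-7))}{-2}
     = \frac{(x + y/7)(y + x/7)}{2}, $$

and $M \ge 4$ defines a hit; the two algebraic forms are the same
polynomial and the package verifies their agreement to 1e-12. $M$ is
symmetric under exchange of $x$ and $y$ and positive only outside the
wedge bounded by the asymptotes $y = -x/7$ and $y = -7x$. The two
branches are separated by the sign of the diagonal projection $x + y$:
positive for activators, negative for inhibitors. This separator is the
package's choice — the branch membership rule is not forced by the
boundary equation — and it is the unique unambiguous one, since
$x + y = 0$ implies $M \le 0$ and so never co-occurs with a passing
margin. Boundary points ($M$ exactly 4) are counted as hits; the rule is
arbitrary but fixed and concerns a measure-zero set.

Two behavioral notes, both covered by tests:

* A strongly anti-concordant pair ($y = -x$) is never a hit at any
  magnitude: this is the geometry that rejects single-luciferase
  artifacts, which move the two arms' ratios in opposite directions.
* A *uni*-directional pair ($x$ large, $y \approx 0$) is rejected only as
  long as $|x|$ stays below the point where the branch crosses the axis
  ($x^2/14 \ge 4$, i.e. $|x| \gtrsim 7.5$); beyond that the gate admits
  it. The gate excludes the majority of unidirectional signals, not all
  of them, and the admission rate for axis-hugging compounds equals the
  probability of the orthogonal score crossing the branch boundary.

Gate constants (divisor 7, threshold 4) are defaults of
`hyperbola_params()` and can be re-fit for other reporter pairs.

## Dose–response validation

The secondary screen measures each cherry-picked hit over a 10-point
two-fold series (40 nM–20 µM). For each concentration the effect score is
the log2 ratio-of-ratios against same-plate DMSO medians,

$$ e = \log_2 \mathrm{rel FLuc} - \log_2 \mathrm{rel NLuc} $$

for V1 (sign flipped for V2): it is symmetric in the two luciferases,
scale-free, and positive toward inclusion. "Comparable change" is
quantified as $|e| \ge$ `effect_threshold` (default 0.5, i.e. a ~40%
ratio shift — large enough to clear the ~14% CV of the ratio under 10%
per-luciferase noise, small enough to keep sub-saturating doses) with the
sign expected from the primary call, at `min_consecutive = 2` or more
consecutive concentrations. The effective range is the longest qualifying
run (ties resolved toward higher concentrations, since potency is read
downward from the top dose); raising the threshold can only shrink or
abolish runs, never create them — the monotonicity is tested across a
threshold sweep. Results are invariant to the input row order because the
series is sorted by concentration internally. No sigmoid is fitted: the
effective range is a property of the measured grid, not of an
interpolated EC50.

## What the simulator emulates

`simulate_screen()` generates plate pairs in which each compound occupies
the same well of a V1 and a V2 plate:

* **Baselines.** Reporter PSI 42 (V1) and 33 (V2) — mid-range baselines
  chosen so both directions of modulation are visible.
* **Controls.** Column 1 holds 16 DMSO wells (ΔPSI 0); column 2 holds 8
  TSA-like (ΔPSI +25) and 8 Scriptaid-like (ΔPSI +20) positive-control
  wells, HDAC-inhibitor-like activators at typical strengths; the
  remaining 352 wells are samples. The layout is fully configurable.
* **True modulators** shift PSI by the same ΔPSI in both arms
  (ΔPSI ~ N(±20, 5) by default), the reciprocal signature. With unequal
  arm baselines an identical ΔPSI does not produce identical ratio *fold
  changes* in the two arms — the fold changes agree exactly only when the
  baselines agree, which is how the exact reciprocity property is tested;
  under the default baselines the shifts are concordant in sign and
  similar in magnitude, which is what the gate requires.
* **Unidirectional artifacts** multiply exactly one luciferase's output
  in both arms (log2FC ~ N(±1.5, 0.3)), the non-reciprocal signature.
  Because the same luciferase is affected in both cell lines, the two
  arms' ratios move in opposite directions and such compounds land in the
  anti-concordant wedge.
* **Spatial artifacts** are additive on the ratio scale (row and column
  offsets, SD 10% of the arm's baseline ratio by default) — precisely the
  structure an additive median polish removes. A
  `spatial_scale = "log_luminescence"` mode instead perturbs one
  luciferase multiplicatively, a deliberate model mismatch for stress
  testing.
* **Noise** is multiplicative log-normal per luciferase per well with
  CV 10%, mean exactly 1.
* **Determinism.** All draws derive from the master seed through
  per-plate substreams, so two runs with the same configuration are
  identical and adding plates never changes earlier plates; the
  generator restores the caller's RNG state.
* **Dose curves.** `simulate_dilution()` scales each compound's true
  effect by a saturating Hill-1 occupancy $c/(c + \mathrm{EC}_{50})$,
  EC50 1 µM by default (mid-grid for a 40 nM–20 µM series).

PSI is clamped to [1, 99] after applying effects — complete inclusion or
skipping would make one luciferase signal exactly zero, which the linear
reporter map treats as degenerate.

The simulator does **not** model cell growth or compound toxicity,
transfection-dose response of trans-acting factors, inter-plate batch
drift, luminescence crosstalk between wells, or heavy-tailed instrument
glitches. Passing the recovery tests therefore shows the pipeline is
correct and well-calibrated *for the stated noise model*, not that any
particular real screen will achieve the same precision.

## Null calibration and the B-score scale

One acceptance-level property deserves an honest account. Under the
plain median-absolute-residual divisor, near-normal plate noise gives
sample B-scores a standard deviation of about
$1/\Phi^{-1}(0.75) \approx 1.48$, not 1. Rotating coordinates
($u = (x+y)/\sqrt2$, $v = (x-y)/\sqrt2$) turns the gate condition
$M \ge 4$ into $16u^2 - 9v^2 \ge 196$, and with independent
$\sigma \approx 1.48$ scores on both axes that region captures on the
order of 1–3% of pure-noise compounds — the package's own null-screen
simulation (`scripts/acceptance.R`, `null_hit_rate_percent`) measures
about 2.4% at the default conditions. With the z-like MAD scale
(`use_mad = TRUE`) the same geometry admits well under 0.5%. The default
remains the plain median-absolute-residual scale because that is the
B-score definition this pipeline is built around; the consequence —
threshold 4 on that scale is a permissive gate whose hit list needs the
secondary dilution screen to weed out noise passengers — is inherent to
the method, and the secondary-validation rate reported by the acceptance
script quantifies exactly that. In the recovery scenario (15% active
compounds) the plate scale is inflated by the active wells, which shrinks
inert compounds' scores and keeps precision high.

## Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline at 10 plates
per arm (3,520 compounds, 7,680 wells) for recovery and null calibration,
2 plates per arm for structural unit tests, 100 random matrices for the
polish exactness property, and a 10⁴-point grid for the gate form
agreement; these sizes make every property measurable in seconds while
keeping estimator noise (e.g. on a 3,520-compound hit rate) far below the
asserted margins. Convergence tolerances, the even-median convention,
tie-breaks and degenerate-input behavior are each pinned by a dedicated
test rather than left implementation-defined.

## Known limitations

* Hit calling requires a compound in both arms; single-arm compounds are
  reported, not gated.
* The polish assumes additive row/column structure on the chosen ratio
  scale; multiplicative spatial artifacts are only removed approximately
  (use `log2_ratio = TRUE` if artifacts are fold-change-like).
* The gate is purely geometric: no error model, no FDR. Significance
  comes from the secondary screen, not the primary margin.
* PSI analytics assume band intensities are already background-corrected
  numbers; densitometry is out of scope.
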