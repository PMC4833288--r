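---
title: "Quantifying membrane fluidity, transgene mosaicism and lipid saturation in C. elegans glucose-toxicity assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane fluidity, transgene mosaicism and lipid saturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfluid)
```

## Background

Dietary glucose rigidifies cellular membranes in *C. elegans* mutants that
cannot mount a compensatory fatty-acid desaturation response: glucose is
converted to saturated fatty acids (SFAs), membrane phospholipids turn over
rapidly, and unless Δ9 desaturases are upregulated the membranes lose
fluidity to a lethal degree. Three quantitative assays probe this biology,
and `memfluid` implements the analysis of each:

1. **FRAP** (fluorescence recovery after photobleaching) on a prenylated GFP
   in intestinal membranes measures fluidity in vivo: a small region is
   bleached and the return of fluorescence, carried by lateral diffusion of
   unbleached membrane-bound GFP, is summarized by the *mobile fraction* and
   the *half-time of recovery* (t½).
2. **Mosaic analysis** exploits the stochastic mitotic loss of multicopy
   extrachromosomal arrays. Worms carrying a rescuing transgene plus a
   ubiquitous nuclear GFP marker are selected for survival on glucose, the
   marker is scored across tissues of known embryonic lineage, and the cell
   divisions at which the array was lost are inferred — revealing in which
   founder lineages the gene is *not* required.
3. **Lipidomics composition tables** (mol% of fatty acids per carbon-count ×
   double-bond bin, within phosphatidylcholine and phosphatidylethanolamine)
   are summarized into SFA/MUFA/PUFA shares and mean double bonds, and
   contrasted between conditions.

Small-assay statistics (Wald proportion intervals for fractions of fertile
adults, Welch t-tests for worm lengths) and a codon-change annotator for
mutant-allele tables round out the toolkit.

## The FRAP pipeline

A raw trace (`frap_trace`) holds the bleached-ROI and a non-bleached
reference-ROI intensity series on a uniform frame grid. Processing follows a
fixed order:

1. **Acquisition-bleaching correction** (`correct_acquisition_bleaching`).
   Repeated scanning slowly bleaches the whole field. A least-squares line
   $r(t)$ is fitted to the reference region and both series are divided by
   $r(t)/r(t_0)$. We treat the loss as *multiplicative* (photobleaching
   destroys a proportion of fluorophores per scan, so the loss scales with
   the signal); the guard property is that a zero-slope reference leaves the
   trace bit-identical. A fitted trend that is not strictly positive over
   the window is an error rather than a silent sign flip.
2. **Bleach-frame detection** (`detect_bleach_index`): the global minimum of
   the corrected bleached-ROI series, earliest frame on ties. It must leave
   at least five earlier frames for the baseline window.
3. **Normalization** (`normalize_trace`). With $F_{min}$ the value at the
   bleach frame and $\bar F_{pre}$ the mean of the five frames immediately
   preceding it,
   $$ f(t) = \frac{F(t) - F_{min}}{\bar F_{pre} - F_{min}}. $$
   The minimum is subtracted *before* the pre-bleach value is formed, so the
   plateau of $f$ is a fraction of the bleached-away signal — which is what
   "mobile fraction" means. By construction $f = 0$ at the bleach frame and
   the pre-bleach window averages 1; both are enforced as invariants.
4. **Model-free estimation** (`estimate_recovery`). The mean of the final
   five measurements approximates the recovery plateau and is reported as
   the mobile fraction; t½ is the time, relative to the bleach frame, of the
   first *upward* crossing of half the plateau, linearly interpolated
   between the bracketing frames. Monotonicity is not assumed. A curve that
   never reaches half its plateau yields `t_half = NA` plus a QC flag, and a
   mobile fraction above 1.2 (possible under noise) is flagged rather than
   rejected.

Both estimators are invariant to rescaling both intensity channels and
equivariant under rescaling time (t½ scales, the mobile fraction does not);
these properties are tested on randomized traces.

`fit_exponential` adds a cross-check: a least-squares fit of
$M(1 - 2^{-t/\tau})$ to the post-bleach segment, in half-time
parameterization so that $\tau$ is directly comparable to the model-free t½.
The analysis itself stays model-free; the fit exists so that simulations can
confirm the two routes agree. We deliberately do not fit diffusion models
(Soumpasis/Axelrod): the summaries of interest are defined non-parametrically.

`summarize_group` aligns normalized curves on the bleach frame (no
resampling — mixed frame intervals are an error), reports mean ± sem per time
point, and compares groups pairwise with Welch t-tests on t½ and mobile
fraction. When both groups are constant and equal, p is 1 by convention.

### The trace generator

`gen_frap_traces` emulates what the estimators assume: a 12-bit-scale
pre-bleach plateau $P$, a bleach event leaving fraction $b$, recovery
$P[b + M(1-b)(1 - 2^{-\Delta t/\tau})]$, linear multiplicative acquisition
bleaching $(1 - s t)$ on both regions, and additive Gaussian noise. It does
**not** emulate spatial structure, Poisson photon statistics, worm movement,
or focus drift — so passing parameter-recovery tests demonstrates estimator
correctness under the stated model, not robustness to every artifact of live
imaging.

Defaults: plateau 1000 AU, bleach depth 0.2, frames every 0.5 s, 10
pre-bleach frames, and an 80-frame (40 s) post-bleach window. The window
length is a bias calculation, not a convenience: the plateau estimator
averages the last five frames, whose truncation bias is approximately
$M \cdot \overline{2^{-\Delta t/\tau}} \approx M\,2^{-(T - 1)/\tau}$ for
window length $T$. At $\tau = 5$ s a 30 s window still carries ~1.5% of $M$
as bias; 40 s brings it under 0.5%, comfortably below the 1% accuracy we
require of the estimator, while recovery itself is complete within ~30 s.

## Dollo-parsimony mosaic inference

Arrays are lost at cell divisions and never regained, so a worm's loss
history is an *antichain* of lineage-tree nodes (no node an ancestor of
another). The packaged tree has 21 nodes: the founder divisions
(P0 → AB/P1, AB → ABa/ABp, P1 → EMS/P2, EMS → MS/E, P2 → C/P3, P3 → D/P4)
plus the sublineage chains needed to place the scored spermatheca, gonad
sheath, pharyngeal and excretory cells.

Each scored tissue is a weighted set of lineage contributions (e.g.
procorpus = 4 ABa + 2 MS). Under a loss hypothesis $H$ the *positive
fraction* of a tissue is the weight not descending from any loss event, and
calls are graded: fraction 1 → `+`, 0 → `-`, ≥ 0.5 → `+/-`, < 0.5 → `-/+`.
The 0.5 boundary maps to `+/-` (majority-inclusive) — the recorded legend
defines "majority positive" without a tie rule, so we declare one.

`infer_losses` scores every antichain of at most `max_events` candidate
nodes:

$$ cost(H) = \alpha\,|H| + \sum_t w_t\, p\, |rank(pred_t) - rank(obs_t)| $$

with $\alpha = 1$ per loss event, $p = 0.5$ per ordinal grade on the
`-` < `-/+` < `+/-` < `+` scale, and $w_t = 0.5$ for the two neuronal rows
annotated only as "mostly ABp" (modelled as a declared 3:1 ABp:ABa split and
down-weighted as soft evidence). These weights encode a deliberate
trade-off: one full-grade scoring error (cost $2p = 1$) never beats an extra
loss event outright, matching how human scorers tolerate single inconsistent
tissues when calling a worm "missing from P1". Candidates are restricted to
nodes that affect at least one scored tissue; a loss in an unsampled lineage
(P4) is unidentifiable and would only inflate tie sets.

**Identifiability limit.** The same trade-off means a loss event whose
*entire* evidence is a single one-grade shift — a loss at ABar, ABara or
ABaraa moves only the isthmus/metacorpus call from `+` to `+/-` — has
omission penalty ≤ α and is, by design, attributed to scoring noise rather
than inferred. Exact recovery on noise-free simulations therefore holds for
truths whose every event carries omission penalty above α, and up to
prediction equivalence (a loss at ABpl, ABplp or ABplpa changes exactly the
same calls; {MS, E} predicts identically to the cheaper {EMS}). The test
suite computes the identifiability condition programmatically rather than
hard-coding a node list.

`founder_summary` maps loss nodes to the founder vocabulary used in the
recorded summaries (a node below a founder reports, e.g., `MS (partial)`),
and `concordance_report` compares cost-minimal hypotheses with the recorded
"Likely missing from" row, excluding the one worm whose recorded call is
annotated as uncertain. The recorded summaries are treated as an evaluation
surface only — inference never reads them. Full per-row agreement is not
expected: the recorded calls were made by eye, and parsimony sometimes
prefers a strictly cheaper equivalent (e.g. {E, P2} for a recorded
"E, C, D", identical in predictions because P4 is unscored); the report
surfaces such conflicts instead of hiding them.

The cohort generator (`gen_mosaic_cohort`) realizes the Dollo process
literally — independent loss per division edge with a given probability,
heritable and irreversible — derives calls through `predict_calls`, and can
corrupt calls by exactly one ordinal grade (mimicking scoring ambiguity, not
arbitrary flips).

## Lipid composition arithmetic

Inputs are fatty-acid-level (carbons × double bonds) mol% tables per lipid
class; conversion from intact-species data is out of scope because
species→fatty-acid attribution is instrument-pipeline specific. Saturation
classes follow the standard convention: SFA = 0 double bonds, MUFA = 1,
PUFA ≥ 2; `saturation_summary` also reports mean double bonds per fatty
acid. Raw-intensity tables are quantified by single-point internal-standard
scaling (`amount = intensity / is_intensity × is_amount`) and renormalized,
which makes the result invariant to overall intensity scale. Every
operation preserves the per-class closure (mol% sums to 100 within 1e-6,
enforced on read and on generation).

`gen_lipid_profiles` draws class-wise compositions from a Dirichlet
distribution centred on a realistic baseline (18:1- and C20-PUFA-dominated,
with a larger saturated share among PEs), with the SFA share shifted
additively per condition before sampling. The default concentration
(dispersion 200) gives per-sample SFA standard deviations of ~3 mol%,
consistent with biological replicate scatter in whole-worm lipidomics; at
n = 20 per group an injected +10 mol% SFA shift is recovered within ±2 with
p < 0.01. The generator does not emulate correlated bin noise or
class-total shifts.

## Assay statistics

- `proportion_ci` is the normal-approximation (Wald) interval
  $\hat p \pm z\sqrt{\hat p(1-\hat p)/n}$, clipped to [0, 1] — chosen
  because these assays report "Z-test" intervals; a Wilson interval is
  available behind `method = "wilson"` but is not the default. The Wald
  interval's true coverage at p = 0.5, n = 100 is 0.943, and the degenerate
  k = 0 interval is [0, 0]; users needing small-n guarantees should opt into
  Wilson.
- `welch_t` is the unequal-variance t-test with Satterthwaite degrees of
  freedom — a robust default for the 20–25-worm groups these assays use. It
  is hand-rolled only to support degenerate-data conventions (both samples
  constant and equal → p = 1) and is verified against `stats::t.test`
  exhaustively in the tests.
- `annotate_codon_change` translates codon pairs through the standard
  genetic code and classifies missense/nonsense/silent/readthrough changes,
  reproducing compact labels such as `D282N` and `W83STOP`;
  `annotate_allele_table` applies it to the packaged five-allele table.

## Numerical conventions and degenerate inputs

- Bleach-frame ties break to the earliest frame; a minimum within the first
  five frames is an error (no baseline window).
- Zero dynamic range (pre-bleach mean equal to the minimum) is an error in
  normalization; a flat-zero recovery yields mobile fraction 0 with `NA`
  half-time and a flag, not an error.
- The exponential cross-check fit uses Levenberg–Marquardt with bounds
  (M ≥ 0, τ > 0), started from the model-free estimates; non-convergence and
  unidentifiable τ (M below 10⁻³) are flagged results, never exceptions.
- Inference ties are ordered by cost, then by number of events; all minimal
  ties are reported.
- Generators restore the caller's RNG state, so seeded calls are
  reproducible without side effects.

## Problem sizes used by the test and acceptance suites

The suites run entirely on packaged tables, closed forms, and seeded
simulations: 100 single-trace FRAP replicates at 2% noise for the recovery
medians, 20–25 randomized traces for the invariance properties, 25–30
simulated mosaic worms (plus exhaustive antichain enumeration, ~6,000
hypotheses per worm at 4 events over 20 candidates), 10,000 binomial draws
for Wald coverage, 5,000 replicates for Welch type-I error, and 20 samples
per group for the lipid shift. These sizes give Monte-Carlo standard errors
well inside the asserted tolerances.

## Known limitations

- The FRAP estimators are the study's model-free summaries; they are biased
  low for the mobile fraction when acquisition ends before the plateau
  (quantified above) and do not separate diffusion from binding. The
  first-crossing half-time is also biased low on noisy single traces (a
  first-passage effect — noise crosses the half line before the mean curve
  does), increasingly so for slow recoveries; group contrasts remain
  decisive at the tested noise levels, and the exponential cross-check fit
  is available where an unbiased per-trace time constant matters.
- Mosaic inference is parsimony, not likelihood: it neither estimates a
  per-division loss rate nor propagates uncertainty; events below the
  identifiability threshold are silently absorbed as scoring noise.
- Lipid contrasts test one summary (SFA share) per class; no
  multiple-testing correction is applied, matching the source assays.
- The recorded scoring table contains internal inconsistencies (it was
  scored by eye); concordance with it is reported, not enforced.
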