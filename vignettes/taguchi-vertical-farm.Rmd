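---
title: "Taguchi orthogonal-array analysis of vertical-farm growth experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taguchi orthogonal-array analysis of vertical-farm growth experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taguchiCEA)
```

## The problem and the method

Controlled-environment agriculture lets a grower set six or more
environmental factors at once — CO2 concentration, light recipe,
nutrient-solution electrical conductivity (EC), day and night temperature,
relative humidity — and each interacts with crop physiology. A full
factorial over six three-level factors needs 3^6 = 729 treatments; the
Taguchi approach screens all six with 27, using the L27(3^13)
orthogonal array. This package implements that workflow end to end for the
packaged 27-run lettuce and basil study and for user-supplied or simulated
response tables:

1. construct and validate the L27 design (`l27Design`,
   `orthogonalityReport`);
2. transform each response to a signal-to-noise (S/N) ratio
   (`snRatio`, `snValues`);
3. average S/N per factor level, rank factors by delta (`mainEffects`);
4. pick the best level per factor and predict the optimum's S/N and
   response with the additive model (`bestLevels`, `predictSN`,
   `predictResponse`);
5. compare against a confirmation run (`confirmationError`);
6. screen factor pairs for interactions via cell-mean non-parallelism
   (`interactionSummary`).

The central container is `TaguchiExperiment`, a `SummarizedExperiment`
with measured parameters as rows, the 27 runs as columns and the coded
design in `colData`.

## The L27 array and its aliasing structure

Runs are indexed by the base-3 expansion of 0..26, giving three digits
(a, b, c). Each array column is a fixed nonzero linear combination of the
digits over GF(3), one per projective line, which guarantees strength-2
balance: every level appears 9 times per column and every ordered level
pair 3 times per column pair. The six study factors map to the
combinations a, b, a+b, 2a+b, c, a+c — exactly the published trial matrix.

Because 6 columns are drawn from a 3-dimensional space, columns are
mutually aliased: the EC column is the GF(3) sum of the CO2 and LED
columns, night temperature plus CO2 spans humidity, and so on. Two
consequences matter for interpretation:

- a genuine CO2 x LED interaction is indistinguishable from an EC main
  effect (and vice versa) on this design;
- in the interaction screen, a strong main effect on a column aliased
  with a factor pair inflates that pair's non-parallelism score even when
  the generating model is purely additive.

The only additive model whose 15 pair scores are all exactly zero on this
design is the effect-free one; the package's tests assert both that fact
and the closed-form contamination (a pure EC offset vector e produces a
CO2 x LED score of max|20 e| dB). This is a property of every saturated
orthogonal array, not of the implementation; conclusions about specific
interactions from such designs are necessarily qualitative. The screen is
therefore descriptive — no F-test is attempted, which would anyway be
impossible without replicate-level data.

## S/N ratios at n = 1

The study publishes one value per treatment (the mean of three
replicates), so all S/N math runs at n = 1, where larger-is-better
reduces to 20·log10(y). Consequences, verified by tests:

- the level maximizing mean S/N equals the level maximizing the mean of
  log responses — ranking is a monotone transform of the data;
- the back-transform y = 10^(dB/20) inverts the S/N exactly (round-trip
  tolerance 1e-12 in the tests);
- smaller-is-better and nominal-is-best are implemented for completeness
  (`snRatio`), but nominal-is-best needs replicate values and is rejected
  for single-value tables rather than silently misapplied.

Level means average 9 runs each; on a balanced array the unweighted mean
of the three level means equals the grand mean (asserted to 1e-9 dB).
Delta ranking uses the S/N scale; raw-response level means are carried in
the `MainEffectsTable` for diagnostics but never ranked. Delta ties are
broken by design-column order and flagged; argmax comparisons use exact
dB values with no pre-rounding.

## Optimum prediction and confirmation error

The additive prediction is the grand mean plus each chosen level's
deviation: eta-hat = eta-bar + sum_f (m_f,l - eta-bar). It is exact when
effects are multiplicative (additive in log space), the regime the
synthetic generator produces; on noise-free simulated data the prediction
reproduces the generating model to 1e-9 (tested against direct evaluation
of the generator).

Confirmation error is 100·|expected − predicted|/expected, using the
absolute difference: the published error columns are positive even where
the prediction exceeds the confirmation measurement (e.g. basil
potassium). Inputs are used at full precision; only reports round to two
decimals. The packaged confirmation table (`confirmationData`) recomputes
the error from each row's printed expected/predicted pair and flags rows
as self-consistent only when the recomputation matches the printed error
to ±0.01 — rounding of the printed inputs breaks a few rows (basil dry
leaves, basil calcium), and those are treated as transcription artifacts,
not targets. The published per-parameter S/N and predicted-value columns
cannot be reproduced from published data at all (the printed S/N and
predicted value are mutually inconsistent under any n = 1 back-transform),
so the package does not attempt them; the reproduction surface is the
optimal-level prose plus the self-consistent error rows.

## Interaction threshold

The screen's `interacting` flag needs a cutoff the source describes only
as lines "almost parallel". The default threshold is 10% of the larger of
the two factors' deltas — scale-aware, so a pair only flags when its
non-additive residual is material relative to the main effects it would
modify. The fraction is exposed (`thresholdFrac`), and a fixed dB
threshold can be supplied instead. On the packaged growth tables the
EC x humidity pair ranks in the bottom third of the 15 scores for fresh
leaf mass in both species, consistent with the study's finding of no
EC-humidity synergy.

## Chlorophyll equations

`chlA`, `chlB`, `chlTotal` implement the study's printed equations
verbatim, reading the printed "× V/1000 × W" as V/(1000·W) — the only
dimensionally sensible form for mg per g fresh weight. Two caveats are
exposed rather than silently corrected: the printed coefficients
(12.25/25.51) differ from the commonly cited spectrophotometric values,
and the printed total is chl_b − chl_a, almost certainly a typographical
variant of the sum. `chlTotal` therefore offers `mode = "as_printed"`
(default, matching the source) and `mode = "sum"`; negative
concentrations are flagged, not clamped. Defaults V = 5 mL, W = 0.1 g
match the study's extraction protocol.

## The synthetic generator

`simulateResponses` draws y_r = baseline · 10^(Σ main offsets +
Σ interaction offsets + ε), ε ~ N(0, σ²) on the log10 scale. Effects are
multiplicative so that the n = 1 larger-is-better S/N is exactly additive
— the regime in which the Taguchi prediction is provably correct, which
turns "the method works when its assumptions hold" into a testable
statement. Log-normal noise keeps responses positive and acts additively
on the dB scale. Identifiability: main-effect offsets sum to zero per
factor, interaction tables are doubly centered; both are enforced.

Defaults emulate the packaged study's conditions: baseline 25 (a typical
lettuce fresh-leaf mass in grams), σ = 0.05 on log10 (≈12% multiplicative
scatter, comparable to the run-to-run spread of the study's growth
columns), and the L27 design in the printed run order (the study models
no run-order randomization). Every stochastic entry point takes an
explicit seed; `recoveryExperiment` derives per-replicate seeds from a
master seed and records them.

What the generator does not emulate: replicate-level variance (the study
publishes only treatment means), heteroscedastic or non-log-normal noise,
and any mechanistic plant physiology. Passing recovery tests therefore
show the pipeline is correct under its own assumptions, not that those
assumptions hold for any particular crop dataset.

## Problem sizes used by the test suite

Monte-Carlo checks run at sizes chosen to give stable verdicts in seconds:
optimal-level recovery uses 500 replicates at σ = 0.05 with offsets
(−0.1, 0, +0.1) — the recovered fraction is ≥ 0.95 by a wide margin
(the level-mean contrast is ≈2 dB against a ≈0.47 dB standard error) —
and the null-uniformity chi-square uses 900 replicates of an effect-free
factor. All fixture-based results are deterministic.

## Known limitations

- Per-parameter factor ranks beyond the prose statements are not
  validated: the published rank tables are typeset as images.
- The interaction flag is descriptive; on a saturated array it cannot
  separate a pair interaction from aliased main effects.
- No percent-contribution (ANOVA) decomposition: without replicate-level
  data there is no error term to test against.
- Units are metadata only; no conversions are performed.
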