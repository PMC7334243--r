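---
title: "Karyotype morphometrics, asymmetry indices, and marker statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype morphometrics, asymmetry indices, and marker statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyostat)
```

## The measurement model

The unit of raw data is one homolog of one chromosome pair in one metaphase
cell: a short-arm length, a long-arm length, and optionally a satellite
length, all in micrometres. A diploid complement measured over `k` cells
therefore contributes `2k` rows per pair. Chromosome identity (`pair_id`)
is required input: homologs are *not* paired automatically by length,
because silent mis-pairing of similar-sized chromosomes would corrupt arm
ratios invisibly. (Karyotyped measurement tables always carry this
identity; an automatic suggestion would have to be reviewed anyway.)

Arms are oriented on read so that the short arm is the shorter of the two.
Satellites are included in the length of their carrying arm for every
length-derived statistic (arm ratio, centromeric index, relative and total
lengths) and flagged separately for the karyotype formula and the idiogram.
This is a convention, not a fact about the data — whether published
complement lengths include satellites is rarely stated — so it is exposed
as the `satellite_in_length` switch of `karyo_config()`; the default
(include) keeps a satellited complement's total length consistent with its
per-pair sum.

## Per-pair and complement statistics

Per pair, `b` and `B` are grand means over homologs and cells; `AR = B/b`;
`CI = 100·b/(b+B)`. Relative length is computed *per cell* — each pair's
mean homolog length as a percent of that cell's haploid total — and then
averaged over cells. Computing RL per cell first makes it exactly invariant
to the cell-level condensation factor, which is the dominant nuisance
variable in metaphase measurements. Pairs are renumbered in decreasing RL
(ties broken by the input id), the universal presentation order.

Karyotype length (TCL) is the mean over cells of the per-cell haploid
totals; its `±` is the standard error over cells. `C = TCL / n` is the mean
chromosome length. With a single cell the SE is degenerate and reported as
0 with a warning.

The asymmetry suite, over the `n` per-pair values:

* `A1 = 1 − (Σ b_i/B_i)/n` (intrachromosomal), in `[0, 1)`, 0 iff every
  pair is perfectly metacentric;
* `A2 = sd(L_i)/mean(L_i)` (interchromosomal), the coefficient of
  variation of chromosome length;
* `AsK% = 100·Σ B_i / Σ (b_i + B_i)`, the long-arm share of the complement,
  50 at perfect symmetry. It satisfies the algebraic identity
  `AsK% + length-weighted mean CI = 100`, which the test suite asserts on
  random karyotypes;
* `CV_CL = 100·A2`, `CV_CI = 100·sd(CI)/mean(CI)`, and Paszko's
  `AI = CV_CL·CV_CI/100`.

All dispersion statistics use the sample (n−1) SD. The `±` printed after a
complement's mean centromeric index in comparative tables is read here as
the *SD of the per-pair CI values* (not an SE): under that reading, and
only under it, `AI` recomputed from a published summary row (A2, mean CI,
CI dispersion) reproduces published AI values to two decimals — the
`reference_karyotypes()` rows for *V. vexillata* (1.52) and *V. caracalla*
(1.41) check this exactly, while the other three species differ by at most
0.03, which is entirely accounted for by two-decimal rounding of the
published A2 before the product is formed.

Levan classes use the conventional break points 1.70 (m|sm), 3.00 (sm|st)
and 7.00 (st|t), half-open on the left so a two-decimal AR sitting exactly
on a break classifies deterministically into the lower class; `M` is
reserved for AR exactly 1 and is merged into `m` when the karyotype
formula is rendered. The Stebbins category combines the proportion of
chromosomes with AR strictly above 2.0 (digit 1–4) with the
largest/smallest chromosome ratio (letter: A below 2, B from 2 to 4, C
above 4). Whether that ratio uses absolute or relative lengths is
immaterial — they are proportional within a complement — so relative
lengths are used.

## Marker statistics

Band and rDNA-site positions are fractions of their arm's length, origin 0
at the centromere, increasing to 1 at the telomere; both arms span 0–1
independently. This makes every positional statistic invariant under
uniform scaling and lets one marker table serve all cells.

The percent distance `di = 100·d/a` takes `d` to the *starting point* of a
terminal site but to the *center* of a non-terminal one — terminal rDNA
clusters are conventionally quantified by where they begin, interior ones
by their midpoint. A site is terminal when its distal end reaches
`end_frac ≥ 0.98`; the 2% tolerance absorbs measurement noise at the
telomere. Non-terminal sites with `di ≤ 28` are pericentromeric, the rest
interstitial; sites spanning the centromere are `CEN` and have no `di`.
The 28% cutoff is a numeric reconstruction of what is, in practice, a
visual call: published assignments place pericentromeric sites up to
di ≈ 25 and interstitial ones from di ≈ 31, so any threshold between
works; it is exposed as `pcen_max_di` in `karyo_config()`.

Band amounts are haploid accounting: one homolog per pair, physical size
`(end_frac − start_frac)·arm length`, expressed as percent of TCL.
Heterochromatin at rDNA sites stains like a band, so the headline CPD
total excludes bands of which at least half is covered by a 5S or 45S site
on the same arm (the total including them is reported alongside). The
half-coverage rule keeps a pericentromeric band that merely brushes an
rDNA site counted while dropping bands coextensive with one.

## Idiograms

`build_idiogram()` produces pure geometry — glyph heights equal RL, the
centromeric constriction sits at the CI fraction, satellites are split off
by a secondary-constriction gap that is *visual only* (it does not alter
heights), marker rectangles carry their fractional extents verbatim — and
`render_svg()` serializes it with fixed-precision coordinates, so the same
input yields byte-identical SVG. The default palette is red CPD, blue
DAPI, orange 5S, green 45S; all styling lives in `idiogram_style()`.

## The synthetic generator

`generate_dataset()` emulates the standard study design: five metaphase
plates per species, 11 pairs, two homologs each. Per cell, a lognormal
condensation factor (5% CV by default) scales every chromosome; per
homolog arm, independent multiplicative lognormal noise with CV
`noise_cv` (default 5%) perturbs the target length. Lognormal noise is the
minimal model matching the two structural facts about such measurements —
lengths are positive, and within-cell lengths are correlated through
condensation; both factors have unit mean so targets are unbiased. Marker
layouts are fractional and are emitted unchanged.

The five built-in templates encode what is published about their species:
the karyotype formula, the relative-length extremes, the satellite (on the
short arm of *V. caracalla* pair 1, distal to a 45S cluster filling the
rest of the arm), and the full rDNA/band layout with published `di`
values. Everything else is unpublished and had to be chosen once:

* interior relative lengths interpolate geometrically between the printed
  extremes on a power-warped index, with the warp exponent solved so the
  profile sums to exactly 100 while the endpoints stay exact
  (`rl_profile_between()`); the interior is therefore non-authoritative;
* per-pair arm ratios are smooth ramps inside the metacentric interval
  (submetacentric pairs set near 1.9), chosen to match each species' mean
  centromeric index and its all-ARs-below-2 Stebbins digit; which pairs
  are submetacentric is itself unpublished and was fixed arbitrarily;
* band extents (pericentromeric widths, interstitial blocks) approximate
  the published band amounts as percent of karyotype length.

Consequently the templates pin down formulae, RL extremes, locus layouts
and position classes — and the noiseless datasets recover all of these
exactly — but **not** A1/A2/AI or band totals, which depend on the
unpublished per-pair values; tests treat those only through invariants and
oracle equivalence, never as template fidelity.

What the generator does *not* emulate: homolog heteromorphism, chromosome
bending and measurement bias of an image-based workflow, signal-intensity
variation, or between-plant variation. Passing recovery tests therefore
demonstrates the correctness of the calculations under the stated noise
model, not robustness to every artifact of real spreads.

## Problem sizes and numerical choices

The test suite runs 1000-karyotype oracle-equivalence sweeps (2–12 pairs),
200-seed stochastic-recovery runs at 5% noise (recovery of the template
karyotype formula is required in ≥ 95% of seeds and the recovered mean CI
within 2 percentage points), and noiseless exact-recovery checks at
tolerance 1e−9; these sizes give stable Monte-Carlo estimates in seconds.
Orientation at AR near 1 under noise slightly inflates recovered ARs (the
per-record max/min of two noisy arms exceeds the true ratio on average);
at 5% noise the effect on mean CI is a fraction of a percentage point and
is absorbed by the 2-point band. Report tables round to 2 decimals;
`report.json` stores full precision and round-trips.

## Limitations

* The package starts from measurement tables; image processing and
  chromosome segmentation are out of scope.
* Homologs must be pre-identified; no automatic karyotyping.
* Band amounts assume bands and arms are linear intervals; no
  signal-intensity weighting.
* The PCEN/INT threshold and the TER tolerance are calibrated conventions,
  not biological constants; both are configurable and echoed into every
  report for provenance.
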