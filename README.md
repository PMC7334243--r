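# karyostat

Comparative karyotype analysis for plant molecular cytogenetics.

Small, poorly differentiated chromosomes — such as those of *Vigna* and
other Phaseoloid legumes (2n = 2x = 22) — are routinely characterized by
measuring arm lengths on a handful of metaphase plates and layering
fluorochrome bands (CPD, DAPI⁺) and 5S/45S rDNA FISH signals on top.
`karyostat` takes those two tables — per-cell, per-homolog arm measurements
and fractional band/site extents — and computes the complete comparative
karyotype report:

* **Per-pair morphometrics.** Mean short- and long-arm lengths `b`, `B`; arm
  ratio `AR = B/b`; centromeric index `CI = 100·b/(b+B)`; relative length
  `RL` (percent of the haploid complement, computed per cell and averaged so
  condensation differences cancel); Levan morphology classes
  (`M`/`m`/`sm`/`st`/`t`); pairs renumbered in decreasing RL.
* **Complement statistics.** Karyotype formula (e.g. `10m (1SAT) + 1sm`),
  karyotype length `TCL ± SE` over cells, mean chromosome length
  `C = TCL/n`, RL range, and the asymmetry suite:
  mean `CI ± SD`, Romero Zarco's `A1 = 1 − mean(b_i/B_i)` and
  `A2 = sd(L_i)/mean(L_i)`, Arano's `AsK% = 100·ΣB_i/ΣL_i`, Paszko's
  `AI = CV_CL · CV_CI / 100`, and the Stebbins category (digit from the
  proportion of AR > 2, letter from the largest/smallest length ratio).
* **Marker statistics.** The `di = 100·d/a` percent distance from the
  centromere (start point for terminal sites, center otherwise),
  CEN/PCEN/INT/TER position classes, band amounts as percent of karyotype
  length with rDNA-CPD bands separated out, rDNA locus counts, synteny and
  band–site colocalization.
* **Idiograms.** RL-scaled SVG idiograms, short arm up, with centromeric
  constriction at the CI height, satellites split off by a secondary
  constriction, and one colored track per marker type. Output is
  byte-deterministic, so figures are diffable.
* **Synthetic karyotypes.** A generator (`species_template()`,
  `generate_dataset()`) that emulates measuring five metaphase plates of a
  diploid complement with lognormal homolog-arm noise and a cell-level
  condensation factor, plus `builtin_templates()` for five wild *Vigna*
  species (*V. luteola*, *V. vexillata*, *V. minima*, *V. trilobata*,
  *V. caracalla*) parameterized from their published karyotype tables.

## Worked example

A synthetic *V. luteola*-like dataset (5 cells × 11 pairs × 2 homologs, 5%
measurement noise) ships with the package:

```r
library(karyostat)

meas <- system.file("extdata", "synthetic_luteola_measurements.tsv",
                    package = "karyostat")
mark <- system.file("extdata", "synthetic_luteola_markers.tsv",
                    package = "karyostat")
rep <- analyze_karyotype(meas, mark, species = "V. luteola (synthetic)")
rep
#> <karyo_summary> V. luteola (synthetic) (2n = 22)
#>   KF:        11m
#>   TCL:       33.73 +/- 0.71 um;  C: 3.07 um
#>   RRL:       6.95 - 12.35
#>   CI:        44.10 +/- 2.42
#>   A1: 0.21  A2: 0.19  AsK%: 55.50  AI: 1.05
#>   Stebbins:  1A
#>   rDNA loci: 1x 5S, 1x 45S
#>   Band amounts (% TCL, non-rDNA): CPD 29.51, DAPI 0.00
```

The karyotype is recovered as 11 metacentric pairs (`11m`), Stebbins class
1A (no arm ratio above 2, largest/smallest RL ratio below 2), with a single
pericentromeric 5S locus on the shortest pair and a single 45S locus
occupying the short arm of pair 3 — the layout the template encodes.
`write_report(rep, "out/")` emits `report.json`, table-style TSVs and
`idiogram.svg`.

Complement summaries can be compared across species; with the published
reference parameters:

```r
cmp <- compare_karyotypes(reference_karyotypes())
round(tcl_ratio(cmp, "V. caracalla", "V. vexillata"), 2)
#> [1] 1.82
```

i.e. the *V. caracalla* karyotype is 1.82 times longer than that of
*V. vexillata*.

A thin command-line front end wrapping the same functions is in
`inst/cli/karyostat.R` (`generate`, `analyze`, `compare` subcommands).

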