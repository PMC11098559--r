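# myostates

Resting myosin in permeabilized skeletal muscle fibers occupies two
metabolic states: the **disordered-relaxed state (DRX)**, where heads sit
free in the interfilamentous space and hydrolyse ATP comparatively fast,
and the **super-relaxed state (SRX)**, where heads fold against the
thick-filament backbone and turn over ATP 5–10× more slowly. The balance
between the two states, and their turnover lifetimes, set the resting
energy consumption of muscle — a quantity of direct interest in hibernation
physiology, muscle disease and thermogenesis research.

`myostates` implements the complete desk-side analysis for loaded Mant-ATP
chase experiments on single fibers, for researchers who record fluorescence
decays (optionally as image stacks with ROIs), small-angle X-ray
diffraction profiles of muscle bundles, and proteomics abundance matrices
from the same animals. Because raw per-fiber recordings are rarely
deposited, the package also ships a first-class synthetic-data module that
generates every input the pipeline consumes, with the hierarchical
animal/fiber structure the statistics assume — so the whole analysis is
testable end to end.

## The model

A Mant-ATP chase decay, normalized to the final pre-washout frame, is fit
to an unconstrained double exponential

```
F(t) = 1 − P1·(1 − exp(−t/T1)) − P2·(1 − exp(−t/T2))
```

where `P1`/`T1` are the amplitude (%) and ATP turnover lifetime (s) of the
fast DRX component, `P2`/`T2` those of the slow SRX component, and
`1 − P1 − P2` a non-exchanging plateau. Fitted parameters feed the
per-fiber myosin ATP consumption (µM·min⁻¹), assuming 220 µM myosin heads
in the fiber:

```
ATP = (P1/100)·220·(60/T1) + (P2/100)·220·(60/T2)
```

Group statistics are run on **animal means** (one value per animal per
condition × fiber type × temperature), with classical one-way ANOVA,
two-way ANOVA with Šídák-corrected follow-ups, and signed percent
differences against a named baseline condition. Temperature sensitivity is
summarised per matched animal as the 20 °C / 8 °C ratio of T1, T2 and ATP
consumption.

X-ray profiles are handled in detector space: reflections (equatorial 1,0
and 1,1; meridional M3 ≈ 14.3 nm and M6 ≈ 7.2 nm) are fit as Gaussians on a
local baseline after smooth background subtraction, with centers converted
to d-spacings through the exact Bragg relation (`θ = ½·atan(r/L)`,
`d = λ/(2·sin θ)`). Proteomics matrices go through log2 transform,
valid-value filtering, MinProb-style left-censored imputation
(mean − 1.8·SD, width 0.3·SD per sample), per-feature t-tests with
Benjamini–Hochberg FDR, PTM-site z-scores and sample PCA.

## Worked example

Simulate a two-condition study (5 animals per condition, 8–12 fibers per
animal) in which torpor shortens the type II DRX lifetime to 65% of the
summer-active value, then run the full analysis:

```r
library(myostates)
library(dplyr)

eff <- condition_effects(condition_mult = tibble::tibble(
  condition = "torpor", fiber_type = "II",
  t1_mult = 0.65, t2_mult = 1, p1_shift = 0))
des <- study_design(conditions = c("SA", "torpor"),
                    animals_per_condition = 5,
                    fibers_per_animal = c(8, 12), seed = 42)

sim  <- simulate_study(des, eff)
fits <- fit_decay_all(sim$traces)
rec  <- fiber_records(qc_filter(fits)$accepted)
s2   <- aggregate_by_animal(rec) |> filter(fiber_type == "II")

s2 |> group_by(condition) |>
  summarise(mean_t1 = mean(mean_t1_s), mean_atp = mean(mean_atp_consumption))
#> # A tibble: 2 × 3
#>   condition mean_t1 mean_atp
#>   <chr>       <dbl>    <dbl>
#> 1 SA          15.5      247.
#> 2 torpor       9.63     394.

ms <- tapply(s2$mean_t1_s, s2$condition, mean)
percent_difference(ms[["SA"]], ms[["torpor"]])
#> [1] -37.70152

one_way_anova(s2, "mean_t1_s", "condition")
#> # A tibble: 1 × 6
#>   test          statistic   df1   df2  p_value stars
#> 1 one-way ANOVA      26.9     1     8 0.000839 ***
```

The shortened DRX lifetime is recovered as a ~38% reduction (truth: −35%
plus between-animal sampling noise), and because the lifetime appears in
the denominator of the turnover term, resting ATP consumption in torpor
*rises* (394 vs 247 µM·min⁻¹). A single fiber's fit prints as:

```r
fit_decay(normalize_trace(simulate_decay(decay_truth(0.25, 15, 0.5, 200), seed = 1)))
#> <decay_fit> DRX P1 = 23.3%, T1 = 15 s | SRX P2 = 48.8%, T2 = 178 s
#>   rss = 0.00467 over 61 frames; converged: TRUE
```

`tidy()`, `glance()` and `autoplot()` work on fit objects;
`run_study_pipeline(run_config(...), out_dir)` executes the whole
simulate → fit → energetics → report chain to CSV/JSON with a hash
manifest.

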