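---
title: "Analysing growth-duration contrasts in maize hybrid trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing growth-duration contrasts in maize hybrid trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizetrial)
```

## The scientific question

Summer maize hybrids differ in growth duration: an early-maturity hybrid
reaches silking (R1) and physiological maturity (R6) sooner than a mid-late
hybrid grown alongside it. Why, then, do mid-late hybrids usually yield
more, and where in the crop's carbon economy does the difference arise? The
standard agronomic dissection — which this package implements as a reusable,
tested pipeline — combines four layers:

1. **Thermal time.** Growth stages are compared on the growing-degree-day
   (GDD) scale rather than calendar days, because development tracks
   temperature. Yield divided by accumulated GDD is a temperature
   resource-use efficiency.
2. **Canopy dynamics.** The post-silking rise and senescent decline of leaf
   area index (LAI) and of ear-leaf net photosynthesis (Pn) is summarized by
   two fitted durations: DLAI (days for LAI to fall from its maximum to
   half-maximum) and APD (days for Pn to fall from its initial post-silking
   value to half of it).
3. **Dry-matter partitioning.** Organ dry masses at R1 and R6 give
   pre-/post-silking accumulation, remobilization of leaf and stalk
   reserves, and harvest index. A ¹³CO₂ pulse label applied at silking
   corrects the remobilization-to-grain bookkeeping: only the fraction of
   tracer recovered in grain counts as grain-bound remobilization.
4. **Trial statistics.** Balanced two-way ANOVA (Year, Hybrid, Year×Hybrid),
   LSD mean-separation letters within years, and Pearson
   correlation/regression reproduce the comparative tables of field-trial
   reports.

## Models and assumptions

### Thermal time

Daily GDD is `max(0, (Tmax + Tmin)/2 − Tbase)` with `Tbase = 10` °C, the
conventional maize base temperature. Negative daily values are clipped to
zero — standard agronomic practice, and irrelevant for summer data where
daily means sit far above 10 °C. No upper temperature cap is applied.
Windows are accumulated start-exclusive and end-inclusive, so an interval
split at any interior date is exactly additive. Day counts use the same
convention (R1 − sowing, R6 − R1), which makes *before + after = total* an
identity. Published stage tables do not always follow one convention
consistently; this package picks the additive one and does not attempt to
reproduce internally inconsistent printed day counts.

The "yield per GDD" efficiency takes its denominator explicitly. Report
tables compute it twice — against post-silking GDD and against total GDD —
because both accountings are used in the literature and printed values are
not always attributable to either; users should state which one they quote.

### Canopy dynamics

Post-silking LAI follows the Gaussian model
\[ LAI(t) = A \exp\!\left(-\frac{(t-B)^2}{2C^2}\right) \]
on the days-after-silking axis: `A` is the maximum LAI, `B` the day it
occurs (typically 3–8 d after silking), `C` the curve width in days. The
duration of higher LAI is the closed form
\[ DLAI = C\sqrt{2\ln 2} \approx 1.1774\,C , \]
the time for the curve to fall from `A` to `A/2`. Fitting initializes
`(A, B, C)` from a quadratic regression on `log(LAI)` — which is the exact
solution for noiseless strictly positive data — and refines by nonlinear
least squares (`nls`, port algorithm, ≤ 200 iterations, tolerance 1e-10).
If the refinement step fails on degenerate input, the log-quadratic
solution is used when it already interpolates the data; otherwise the last
iterate is reported in the error. `R` is the determination coefficient
`1 − SSres/SStot`.

Ear-leaf Pn after full expansion declines linearly: OLS of Pn on days after
silking, reported as `y = a − b x` with `b > 0`. The initial net
photosynthetic rate `Pi` is the *observed* Pn at the earliest post-silking
time point, not the fitted intercept, and the active photosynthesis
duration is `APD = Pi/(2b)`. This closed form reproduces published APD
values within printed-coefficient rounding for most year×hybrid
combinations; residual deviations of up to ~2 d in some years trace to the
published tables' own rounding and cannot be resolved from printed
precision, so no adjustment is attempted.

### Partitioning and the ¹³C correction

With total aboveground dry matter `DMA(R1)` and `DMA(R6)` per plant:
`PrSDMAR = 100·DMA(R1)/DMA(R6)`, `PoSDMA = DMA(R6) − DMA(R1)`,
`PoSDMAR = 100 − PrSDMAR`. Organ remobilization is
`DMR = mass(R1) − mass(R6)` and `DMRE = 100·DMR/mass(R1)` for leaf and
stalk. Negative DMR (an organ that gained mass) is retained and flagged,
but floored at zero inside the grain-bound step, since mass flow to grain
cannot be negative.

The tracer bookkeeping uses organ dry mass × atom-% excess
(labeled-cohort mean minus reference-cohort mean) as the tracer-mass proxy,
assuming a constant carbon fraction across organs — the published protocol
gives no isotope formula, so this is the package's stated convention.
Negative excesses are floored at zero before normalizing to organ
fractions. Then
`DMR to grain = (max(DMR_leaf,0) + max(DMR_stalk,0)) × f_grain` and
`DMRC = 100·(DMR to grain)/grain DMA(R6)`; the complement `100 − DMRC` is
the contribution of post-silking assimilation. The year×hybrid mean tracer
fraction is applied to replicate-level DMR (replicate-level isotope
pairing is not available in this design). Harvest index is
`grain DMA/total DMA` at R6; sink capacity is
`ears m⁻² × grains per ear × single-kernel weight`; grain/leaf divides sink
capacity by leaf area at R1 (in kg m⁻²). "Other" organs (bract + cob) are
always a separate pool, never merged into stalk.

### Statistics

The two-way ANOVA is the balanced fixed-effects decomposition (year fixed,
as in printed trial tables; no mixed model). Unbalanced designs are an
error, matching the balanced published design, and a zero error SS
(noise-free data) is flagged rather than producing infinite F. LSD at level
α is `t(1−α/2, df_err)·sqrt(2·MSE/n)` with the error pooled within year
(treatments = hybrids), matching "in the same year" table comparisons.
Letters are assigned by the usual greedy descending-means sweep with
absorption of nested groups; published tables never state their algorithm,
and for the two-treatment case all algorithms coincide. Percent and paired
difference ranges round half-up to 1 decimal only in the reported min/max
(parity with printed ranges); full precision is kept internally. Per-year
yield regressions use replicate-level points (n = 3), consistent with the
degrees of freedom implied by printed significance stars.

## The synthetic stated world

`generate_trial()` emulates a 5-year × 2-hybrid × 3-replicate completely
randomized trial at 75,000 plants ha⁻¹. Defaults are centred on the
published ranges: Gaussian LAI truth A ≈ 4.5–5.1, B ≈ 5–6, C ≈ 42–50; Pn
decline a ≈ 47–48.3, b ≈ 0.43–0.54; organ masses giving PrSDMAR ≈ 40%,
HI ≈ 0.55–0.58, stalk DMRE ≈ 21–25%, leaf DMRE ≈ 5–15%; tracer fractions
ordered grain > other > stalk > leaf with grain ≈ 0.6; yield components
near 6.9×10⁴ ears ha⁻¹, 510–530 grains, 340–350 g TGW. Published "±"
values are read as SE of n = 3, so plot noise is drawn with sd = SE·√3.
Weather is an annual sinusoid (annual mean 20 °C, amplitude 9 °C, peak at
day-of-year 205 — giving ~26 °C mid-June means and ~16 °C d of daily GDD)
plus AR(1) noise; phenology dates are solved by accumulating GDD to each
hybrid's thresholds, with R3 placed 15 d and R5 45 d after silking. Two
constants the protocol does not state were fixed once: the reference
baseline of 1.08 atom-% ¹³C (natural abundance) and a total labeled excess
of 0.35 g tracer-mass proxy per plant; both cancel from the recovered
fractions.

What the generator does *not* emulate: weather-driven variation in organ
masses and yield (year effects beyond thermal time are pure noise),
within-plot sampling structure, spatial field trends, lodging or disease,
and any soil/water/nitrogen process. A green recovery test therefore
establishes that the pipeline's estimators are consistent and unbiased in
this stated world — not that the generator reproduces any particular
year's field data.

At `noise = 0` the full pipeline is the identity on the generator's
analytic ground truth (verified to 1e-6 in the acceptance suite); with
default noise, DLAI and HI are recovered with < 2% bias over 100 seeds.

## Numerical choices and degenerate inputs

* Gaussian fits require ≥ 4 positive observations spanning the peak;
  all-equal LAI is a fit error. Width `C` is constrained positive; its sign
  is immaterial in the model, so `|C|` is reported.
* Pn fits require ≥ 3 post-silking points with time variance; `APD` is
  undefined (error) for non-declining series.
* Labeling failure (no positive excess in any organ) is an error, not a
  zero.
* `pre_post_silking` warns rather than errors when R1 mass exceeds R6 mass,
  carrying the negative value through for inspection.
* LSD letter grouping uses a 1e-12 absolute slack on the threshold
  comparison so that exact ties (to machine precision) share a letter.
* Dataset validation reports all violations with severities; the reader
  raises only on `error`-severity findings, while unbalanced replicate
  counts are warnings (the ANOVA itself raises where balance is required).

## Open design points, decided

* **Width parameter naming.** Published table notes call `C` the "kurtosis"
  of the Gaussian; it is read here as the width (scale) parameter because
  `DLAI = C·√(2 ln 2)` reproduces the printed DLAI column.
* **`Pi` versus intercept.** `Pi` is the earliest observed post-silking Pn;
  published `Pi` columns exceed the printed intercepts `a`, which rules out
  `Pi = a`.
* **Yield-per-GDD denominator.** Left explicit (see above); printed values
  are not exactly reproducible from printed yields and printed accumulated
  temperatures, so the package refuses to guess a single denominator.
* **"±" dispersion.** Interpreted as SE of the mean of n = 3 plots
  throughout (generator and summaries); published tables do not say.

## Limitations

Pipelines of this kind summarize treatment means; they do not model
grain-filling kinetics (no logistic filling curves), light interception, or
photoperiod effects, and the thermal-time model has no upper cap — fine for
warm-temperate summer maize, not for heat-stressed environments. The ¹³C
correction assumes the silking-time pulse label equilibrates with the
remobilizable pool; systematic label loss (respiration, rhizodeposition)
biases DMRC downward and is not corrected. Statistical comparisons are
fixed-effects and within-trial; they support no inference beyond the
trialed site-years.
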