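---
title: "Skin-temperature variability as a digital biomarker of glycemia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skin-temperature variability as a digital biomarker of glycemia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoglyc)
```

## The analysis

`thermoglyc` processes paired recordings from a continuous glucose monitor
(CGM, one interstitial glucose sample every 5 minutes, mg/dL) and a
wrist-worn skin-temperature sensor (4 Hz, °C), and asks whether the
statistical behavior of skin temperature differs between glycemic states.
The motivation is physiological: hypoglycemia triggers sympathetic
vasoconstriction and sweating that perturb distal skin temperature, and
postprandial hyperglycemia redistributes peripheral blood flow. Skin
temperature is cheap to measure non-invasively, so temperature-derived
features are candidate digital biomarkers for glycemic events.

The pipeline has five stages.

**1. Ingestion and subject screening.** Each subject contributes two
two-column CSVs (timestamp, value). A subject whose percentage of missing
CGM samples exceeds 20% (strictly) is excluded. The expected sample count
is computed from the subject's own first-to-last-timestamp span at the
5-minute cadence (`floor(span/300) + 1`), not from a nominal protocol
length, because monitoring spans differ between subjects. Timestamps are
treated as timezone-naive wall-clock time, which is what the day/night
split needs. Duplicate timestamps keep the first occurrence; empty or
non-numeric value cells are missing samples at their timestamp, never
silently dropped rows.

**2. Window alignment and quality screening.** The temperature stream is
cut into 5-minute windows *backward* from each CGM timestamp `t`, over the
half-open interval `(t - 300 s, t]`; half-open bounds prevent a sample
from being counted in two adjacent windows. A full window holds exactly
N = 5 × 60 × 4 = 1200 samples, and exactly 1200 are required — the metric
denominators assume fixed N, and the 4 Hz stream carries no explicit
missing-value markers, so "missing data" is operationalized as a sample
count below N. Each full window is then screened:

* *artifact*: any sample strictly below 28 °C. This floor suits
  free-living wrist recordings, which reach lower values than
  room-temperature laboratory data;
* *outlier*: otherwise, any sample strictly outside the window-local
  `mean ± 5 SD` band.

Either condition discards the whole window. Equality at a bound retains
the sample (the rules say "lower than" and "outside"); a constant window
(SD = 0) is retained. Verdict precedence is fixed: missing glucose <
missing temperature < artifact < outlier, and the conservation identity
`retained + all discards = number of CGM timestamps` is asserted
throughout. The within-window SD uses the sample (N−1) denominator, the
conventional default, configurable via `sd_denominator`; at N = 1200 the
distinction is negligible but pinning it makes results bit-reproducible.
No imputation is performed anywhere, and the 4 Hz stream is never
resampled.

**3. Metrics.** For each retained window *i* with samples
`st_i1 … st_iN`, the *current-behavior* metrics are the mean, median, SD,
IQR (type-7 linear-interpolation quartiles), coefficient of variation
CV = SD/mean, the mean amplitude deviation

$$\mathrm{MAD}_{Ti} = 1.4826 \cdot \frac{1}{N}\sum_k |st_{ik} - \mathrm{median}_{Ti}|,$$

(1.4826 is the consistency factor for normal data), a J-index adaptation

$$J_{Ti} = 0.001\,(\mathrm{mean}_{Ti} + \mathrm{SD}_{Ti})^2,$$

and two M-value adaptations measuring deviation from a reference
temperature r,

$$M_{Ti} = \frac{1}{N}\sum_k \left|10\log_{10}(st_{ik}/r)\right|^3,$$

with r₁ = 36 °C (maximal skin temperature) for M1 and r₂ = 32 °C (typical
mean) for M2. Printed definitions of this index family are ambiguous
about the placement of the cube; we follow the original
glycemic M-value convention (absolute value of the scaled log, then
cubed). The literal alternative `10·|log10((st/r)^3)| = 30·|log10(st/r)|`
is available via `m_value_form = "literal"` for sensitivity checks; base
10 is used throughout, as in the original index.

The *retrospective* metrics accumulate over retained windows 1..i of the
same subject, in chronological order, spanning the whole recording:
the running mean and the running **population** SD (denominator i, exactly
as defined, not i−1) of the CV series, and `SD_T hhmm`, the population SD
of the window means about the grand mean m of all samples so far. Because
every retained window has identical length, m equals the mean of the
window means — an equivalence the tests assert. Discarded windows
contribute nothing to the history. Whether the accumulators should reset
at day boundaries is a genuinely open choice; we run over the whole
recording by default and expose `reset_daily`.

Numerically, the running statistics use a centered cumulative-sum
recurrence (anchored at the first value) so that streaming results agree
with batch recomputation to better than 1e−9 relative error; the
per-window statistics are computed in a single compiled pass per window
(one sort yields median and both quartiles).

**4. Stratification.** Windows are labeled by the tight glycemic range:
in range (IR) for glucose in [70, 140] mg/dL inclusive, above range (AR)
strictly over 140, below range (BR) strictly under 70 — the strict
inequalities defining AR/BR force the boundaries into IR. The day/night
split is [06:00, 21:00) wall clock for daytime; each boundary instant
belongs to the period it opens. Both cut-offs are configurable
(`tight_range_mg_dl = c(70, 180)` gives the conventional time-in-range
variant, not used by default).

**5. Statistics.** Per subject, each metric is compared between AR and IR
and between BR and IR, separately for daytime and nighttime, with the
two-sided Wilcoxon rank-sum test (exact null distribution for untied
samples with n + m ≤ 25, midrank normal approximation otherwise), then
Benjamini–Hochberg FDR correction across the 12-metric family within each
(subject, contrast, period) cell — the correction scope is configurable
(`fdr_scope = "pooled_periods"` pools day and night). A comparison needs
at least 4 windows per group — the smallest size at which a two-sided
exact rank-sum test can reach p < 0.05 — otherwise the cell is reported
absent (rendered "-"), never fabricated. Lilliefors' test screens metric
distributions for normality; it gates nothing, because the subject-level
analysis is nonparametric by design. Cohort-level generalization uses a
linear mixed-effects model per metric, contrast and period:
`value ~ glycemic_level + (1 | subject)`, fitted by maximum likelihood on
square-root-transformed values (most of these metrics show variance
roughly proportional to the mean), IR as the reference level. The
fixed-effect p-value uses the Satterthwaite approximation; when the
residual degrees of freedom exceed 1500 the Wald normal approximation is
used instead — the two agree to three decimals there, and the Wald path
is an order of magnitude faster. Singular fits are flagged, not hidden.

## The synthetic-data generator

No real deposit ships with the package, so a seeded generator produces
cohorts with the statistical structure the analysis assumes, plus
ground-truth labels for every injected feature. Glucose is a
*label-generating process*, not a metabolic simulation: a subject-level
baseline (100 ± 8 mg/dL, a population at risk of diabetes but without
it), Gaussian meal excursions at breakfast/lunch/dinner plus a late
evening snack (so hyperglycemia occurs in both periods), AR(1) noise, and
flat-top hypoglycemic episodes assigned to a subset of subjects (6 of 15
by default) that pull glucose to a nadir near 60 mg/dL. Temperature is a
two-level circadian profile — 31.5 °C by day, 33.5 °C by night, the
distal-skin rise at sleep — plus AR(1) noise (coefficient 0.97 at 4 Hz,
innovation SD 0.03 °C, i.e. slow dynamics with a marginal SD of about
0.12 °C and a decorrelation time of seconds, so window summaries 5
minutes apart are effectively independent).

Three couplings tie temperature to glycemia: `cv_effect` multiplies the
innovation SD during BR samples (default 3), `level_effect_day_c` shifts
the level during daytime AR (default +0.3 °C), and `retro_effect_c_per_h`
adds a slow drift during contiguous nighttime AR runs (default
0.15 °C/h). Defects are injected into *disjoint* window sets: artifact
windows get a contiguous run forced below 28 °C (and all other windows
are guaranteed not to dip below the floor, so artifact ground truth and
screening verdicts must agree exactly); outlier windows get a single
spike at the local mean + 6 local SD, which deterministically exceeds the
recomputed mean + 5 SD bound; missing-temperature windows lose a
contiguous chunk. Default rates (6% artifact, 2% outlier, 5% missing
temperature, 3% missing CGM) put overall retention in the low-to-mid 80s
percent, a realistic figure for free-living wearable campaigns.

Two design choices deserve emphasis.

*Window-aligned circadian switching.* A sample takes the day/night level
of the analysis window it terminates. With switches at the raw clock
hours instead, the single window straddling each transition would mix
levels and be systematically mislabeled — a label-correlated artifact
that inflates the null rejection rate of every location metric. Aligning
the switch to the window grid makes each labeled window homogeneous in
circadian phase. `circadian_offset_min` deliberately misaligns it for
robustness experiments.

*An exchangeable-label null mode.* `iid_glucose = TRUE` draws glucose
serially independent, N(110, 25²), instead of the meal process. This
exists because the retrospective metrics are *running* statistics: their
trajectories drift over the recording, so any systematic association
between label positions and recording time (meals at fixed hours,
episodes lasting many consecutive windows) makes rank tests on them
anticonservative even when temperature is completely independent of
glycemia. That is a property of the analysis design itself, not a bug in
the generator — it equally affects analyses of real data, and is one
reason the per-subject results on running metrics should be read with
care. With serially independent glucose the label sequence is
exchangeable within (and across) periods, rank tests are exactly valid
for *all* metrics, and the type-I calibration study has a well-defined
target. The calibration suite verifies, over 200 seeded replicates of a
15-subject, 2-day null cohort, that the FDR-corrected per-subject
Wilcoxon stage rejects at most 7.5% of cells and that the mixed-model
fixed-effect test rejects within [2%, 10%] at α = 0.05. (The 2-day span
keeps 200 full-resolution replicates — about six billion temperature
samples in total — inside a practical compute envelope; the problem sizes
are stated here as the package's own choice of study scale.)

Conversely, the *effect-recovery* study uses the realistic episodic
process: with `cv_effect = 3` and at least 30 daytime BR windows per
subject, the CV-based metric family flags over 80% (in practice all) of
affected subjects after FDR correction, with the current-window CV alone
also above 80%. The running `CV_T SD` is notably less sensitive here
(roughly half of affected subjects): once early episodes have inflated
the running SD, later IR windows inherit the elevated value and the BR/IR
contrast dilutes. This saturation is intrinsic to full-history running
metrics on long recordings and is worth keeping in mind when comparing
against results on real cohorts, where slow physiological co-variation
(not modeled here) can favor retrospective metrics.

What the generator does *not* emulate: ambient-temperature confounding,
posture and activity effects, device drift, glucose sensor error,
physiologic glucose dynamics (meals are bumps, not insulin–glucose
kinetics), and subject-specific circadian phase. Passing the synthetic
studies therefore demonstrates correctness of the computational pipeline
and calibration of its statistics under the stated assumptions — not
clinical validity on real data.

## Numerical and interface choices

* Quartiles: type-7 (linear interpolation), R's default and the common
  convention when none is stated.
* Exact vs approximate rank-sum: exact when n + m ≤ 25 without ties.
* Retention of equality at screening bounds, SD = 0 windows, and the
  minimum group size of 4 are described above; all are configurable.
* All timestamps are parsed as local wall-clock time into a fixed
  timezone; fractional seconds carry the 4 Hz grid exactly (quarter
  seconds are dyadic, so the double representation is exact and
  half-open interval tests never suffer rounding).
* Synthetic traces are rounded to the device's two decimals (temperature)
  and integers (glucose), making CSV round-trips byte-exact and cohorts
  fully reproducible from a seed, file bytes included.
* M2 values are stored raw; only the rendered tables scale them by 10²
  (the header notes the 10⁻² convention).
* The analysis configuration is a plain list (`tg_config()`), loadable
  from YAML (`read_config()`); the generator configuration mirrors it
  (`tg_synth_config()`).

## Limitations

The per-subject testing stage treats windows as exchangeable units within
a period; for the three retrospective metrics this is only approximately
true on realistic (serially structured) data, as discussed above. The
mixed model assumes a common fixed effect across subjects and a single
residual variance; the day/night split is a fixed-clock proxy for
sleep/wake, and actigraphy-based sleep detection is out of scope. The
package reproduces the computational pipeline; validating the biomarkers
themselves requires real paired recordings, which the I/O layer reads in
the standard per-subject folder layout (`Dexcom.csv`, `TEMP.csv`).
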