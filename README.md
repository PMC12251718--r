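# thermoglyc

Skin-temperature variability metrics as digital biomarkers of glycemia.

`thermoglyc` analyzes paired recordings from a continuous glucose monitor
(CGM; one sample per 5 minutes, mg/dL) and a wrist-worn skin-temperature
sensor (4 Hz, °C), of the kind produced by free-living wearable studies
that store each subject as a folder with `Dexcom.csv` and `TEMP.csv`. It
is written for biosignal and digital-biomarker researchers who want a
tested, reproducible implementation of the full analysis chain:

1. **Ingestion & screening** — subjects with more than 20% missing CGM
   samples are excluded (computed on the subject's own monitoring span).
2. **Window alignment** — the 4 Hz stream is cut into backward 5-minute
   windows `(t − 300 s, t]`, one per CGM timestamp; a full window has
   exactly N = 5 × 60 × 4 = 1200 samples. Windows with missing glucose,
   missing temperature samples, any value below the 28 °C artifact floor,
   or any value outside the window-local mean ± 5 SD band are discarded.
3. **Metrics** — per retained window: mean, median, SD, IQR, CV, the mean
   amplitude deviation `MAD_T = 1.4826 · Σ|st_k − median|/N`, a J-index
   adaptation `J_T = 0.001·(mean + SD)²`, and two M-value adaptations
   `M_T = Σ|10·log10(st_k/r)|³/N` with r = 36 °C (M1) and 32 °C (M2);
   plus three retrospective metrics over windows 1..i: the running mean
   and running population SD of the CV series, and `SD_T hhmm`, the
   population SD of window means about the grand mean of all samples so
   far.
4. **Stratification** — glycemic range labels from the tight range
   (IR: 70–140 mg/dL inclusive; AR > 140; BR < 70) and a day/night label
   (daytime = [06:00, 21:00) wall clock).
5. **Statistics** — per subject, two-sided Wilcoxon rank-sum tests of AR
   vs IR and BR vs IR for each metric and period with Benjamini–Hochberg
   FDR correction; cohort-level linear mixed-effects models
   `value ~ glycemic_level + (1 | subject)` on square-root-transformed
   values; Lilliefors normality screening; percent-of-subjects
   significance summaries and publication-shaped tables
   (`median[p25; p75]`, `-` for absent cells, M2 rendered ×10⁻²).

A seeded synthetic-cohort generator (`tg_synth_config()`,
`generate_cohort()`) emulates the whole data-generating process —
circadian two-level temperature with AR(1) noise, meal-driven
hyperglycemia, hypoglycemic episodes, artifact/outlier/missingness
defects with ground-truth sidecars, and configurable
temperature–glycemia couplings — so every stage is testable without any
real deposit. See the methods vignette
(`vignettes/methods.Rmd`) for the model, assumptions and design choices.

## Worked example

```r
library(thermoglyc)

cfg <- tg_synth_config(n_subjects = 4, days = 2, hypo_subjects = 2, seed = 42)
subjects <- generate_cohort(cfg)          # in-memory; add out_dir= to write CSVs
res <- run_pipeline(subjects, fit_lme = FALSE)
res
```

```
Skin-temperature / glycemia analysis
  Subjects: 4 analyzed, 0 excluded (> 20% missing CGM)
  Windows: 2271 total, 1946 retained (85.7%)
  Top metric cells by % of subjects significant (FDR < 0.05):
    J_T        AR-vs-IR  daytime   100.0% (4/4)
    M1_T       AR-vs-IR  daytime   100.0% (4/4)
    M2_T       AR-vs-IR  daytime   100.0% (4/4)
    mean_T     AR-vs-IR  daytime   100.0% (4/4)
```

Four synthetic subjects were analyzed, none excluded; 85.7% of the 2271
candidate windows survived screening (the defaults inject artifacts,
outliers and missing segments at realistic rates). Every subject shows
significantly different daytime temperature levels between above-range
and in-range windows — the injected daytime hyperglycemia level shift,
recovered end-to-end through the level-sensitive metrics (mean, J-index,
M-values). Drill down with:

```r
subset(res$comparisons, metric == "CV_T" & contrast == "BR-vs-IR" &
                        period == "daytime" & n_alt > 0)
render_subject_table(res, "CV_T_SD")   # median[p25; p75] table, "-" cells
plot(res)                              # temperature histogram, 0.25 °C bins
export_cohort(res, "results/")         # tidy CSVs of every table
```

Real data in the per-subject folder layout are analyzed identically with
`run_pipeline("path/to/cohort_dir")`.

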