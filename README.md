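# placentapd

Simulation and pharmacodynamic analysis of longitudinal multimodal placental
imaging studies in preclinical models of preeclampsia.

## What problem this addresses, and for whom

Preclinical evaluation of placental therapeutics (e.g. statin rescue in the
L-NAME rat model of preeclampsia) increasingly relies on following the same
placenta in the same dam across gestation with several imaging modalities:
photoacoustic oximetry (hemoglobin oxygen saturation, sO₂), contrast-enhanced
ultrasound (wash-in area under the bolus time–intensity curve, WiAUC),
microvascular flow imaging (vascular index, VI) and pulse-wave Doppler
(uterine artery resistance index, UtA-RI = (PSV − EDV)/PSV). The scientific
question such designs answer is *when* and *how much* each physiological axis
recovers under treatment — functional recovery (oxygenation, perfusion)
typically precedes structural recovery (vessel density, arterial resistance).

This package is for biostatisticians and imaging scientists who need that
analysis chain as tested, reusable code: a seeded three-arm cohort generator
calibrated by group trajectory anchors and slopes, forward measurement models
for all four modalities, the two exploratory pharmacodynamic metrics, and the
supporting classical inference, composed into an end-to-end pipeline. Because
the motivating study deposits no subject-level data, the generator is
calibrated to its published group-level endpoints and doubles as a validation
harness: the whole measurement-and-metrics chain can be checked against its
own calibration.

## The core metrics

Per subject and marker, the **recovery slope** β is the OLS slope of the
marker against gestational day (GD), sign-flipped for markers where a
decrease means improvement, so positive adjusted β always means movement
toward the healthy phenotype. At the study endpoint the
**Functional Recovery Index**

```
FRI = 100 × (X_i − X̄_disease) / (X̄_control − X̄_disease)
```

places every modality on a common percent scale: 100 = complete
normalization to the healthy control level, 0 = no improvement over the
untreated disease phenotype, negative = further deterioration. Slopes are
compared between arms by homogeneity-of-slopes ANCOVA (with a
per-subject-slope t-test as sensitivity analysis), session-wise arm
contrasts come from a mixed repeated-measures ANOVA with Greenhouse–Geisser
correction and Bonferroni post hoc tests, FRIs are compared across
modalities by one-way ANOVA with Tukey HSD, and endpoint associations use
Pearson correlation / simple linear regression.

## Worked example

```r
library(placentapd)

fri(77.81, 80, 50)
#> [1] 92.7

study <- run_study(seed = 1, replicates = 20)
study
```

```
<pd_study> 20 replicate(s), seed 1

marker            slope disease          slope treated   p(slope)     FRI@endpoint  pattern
sbp             3.911 ± 0.123          2.146 ± 0.126        0.238     44.08 ± 29.6   no slope alteration
uprot           43.83 ± 1.21           29.12 ± 1.2          0.477     43.74 ± 35.3   no slope alteration
so2           -0.7253 ± 0.142          1.964 ± 0.143      0.00169     95.88 ± 7.03   trajectory inversion
wiauc            1453 ± 61.4            3246 ± 64        7.88e-05      91.2 ± 6.15   enhanced increase
vi             -1.028 ± 0.164        -0.7503 ± 0.2          0.843     68.57 ± 17.7   no slope alteration
uta_ri        0.00996 ± 0.00222    -0.004921 ± 0.00211     0.0147     43.06 ± 5.62   trajectory inversion
```

Each row is one marker, averaged over 20 replicate simulated cohorts of the
packaged study conditions (3 arms × 8 dams; systemic sessions GD 7/10/13/18,
imaging GD 14/16/18). The slope columns are the disease- and treated-arm
per-subject OLS slopes (± within-cohort SEM): e.g. oxygen saturation falls
by 0.73 %/day untreated but rises by 1.96 %/day under treatment — a
trajectory inversion — while blood pressure keeps rising, only more slowly.
`p(slope)` is the pooled ANCOVA interaction p (conservative for the
systemic markers under between-animal intercept variance; the per-subject
sensitivity test is in `study$summary$p_slope_subject_t`). `FRI@endpoint`
shows the functional markers nearly normalized (sO₂ ≈ 96 %, WiAUC ≈ 91 %)
while arterial resistance recovers less than half-way (≈ 43 %) — the
functional/structural dissociation the design is built to detect.

Session-wise detection of the treated-vs-disease contrast shows the
temporal ordering directly:

```r
cf <- study$contrast_freq
cf[cf$pair == "disease vs treated" & cf$marker %in% c("so2", "uta_ri"), ]
```

```
  marker gd               pair freq_significant mean_estimate
1    so2 14 disease vs treated             0.95       10.2193
2    so2 16 disease vs treated             1.00       15.4805
3    so2 18 disease vs treated             1.00       20.9765
4 uta_ri 14 disease vs treated             0.20       -0.0266
5 uta_ri 16 disease vs treated             0.80       -0.0570
6 uta_ri 18 disease vs treated             1.00       -0.0861
```

Oxygenation is already detectable in 95 % of replicates at the first
imaging session (GD14); arterial resistance only becomes reliably
detectable at the endpoint.

Every stage is also available separately — `generate_cohort()`,
`measure_cohort()`, `compute_pd_metrics()`, `rm_anova()`,
`ancova_slopes()`, `oneway_anova_tukey()` — and a thin command-line front
end ships in `inst/cli/placentapd.R`
(`Rscript placentapd.R run --seed 1 --out study`). Calibrations are YAML
configs (`read_calibration()` / `write_calibration()`; the packaged default
is `inst/extdata/default_calibration.yaml`).

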