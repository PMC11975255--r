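# actirhythm

Physical-activity and circadian-rhythm analysis of minute-epoch wrist
actigraphy, for clinical cohort studies that ask whether 24-hour
behaviour distinguishes patient groups — the motivating case is
relapsing-remitting versus progressive multiple sclerosis (RRMS / PMS).

Starting from 60-second-epoch vector-magnitude activity counts (1440
minutes per day over ~2 weeks of wear), the package provides:

- **Preprocessing** per the standard wrist-actigraphy rules: nonwear =
  maximal all-zero runs ≥ 90 min (detected across midnight), valid day =
  ≥ 1296 wear minutes (90%), subject inclusion = ≥ 3 valid days, and
  daylight-saving resolution (repeated hours averaged, skipped hours
  imputed from the subject's other valid days).
- **Intensity classification** at reference cut points (nonactive ≤ 2000
  < LIPA ≤ 6750 < MVPA, counts/min) with an optional cohort-specific
  recalibration maximizing concordance with IPAQ self-report.
- **PA metrics**: TAC, TLAC = Σ log(1 + count), minutes per intensity
  class, composition ratios, 2-hour TAC bins, and fragmentation
  SATP = (sedentary→active transitions)/(sedentary minutes),
  ASTP = (active→sedentary transitions)/(active minutes).
- **CR metrics**: M10/L5 circular-window landmarks and midpoints,
  relative amplitude RA = (M10 − L5)/(M10 + L5), daytime activity ratio
  (DARE), single-subject cosinor
  x(t) = M + A·cos(2π(t − φ)/24) fitted by least squares (MESOR M,
  amplitude A, acrophase φ), intradaily variability IV and interdaily
  stability IS on hourly means.
- **Functional PCA** of mean diurnal profiles (10-min binning, top 5
  components, deterministic sign convention).
- **JIVE** (Joint and Individual Variation Explained) of the PA and CR
  feature blocks: X_k = J_k + A_k + E_k with a shared joint subject-score
  space, per-block individual spaces orthogonal to it, permutation-based
  rank selection, and standardized uncorrelated latent scores.
- **Association models**: Welch t / chi-squared group comparisons and
  age-, sex-, BMI-adjusted logistic regressions per metric and per JIVE
  component, plus an M10-window sensitivity analysis.
- A **synthetic cohort generator** (three groups, coupled Markov-chain
  fragmentation and cosinor-modulated diurnal rhythm, realistic
  between-subject heterogeneity, nonwear, DST events, IPAQ reports) with
  retained ground truth, so every stage is validated by parameter
  recovery without any participant data.

## Worked example

```r
library(actirhythm)

coh <- simulateCohort(cohortConfig(nPerGroup = 20, nDays = 7, seed = 1))
pre <- preprocessCohort(coh)          # nonwear, valid days, inclusion
cl  <- pre$clean[[1]]
cl
#> CleanSeries 'S001': 7 valid day(s)

round(aggregateCr(cl), 3)[c("M10", "L5", "RA", "MESOR", "Amplitude",
                            "Acrophase", "IV", "IS")]
#>       M10        L5        RA     MESOR Amplitude Acrophase        IV        IS
#>  2457.644    42.059     0.966  1301.355  1453.286    15.500     0.326     0.914
```

This subject's most active 10 hours average 2458 counts/min against 42 in
the least active 5 (hence RA near 1); the fitted cosinor peaks at 15:30
with rhythm-adjusted mean 1301 and amplitude 1453 counts; the low IV
(0.33) and high IS (0.91) say the hourly pattern is smooth and repeats
across days.

```r
pa <- paFeatures(pre$clean)
cr <- crFeatures(pre$clean)
fp <- fitFpca(profileMatrix(pre$clean))
fp
#> FPCAModel: 60 subject(s), 5 component(s) on a 10-min grid
#>   variance explained: 41.0%, 15.7%, 3.5%, 2.6%, 2.2%

crAll <- cbind(cr, setNames(as.data.frame(fpcaScores(fp)),
                            paste0("fPC", 1:5)))
jm <- fitJive(list(featureBlock(pa, "PA"), featureBlock(crAll, "CR")),
              jointRank = 1, individualRanks = c(4, 3), maxIter = 5000)
jm
#> JIVEModel [PA + CR]: joint rank 1; individual ranks PA=4, CR=3
#>   PA: joint 52.0%, individual 38.7%, residual 9.3%
#>   CR: joint 27.4%, individual 49.3%, residual 23.3%

groupCompare(pa[, c("subject_id", "TAC", "MVPA", "ASTP")],
             subjectTable(coh))[, c("metric", "mean_PMS",
                                    "mean_RRMS-Stable", "p")]
#>   metric  mean_PMS mean_RRMS-Stable        p
#> 1    TAC 1.843e+06        2.087e+06 0.027786
#> 2   MVPA 4.194e+01        6.053e+01 0.004102
#> 3   ASTP 3.062e-01        2.644e-01 0.025807
```

Half of the PA block's variation is shared with the CR block (the joint
component), and even this small synthetic cohort shows the expected
group pattern: lower total activity and MVPA, more frequent
active-to-sedentary transitions in the progressive group.

`runPipeline(pipelineConfig(...), outDir = "...")` chains all stages and
writes flat CSV/JSON intermediates plus a markdown report;
`inst/scripts/run-pipeline.R` wraps it for the shell.

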