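# tachosep

Separation of respiratory influences from heart-rate tachograms.

Short-term heart-rate variability (HRV) is dominated by respiratory sinus
arrhythmia — the vagally mediated heart-rate oscillation at the breathing
frequency — which confounds spectral HRV indices whenever the breathing
pattern differs between subjects or conditions. Given a recorded
respiration signal r(n) and the tachogram t(n) (RR intervals in ms,
uniformly resampled at 4 Hz), `tachosep` splits the tachogram as

    t(n) = t_r(n) + t_resid(n)

into a respiration-driven component t_r and a residual t_resid containing
every heart-rate variation unrelated to breathing. The residual is always
computed by subtraction, so the identity holds to machine precision.

Five data-driven estimators of t_r are implemented:

| method | function | idea |
|---|---|---|
| LMS | `separate_lms()` | adaptive FIR filter on (Savitzky–Golay smoothed) respiration, weights updated as w(n+1) = w(n) + 2 mu e(n) x(n), two passes |
| ICA | `separate_ica()` | FastICA on the two-channel mixture [r; t], sources rescaled to ms by regression |
| FIR / ARX | `separate_armax()` | least squares of t(n) on r(n), ..., r(n−12) (delays up to 3 s at 4 Hz) |
| MSPCA | `separate_mspca()` | per-scale PCA on Daubechies-4 wavelet coefficients, scales kept only when the first eigenvector explains > 90% variance |
| OSP | `separate_osp()` | projection t_r = X(X'X)⁻¹X't onto a 61-column basis of delayed wavelet detail signals of r plus intercept |

Around them: tachogram construction from RR intervals (cubic-spline
resampling at 4 Hz), zero-phase 0.05 Hz high-pass preprocessing of
respiration, Welch spectral estimation with the standard LF (0.04–0.15 Hz)
/ HF (0.15–0.40 Hz) HRV band powers and normalized units, a ground-truth
synthetic cardiorespiratory generator, and two benchmark protocols: a
cross-validated simulation study on spliced composite tachograms and a
windowed stability study. The methods vignette
(`vignettes/tachogram-separation.Rmd`) documents the models, parameters
and numerical choices.

## Worked example

```r
library(tachosep)

# a 6-minute synthetic subject with known ground truth
subject <- generate_subject(cohort_config(), seed = 42)
subject
#> synthetic_subject (seed 42): 360 s @ 4 Hz, mean RR 900 ms
#>   sd: rsa 25.9 ms, residual 22.8 ms

res <- separate_osp(subject$tachogram, subject$respiration)
res
#> separation_result [osp]: 1440 samples @ 4 Hz
#>   var split: respiratory 58.5%, residual 42.1% of original
#>   11 leading samples flagged (regressor startup)

conservation_error(res)      # t - (t_r + t_resid), relative
#> [1] 0

hrv_features(res$original)
#> band_powers [ms^2]: LF 435.4  HF 672.2  TP 1108  LFnu 0.393  HFnu 0.607  LF/HF 0.648
hrv_features(res$residual)
#> band_powers [ms^2]: LF 437.2  HF 16.21  TP 453.6  LFnu 0.964  HFnu 0.036  LF/HF 26.978
```

The separation removes the respiration-driven HF power from the residual
(672 → 16 ms²) while leaving the LF power, which respiration does not
drive here, essentially untouched (435 → 437 ms²): the residual's spectral
profile now reflects non-respiratory autonomic modulation only. Against
the generator's ground truth, the estimated respiratory component has a
demeaned NRMSE of 0.037 (prefix excluded).

Benchmarks on a synthetic cohort:

```r
cohort <- generate_cohort(cohort_config(n_subjects = 20))
sim <- run_simulation_study(cohort)     # (subjects-1) x 5 x 4 metric rows
summarize_study(sim)                    # per-algorithm medians/quartiles
```

## Command line

A thin dispatcher is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "tachosep", package = "tachosep"))') \
  separate --method osp --rr rr.txt --resp resp.csv --out sep.csv
```

Subcommands: `separate`, `features`, `synth`, `pipeline`, `benchmark-sim`,
`benchmark-stability`. Each run writes its resolved parameters and seeds
to a JSON sidecar for reproducibility.

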