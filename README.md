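# eldshunt

Shunt surgery can reverse the symptoms of idiopathic normal pressure
hydrocephalus (iNPH), but only for patients whose hydrocephalus actually
drives their gait and cognitive decline. Continuous external lumbar
drainage (ELD) is used as a prognostic test before surgery: if a few days
of cerebrospinal-fluid drainage improves gait and cognition, a shunt is
likely to help. Traditional bedside measures of that improvement (MMSE,
10-m walk, timed up-and-go) are insensitive; computerized cognitive
batteries and vision-based 3-D gait analysis promise a sharper readout.

`eldshunt` implements the full evaluation pipeline for that setting, for
biostatisticians and clinical researchers working with small drainage-test
cohorts:

- **Composite improvement scoring.** Raw cognitive scores are standardized
  against population norms with direction-aware z-scores —
  z = (x − μ)/σ for "higher is better" tests, z = (μ − x)/σ for timed
  tests — and averaged into a composite cognitive z. Improvement rates are
  oriented percent changes, e.g. for a timed parameter
  (pre − post)/pre × 100, so positive always means clinically better; the
  gait rate averages five quantitative gait parameters, and the combined
  rate is the equal-weight mean of the cognitive and gait rates.
- **Responder rules.** The traditional positive-drainage-response criteria
  (≥20% on a 10-m-walk component, ≥10% on both, ≥10% TUG, or ≥3 MMSE
  points; all inclusive) and the shunt-responder definition (≥1-point mRS
  or any iNPHGS-domain improvement at the last follow-up).
- **Firth penalized logistic regression**, written from scratch: maximizes
  ℓ(β) + ½·log det I(β) (Jeffreys-prior penalty) by modified-score Newton
  iteration with step-halving, giving finite, bias-reduced odds ratios
  even with 5 events or complete separation. Wald and profile
  penalized-likelihood intervals, predictions, and an S3 modelling
  interface (`firth_glm`, `summary`, `confint`, `predict`, ...).
- **Diagnostics**: Mann–Whitney AUC with tie handling, Youden-index
  cutoffs, confusion metrics, reconstruction of integer confusion matrices
  from rounded published rates, the DeLong test for paired AUCs,
  stratified percentile bootstrap CIs, permutation tests on the penalized
  likelihood-ratio statistic, and calibration (Spiegelhalter test,
  logistic recalibration slope/intercept, binned mean calibration error).
- **A synthetic cohort generator** reproducing the statistical structure
  of a 70-patient drainage cohort (39 shunted, 5 nonresponders) with
  class-conditional improvement distributions, so the whole pipeline is
  testable without patient data.

## Worked example

```r
library(eldshunt)

gen    <- generate_cohort(default_cohort_config(), seed = 1)
report <- run_eld_analysis(gen$cohort, boot_B = 200, perm_B = 200, seed = 1)
print(report)
```

```
Drainage-test shunt-outcome analysis report
  cohort: n=70, shunted=39, responders=34, nonresponders=5
  diagnostics (positive class = nonresponder):
    traditional  AUC 0.506 (0.282-0.765)  cutoff 0.146  sens 0.800  spec 0.412
    gait         AUC 0.776 (0.506-1.000)  cutoff 0.428  sens 0.600  spec 1.000
    cognitive    AUC 0.659 (0.465-0.835)  cutoff 0.112  sens 1.000  spec 0.441
    combined     AUC 0.771 (0.529-0.941)  cutoff 0.099  sens 1.000  spec 0.529
  DeLong gait vs traditional: Z=1.33, p=0.1849
  DeLong cognitive vs traditional: Z=0.73, p=0.4651
  DeLong combined vs traditional: Z=1.32, p=0.1869
  calibration (combined (adjusted)): Spiegelhalter p=0.48, slope=1.430, mean error=2.2%
```

Reading this: among the 39 shunted patients, 34 improved measurably
(responders). Each improvement score is turned into a Firth-model
predicted probability of shunt *non*response (the positive class — with
only 5 nonresponders, that orientation is what the predictive values
refer to). The digital combined score separates nonresponders far better
than the traditional battery (AUC 0.77 vs 0.51); its Youden cutoff of
0.099 on the probability scale catches all 5 nonresponders (sensitivity
1.00) at specificity 0.53. The calibration block says the adjusted
combined model's probabilities track observed outcome frequencies
(Spiegelhalter p = 0.48, mean binned error 2.2%). `write_report()`
serializes every number, the seed and the configuration to JSON.

The cohort CSV schema (one wide row per patient; follow-ups as
`fu1_`/`fu2_`/`fu3_` blocks) is documented in `?read_cohort`, and the
norms table in `?read_norms`; `default_norms()` is an explicitly synthetic
placeholder, since the battery's population norms are supplied by the
user.

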