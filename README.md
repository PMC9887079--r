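# bmgrowth

Growth-dynamics discrimination of **radiation necrosis (RN)** from
**progressive disease (PD)** in brain metastases after stereotactic
radiotherapy (SRS/FSRT).

## The problem

After focal irradiation of a brain metastasis, both true tumour regrowth
and radiation necrosis — a transient inflammatory treatment effect —
enlarge on contrast-enhanced T1-weighted MRI and are nearly
indistinguishable on any single scan. Misreading one for the other leads
either to unnecessary surgery or to delayed retreatment. What *does*
differ is the growth dynamics: necrosis shows fast, accelerating but
transient growth, while recurrent tumour grows more steadily.

`bmgrowth` quantifies this with the Von Bertalanffy power-law growth
model for the contrast-enhancing volume *V* (cm³) over time *t* (months):

$$\frac{dV}{dt} = \alpha V^{\beta}, \qquad V(t_0) = V_0 .$$

Three consecutive scans with increasing volume `(V0, V1, V2)` at times
`(t0, t1, t2)` identify the three parameters `(V0, α, β)` **exactly**:
`V0` is pinned to the first measurement and `β` is the unique root of

$$\frac{V_2^{1-\beta} - V_1^{1-\beta}}{V_1^{1-\beta} - V_0^{1-\beta}}
  = \frac{t_2 - t_1}{t_1 - t_0},$$

with `α` back-substituted. The dimensionless growth exponent `β` is the
classifying score: `β > 1` means super-exponential (accelerating) growth,
typical of necrosis; `β < 1` decelerating growth, typical of recurrence.
The package also computes the two-point specific growth rates
`λ = log(V_b/V_a)/(t_b − t_a)` for each scan pair, a Monte-Carlo
robustness screen of `β` against bounded (±5%) volume error, and
cohort-level statistics: Kruskal–Wallis comparison of the exponents,
empirical ROC with trapezoidal AUC (positive class RN, higher `β` more
RN-like), and a Youden operating point.

Because the clinical dataset behind the method is not public, the package
includes a calibrated synthetic-cohort generator (`generate_cohort()`)
reproducing its structure — 60 PD and 41 RN lesions, group mean exponents
0.52 and 2.10, median scan intervals 3.04 and 2.42 months, treatment
strata SRS/FSRT/upfront-WBRT — so the whole pipeline is testable and
demonstrable end to end.

## Worked example

Fit one lesion (three scans, volumes in cm³, times in months):

```r
library(bmgrowth)
s <- lesion_series("BM-07", times = c(0, 3.1, 5.6),
                   volumes = c(0.42, 0.81, 2.33), label = "RN")
fit_vb_exponent(s)
#> Von Bertalanffy exponent fit: converged
#>   beta = 1.82877, alpha = 0.335312, V0 = 0.42 cm^3
#>   ratio residual 1.11e-16 after 13 iterations in bracket [-5, 10]
growth_rates(s)
#> lambda1 = 0.2119 /month, lambda2 = 0.4226 /month (accelerating)
assess_robustness(s, seed = 42)
#> Exponent robustness (+/-5% volume error, 200/200 refits)
#>   beta = 1.829; perturbed mean 1.831, median 1.825
#>   robust (|diff| < 0.5): by mean TRUE, by median TRUE
```

`beta = 1.83 > 1`: accelerating growth (the second-interval rate λ2 is
double the first), stable under ±5% volume error — an RN-like profile.

Cohort-level discrimination on the default calibrated synthetic cohort:

```r
cohort <- generate_cohort(cohort_config(), seed = 1)
ft <- fit_cohort(cohort)
ft <- add_robustness(ft, cohort, seed = 2)
run_discrimination(ft)
#> Discrimination of RN vs PD by growth exponent — stratum all
#>   n: 60 PD, 41 RN
#>   mean beta: PD 0.499, RN 2.03
#>   Kruskal-Wallis H = 23.2, p = 1.43e-06 (adjusted 1.43e-06)
#>   AUC = 0.783; at beta >= 0.979: sensitivity 0.805, specificity 0.650
#>   mean lambda1: PD 0.255 vs RN 0.162; mean lambda2: PD 0.187 vs RN 0.288
```

The RN group's exponents sit far above the PD group's (p < .001) and the
exponent classifies the two conditions with AUC ≈ 0.78. Note the
growth-rate reversal: over the first scan pair PD grows *faster*
(λ1: 0.255 vs 0.162/month), over the second RN does (λ2: 0.187 vs
0.288/month) — a single two-scan growth rate is therefore an unreliable
discriminator, while the exponent, which captures the acceleration, is
not.

`run_pipeline()` chains everything (ingest or simulate → fit →
robustness → stratified discrimination) and writes a per-lesion table,
per-stratum JSON results, ROC point files and a run manifest. A thin
command-line front end with `simulate`, `fit`, `robustness`,
`discriminate` and `run` subcommands is installed at
`inst/cli/bmgrowth.R`. Real cohorts are read from CSV (one row per scan:
`lesion_id, patient_id, time_months, volume_cm3[, label, subgroup,
upfront_wbrt]`) via `read_cohort()`.

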