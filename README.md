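# periogrm

Item response theory tools for periodontal epidemiology: given full-mouth
periodontal charts, `periogrm` fits Samejima's graded response model (GRM)
to site-level severity data, ranks examination sites by Fisher
information, and reduces the 168-site full-mouth examination to a
justified 6-variable, 12-site partial protocol — then evaluates how well
that partial protocol stands in for the full mouth.

## Who this is for

Periodontal epidemiologists and biostatisticians who need a
*defensible* partial-mouth examination protocol. Classic partial indices
(CPI index teeth, PDI, and relatives) fix their examination teeth by
convention; here the subset is chosen by a statistical criterion — the
information each site carries about a patient's latent periodontal
severity.

## The model in brief

Each site is an item. CAL and PD readings are categorized into ordered
severity classes (< 4, 4–5, > 5 mm by default); BOP is binary. Responses
follow the graded response model with logistic boundary curves

P\*ₖ(θ) = 1 / (1 + exp(−a(θ − bₖ))),

one discrimination *a* and ordered extremity parameters b₁ < b₂ per item,
under a standard-normal latent severity trait θ. No 1.7 scaling constant
is used, so a dichotomous item's information integral over the trait range
equals its discrimination. Estimation is marginal maximum likelihood by
EM; abilities are EAP posterior means. Site selection proceeds stepwise:

1. **Model 1** — all 168 sites;
2. **Model 2** — the best site per tooth type by bilateral (left+right)
   information sum: 28 sites;
3. **Model 3** — the top six tooth types: 12 sites;
4. **Model 4** — left/right pairs merged by worst category: 6 variables.

Evaluation covers GLM link selection by AIC, ROC analysis with the
equal-error cutoff rule (argmin |sensitivity − specificity|), CDC-AAP case
classification, a CPI (PD+BOP) comparator, and partial-exam metrics
(sensitivity, prevalence, relative bias of severity and extent). Because
no patient-level dataset is deposited with the reference study, the
package ships a calibrated synthetic cohort generator whose default preset
plants the published final-model parameters at the six published winner
sites and reproduces the reference cohort's descriptive statistics
(mean CAL 3.1 mm, mean PD 2.5 mm, BOP 15.0%, PlI 0.3 at n = 254).

## Worked example

```r
library(periogrm)

cohort <- generate_cohort(cohort_config(n_subjects = 254, seed = 1))
sprintf("cohort means: CAL %.2f mm, PD %.2f mm, BOP %.1f%%",
        mean(cohort$cal), mean(cohort$pd), 100 * mean(cohort$bop))
#> "cohort means: CAL 3.07 mm, PD 2.49 mm, BOP 15.2%"

chain <- build_model_chain(cohort, parameter = "cal")
chain
#> Stepwise site-selection chain (cal):
#>   Model 1: 168 sites  -> Model 2: 28 sites  -> Model 3: 12 sites  -> Model 4: 6 merged variables
#>   kept tooth types: max3, max2, max4, max1, max5, mand5

grm_param_table(chain$model4)[, 1:5]
#>             item Extrmt1 Extrmt2 Dscrmn ItemInformation
#> 1  max1:l-distal  0.5716   1.304   3.14            5.19
#> 2 max2:l-central  0.9804   1.366   4.81            7.49
#> 3  max3:l-mesial  0.4494   1.061   4.57            7.97
#> 4  max4:l-distal  0.2248   0.896   4.24            7.42
#> 5  max5:l-mesial -0.0253   0.989   2.90            5.13
#> 6 mand5:l-mesial  0.3990   1.734   1.67            2.74

partial_exam_metrics(cohort, chain$selected_sites)
#> Partial exam (12 sites, CAL > 4 mm): sensitivity 0.522, prevalence 0.516,
#>   relative bias severity 0.0199, extent 0.0146

resp <- chart_to_response_matrix(cohort, chain$selected_sites, "cal",
                                 bilateral = TRUE)
ability <- eap_ability(chain$model4, resp$responses)
stats <- summary_stats(cohort)
roc_analysis(ability$theta, as.integer(stats$mean_cal > 4))
#> ROC: AUC 0.990; cutoff 1.030 (sens 0.962, spec 0.956, +LR 21.92)
```

Reading the output: the chain recovers five of the six generating winner
tooth types at this cohort size; the sixth (the mandibular first premolar,
the weakest planted item at information 3.27) swaps with a background
tooth under sampling noise at n = 254 — at n = 500 the planted set is
recovered with recall ≥ 0.8 across seeds, which the test suite checks.
The six-variable ability separates severe full-mouth disease
(mean CAL > 4 mm) with AUC 0.99 on this synthetic cohort; the equal-error
cutoff 1.03 on the ability scale gives sensitivity ≈ specificity ≈ 0.96.

A command-line wrapper for the same pipeline
(`simulate` / `fit` / `select` / `evaluate` / `score`) is installed at
`inst/cli/periogrm`; see `run_pipeline_cli()`.

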