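---
title: "Selecting optimal periodontal examination sites with graded response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting optimal periodontal examination sites with graded response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A full-mouth periodontal examination records six probing sites on each of
up to 28 teeth — 168 sites — and at each site several clinical parameters:
clinical attachment level (CAL, mm), probing pocket depth (PD, mm),
bleeding on probing (BOP), plaque index (PlI, 0–3) and tooth mobility
(0–3). Epidemiological surveys and mass screenings cannot afford this, so
partial-mouth indices examine a fixed subset of teeth — but the classic
index-teeth choices (CPI, PDI, and relatives) were never derived from a
statistical criterion.

`periogrm` treats site selection as an item-selection problem in item
response theory. Each examination site is an *item*; a patient's
periodontal severity is a single latent trait $\theta$; the ordinal
severity category observed at a site is that item's response. Sites whose
responses carry the most Fisher information about $\theta$ are, by
construction, the sites that best represent the whole mouth.

## The model

Site-level CAL and PD are categorized into three ordered severity classes,
by default $<4$, $4\text{–}5$, and $>5$ mm (`categorization_config(4, 5)`).
An alternative $<4$ / $4\text{–}6$ / $>6$ mm scheme is available as
`categorization_config(4, 6)`; both appear in the clinical literature for
this protocol and the package keeps the choice explicit rather than silent.
BOP stays binary. PlI and mobility (0–3) are collapsed to three ordered
levels $\{0, 1, \geq 2\}$, which matches the two-threshold structure under
which the reference parameters of the final models are reported.

Responses follow Samejima's graded response model. For item $j$ with
discrimination $a_j > 0$ and ordered thresholds
$b_{j1} < \dots < b_{jm}$, the boundary curves are logistic,

$$P^*_{jk}(\theta) = \frac{1}{1 + e^{-a_j (\theta - b_{jk})}},$$

and category probabilities are their differences
$P_{jk} = P^*_{jk} - P^*_{j,k+1}$ (with $P^*_{j0} = 1$,
$P^*_{j,m+1} = 0$). No 1.7 scaling constant is applied to the logistic:
with this pure-logistic parameterization the integrated information of a
dichotomous item equals its discrimination, which is the identity the
reference parameter table exhibits (e.g. a bleeding item with $a = 3.70$
has integrated information 3.70), and which makes "information" directly
comparable to "discrimination" when ranking sites.

The Fisher information of item $j$ is

$$I_j(\theta) = a_j^2 \sum_k \frac{(w_k - w_{k+1})^2}{P^*_{jk} - P^*_{j,k+1}},
\qquad w_k = P^*_{jk}(1 - P^*_{jk}),$$

and sites are ranked by $\int I_j(\theta)\,d\theta$ over $[-10, 10]$.

## Estimation

`fit_grm()` maximizes the marginal likelihood under a standard-normal
latent prior (which fixes the scale) by EM:

* **E-step** — posterior weights of each subject over a fixed grid of 61
  equally spaced quadrature nodes on $[-6, 6]$ with normalized normal
  prior weights. Missing responses (missing teeth) simply drop out of the
  subject's likelihood product (missing-at-random).
* **M-step** — each item's expected complete-data log-likelihood is
  maximized by warm-started BFGS over $(\log a,\ b_1,\ \log \Delta_2,
  \dots)$, the log-gap reparameterization keeping thresholds strictly
  ordered. A small number of BFGS steps per M-step (a generalized EM)
  preserves the likelihood ascent, which the tests assert to $10^{-8}$
  per step.

Starting values are $a = 1$ and thresholds at prior quantiles of the
observed cumulative category frequencies. Convergence is declared when the
marginal log-likelihood changes by less than `tol` (default $10^{-4}$);
non-convergence is flagged on the fit, not raised. The EM is deterministic
given data and starts — no seed enters estimation.

Information integrals use a 2001-point trapezoid grid on $[-10, 10]$.
Dense fixed grids, rather than adaptive quadrature, were chosen because
very steep items (discriminations above ~7) concentrate their information
in spikes a few hundredths wide on the $\theta$ axis, which adaptive rules
visibly under-integrate; on the fixed grid the integrals are stable to
better than $10^{-3}$ for every discrimination met in practice. Reported
reference values for two extremely steep bleeding items ($a = 7.71,
16.96$, printed informations 7.62 and 16.65) carry exactly this kind of
integration error in the software that produced them; the pure integral
equals the discrimination, and this package reproduces only the
moderate-discrimination values as printed.

Ability is scored by EAP (`eap_ability()`): the posterior mean and SD on a
denser 201-point grid, so posterior means are stable to about $10^{-4}$
against a $10^4$-node reference. An all-missing pattern returns the prior.
`score_table()` enumerates all $\prod_j (m_j + 1)$ response patterns of a
short protocol (729 for six three-category items) with their abilities —
the "quick reference" with which a field protocol can be scored on paper —
plus an aggregation by raw sum score. A caption in the source literature
describes ability as a "sum of weighted scores"; that phrase is ambiguous
(it matches no standard GRM estimator), and this package reads it as
exactly this pattern-to-ability lookup, which is what a weighted scoring
table operationalizes.

## The stepwise reduction

`build_model_chain()` reproduces the four-model reduction:

1. **Model 1** — fit all 168 unilateral sites.
2. **Model 2** — for each of the 14 tooth types (jaw × distance from
   midline), keep the surface/position with the highest *bilateral*
   information sum (left + right), and refit the resulting 28 sites.
3. **Model 3** — rank tooth types by bilateral information in the 28-site
   fit, keep the top $k = 6$, and refit their 12 sites. The source
   procedure states only that higher-information teeth were kept; top-$k$
   by bilateral information sum is the operationalization here, with $k$
   configurable.
4. **Model 4** — merge each left/right pair into one variable by worst
   category (`merge_bilateral()`: "at least one side in the top category"
   scores top, only "both sides below" scores bottom) and refit the six
   merged items.

Models 2–4 are refit from scratch rather than carrying Model 1 parameters
forward: each reduced item set defines its own marginal likelihood, and
refitting keeps the information criteria comparable within each stage.
Ties in the argmax are broken deterministically (higher summed
discrimination, then lingual before buccal, then mesial, central, distal).
Sites whose top severity category is empty in a given cohort are
category-collapsed before fitting and recorded in the chain's audit table.
Molars can be excluded up front (`include_molars = FALSE`) to reproduce
the premolar/anterior examination universe argued for on anatomical
grounds (furcations, enamel projections, occlusal load); the default keeps
all 28 teeth and lets information decide.

The chain's EM defaults (`tol = 1e-3`, `max_iter = 60`, two BFGS steps per
M-step) are coarser than `fit_grm()`'s: selection consumes only the
information *ordering*, which stabilizes long before the parameters reach
full precision. With these settings a complete 168 → 6 chain on a
500-subject cohort runs in well under a minute.

## Evaluation tools

* `glm_link_selection()` regresses a full-mouth summary on ability over
  the candidate set {Gaussian-identity, Gaussian-log, Gamma-log,
  Gamma-inverse} and keeps the minimum-AIC fit — the ability-to-mean-CAL
  relationship is visibly curved, so the link is chosen by fit, not
  assumption.
* `roc_analysis()` (curve and AUC via pROC) chooses the cutoff minimizing
  $|\text{sensitivity} - \text{specificity}|$, ties broken toward higher
  sensitivity — the equal-error rule used to read screening cutoffs off
  these curves.
* `cdc_aap_classify()` applies the CDC-AAP surveillance case definitions
  (interproximal sites, different-teeth requirements; severe: ≥2
  interproximal CAL ≥ 6 mm on different teeth plus ≥1 interproximal
  PD ≥ 5 mm; moderate: ≥2 interproximal CAL ≥ 4 mm or ≥2 interproximal
  PD ≥ 5 mm, each on different teeth).
* `cpi_score()` is the community periodontal index comparator. The charts
  carry no calculus data, so CPI code 2 is unreachable; the comparator is
  therefore a "CPI (PD+BOP)" variant — per-site codes 4 (PD ≥ 6 mm),
  3 (PD 4–5 mm), 1 (BOP), 0 — which preserves its use for ranking
  subjects.
* `partial_exam_metrics()` scores any partial protocol against the full
  mouth: sensitivity for detecting a subject with at least one site of
  CAL > 4 mm (strictly greater, per the convention in the partial-mouth
  literature; configurable to ≥), partial-exam prevalence, and relative
  bias of severity (mean CAL) and extent (share of sites CAL ≥ 4 mm).
  Biases are cohort-level ratios of means — the convention under which
  published biases of order $10^{-3}$ are interpretable — with a
  per-subject variant behind a flag.

## The synthetic cohort generator

No site-level periodontal dataset is deposited with the reference study,
so validation runs on synthetic cohorts (`generate_cohort()`) built to
have exactly the latent structure the analysis assumes:

* one severity trait $\theta \sim N(0,1)$ per subject drives *all*
  parameters;
* each site's CAL category is drawn from the GRM under that site's
  susceptibility profile; the `"paper-2020"` preset plants the published
  final-model CAL parameters at the six reference winner sites (mirrored
  left/right), attenuates the other sites of those teeth, and gives every
  remaining tooth type a low-information background profile — so the
  selection pipeline has a known ground truth;
* integer millimetres are emitted per category (category 0 → 1–3 mm,
  category 1 → 4–5 mm, category 2 → 6 mm plus a geometric tail), matching
  probe-reading granularity and making categorization exactly invertible;
* PD is CAL minus a truncated-Poisson recession (floor 1 mm), which
  guarantees PD ≤ CAL and the observed ordering of the cohort means;
* BOP is Bernoulli on a logit in $\theta$ with a bonus at sites already in
  a diseased CAL category; PlI (per site) and mobility (per tooth) come
  from cumulative-logistic models on the same trait;
* teeth go missing with Poisson rate 1.5 per subject, truncated so every
  chart keeps ≥ 20 of 28 teeth (the usual inclusion criterion for treated
  chronic-periodontitis cohorts).

The emission tables, recession rate, and intercepts are calibrated once so
that a 254-subject cohort reproduces the reference cohort's descriptive
statistics — mean CAL 3.1 mm, mean PD 2.5 mm, BOP 15.0%, mean PlI 0.3 —
which the test suite checks across seeds. Only the four cohort means are
published, so the calibration targets exactly those; site-level
distributions are otherwise the generator's own construction.

**What passing tests do and do not show.** The generator emulates the
unidimensional latent structure, ordinal emission, probe granularity,
bilateral symmetry and tooth missingness of real charts. It does not
emulate spatial clustering of deep pockets within quadrants, examiner
variation, or localized (tooth-specific) disease; because one trait drives
every site, severe interproximal findings co-occur more often than in real
treated cohorts, and the CDC-AAP class distribution is shifted toward
"severe" relative to a clinical population. Recovery and recall results on
these cohorts therefore validate the estimator and the selection machinery
under the model's own assumptions — they do not certify performance on
real charts, where the latent structure is at best approximate.

## Validation scale and reproducibility

The test suite exercises: parameter recovery at $n = 2000$ (mean absolute
error below 0.4 for discriminations and 0.15 for thresholds);
planted-truth selection recall of the six winner tooth types at
$n = 500$ over 20 seeded replicates (mean recall ≥ 0.8); information-rank
recovery at the reference cohort size $n = 254$ (two generating items are
near-tied at 7.97 vs 7.93 integrated information, so rank recovery is
checked by rank correlation and by identification of the least informative
item rather than a strict full ordering, which is not identifiable at any
sample size); calibration of the preset at $n = 254$; and oracle
equivalences for the AUC (exhaustive pair counting), the EM (direct
marginal-likelihood maximization), and EAP scoring (dense-grid
posteriors). All randomness flows through explicit integer seeds; the EM
itself is deterministic.

## Known limitations

* Unidimensional IRT only; no multidimensional, partial-credit, nominal,
  or MCMC estimation.
* The latent scale is identified by the N(0,1) prior; abilities are
  comparable across protocols only through the model, not across
  differently calibrated fits.
* The categorization discrepancy (4–5/>5 vs 4–6/>6 mm) in the source
  literature is unresolved; both schemes are supported and the default is
  the Methods-text scheme.
* CPI is computed without calculus, and the CDC-AAP thresholds follow the
  published surveillance definitions rather than any re-derivation.
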