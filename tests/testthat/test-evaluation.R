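test_that("link selection picks the generating family and reports exact AICs", {
  set.seed(4)
  x <- seq(-2, 2, length.out = 80)
  y_lin <- 3 + 0.8 * x + rnorm(80, sd = 0.01)
  expect_equal(glm_link_selection(x, y_lin)$family_label, "gaussian-identity")

  y_exp <- exp(0.5 * x) * exp(rnorm(80, sd = 0.15))
  expect_match(glm_link_selection(x, y_exp)$family_label, "log")

  # AIC of every candidate equals -2*loglik + 2p recomputed from the glm
  x12 <- 1:12 / 4; y12 <- 2 + x12 + rnorm(12, sd = 0.3)
  g <- glm_link_selection(x12, y12)
  for (i in which(g$candidates$error == "")) {
    fam <- g$candidates$family[i]
    refit <- glm(y12 ~ x12, family = switch(fam,
      "gaussian-identity" = gaussian(),
      "gaussian-log" = gaussian("log"),
      "Gamma-log" = Gamma("log"),
      "Gamma-inverse" = Gamma("inverse")))
    expect_equal(g$candidates$aic[i],
                 -2 * as.numeric(logLik(refit)) + 2 * attr(logLik(refit), "df"))
  }
  # negative responses knock out the Gamma candidates, not the fit
  g2 <- glm_link_selection(x, y_lin - 10)
  expect_equal(g2$family_label, "gaussian-identity")
  expect_true(any(grepl("requires y > 0", g2$candidates$error)))
  expect_error(glm_link_selection(1:5, 1:5), "at least 10")
})

test_that("ROC analysis matches the pair-counting oracle and the cutoff rule", {
  # perfectly separated
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # worked example: 1 discordant-free arrangement
  r2 <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1))
  expect_equal(r2$auc, 1)

  # constant scores: chance by the tie convention
  r3 <- roc_analysis(rep(2, 10), rep(0:1, 5))
  expect_equal(r3$auc, 0.5)

  # oracle equivalence on random instances (with ties) up to n = 200
  set.seed(11)
  for (n in c(20, 75, 200)) {
    score <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    outcome <- rbinom(n, 1, plogis(3 * (score - 0.5)))
    if (length(unique(outcome)) < 2) next
    r <- roc_analysis(score, outcome)
    expect_equal(r$auc, pair_count_auc(score, outcome), tolerance = 1e-12)
    # chosen cutoff minimizes |sens - spec| over the whole curve
    gap <- abs(r$curve$sensitivity - r$curve$specificity)
    expect_lte(abs(r$sensitivity - r$specificity), min(gap) + 1e-12)
  }
  expect_error(roc_analysis(1:5, rep(1, 5)), "both outcome classes")
})

test_that("CDC-AAP classification applies the case definitions", {
  healthy <- make_flat_chart(cal = 2, pd = 3)
  expect_equal(as.character(cdc_aap_classify(healthy)$diagnosis), "none")

  # two interproximal CAL 4 sites on different teeth -> moderate
  mod <- make_flat_chart(cal = 2, pd = 3)
  mod <- set_site(mod, 11, "buccal", "mesial", "cal", 4)
  mod <- set_site(mod, 24, "lingual", "distal", "cal", 4)
  expect_equal(as.character(cdc_aap_classify(mod)$diagnosis), "moderate")

  # the same CAL at non-interproximal (central) sites does not count
  ctr <- make_flat_chart(cal = 2, pd = 3)
  ctr <- set_site(ctr, 11, "buccal", "central", "cal", 4)
  ctr <- set_site(ctr, 24, "lingual", "central", "cal", 4)
  expect_equal(as.character(cdc_aap_classify(ctr)$diagnosis), "none")

  # two interproximal CAL >= 6 on different teeth + one interproximal
  # PD >= 5 -> severe
  sev <- make_flat_chart(cal = 2, pd = 3)
  sev <- set_site(sev, 11, "buccal", "mesial", "cal", 6)
  sev <- set_site(sev, 24, "lingual", "distal", "cal", 6)
  sev <- set_site(sev, 31, "buccal", "mesial", "pd", 5)
  expect_equal(as.character(cdc_aap_classify(sev)$diagnosis), "severe")

  # both CAL 6 sites on the same tooth fail the different-teeth requirement
  # of both clauses (one tooth with CAL >= 4, one tooth with PD >= 5)
  same <- make_flat_chart(cal = 2, pd = 3)
  same <- set_site(same, 11, "buccal", "mesial", "cal", 6)
  same <- set_site(same, 11, "buccal", "distal", "cal", 6)
  same <- set_site(same, 31, "buccal", "mesial", "pd", 5)
  expect_equal(as.character(cdc_aap_classify(same)$diagnosis), "none")

  # severe implies the moderate CAL clause (monotone severity)
  d_sev <- cdc_aap_classify(sev)
  expect_true(all(d_sev$diagnosis[d_sev$diagnosis == "severe"] > "none"))
})

test_that("CPI scores the per-person maximum over index teeth", {
  healthy <- make_flat_chart(cal = 2, pd = 2)
  expect_equal(cpi_score(healthy)$cpi, 0L)

  deep <- set_site(make_flat_chart(cal = 2, pd = 2), 16, "buccal", "mesial",
                   "pd", 6)
  expect_equal(cpi_score(deep)$cpi, 4L)
  shallow_pocket <- set_site(make_flat_chart(cal = 2, pd = 2), 16, "buccal",
                             "mesial", "pd", 4)
  expect_equal(cpi_score(shallow_pocket)$cpi, 3L)
  bleed <- set_site(make_flat_chart(cal = 2, pd = 2), 11, "buccal", "mesial",
                    "bop", 1)
  expect_equal(cpi_score(bleed)$cpi, 1L)

  # a deep pocket on a non-index tooth only counts with index_teeth_only = FALSE
  off_index <- set_site(make_flat_chart(cal = 2, pd = 2), 14, "buccal",
                        "mesial", "pd", 6)
  expect_equal(cpi_score(off_index)$cpi, 0L)
  expect_equal(cpi_score(off_index, index_teeth_only = FALSE)$cpi, 4L)
})

test_that("partial-exam metrics match hand arithmetic and sign conventions", {
  co <- generate_cohort(cohort_config(n_subjects = 40, seed = 12))
  all_sites <- site_universe()
  # identity protocol: sensitivity 1, both biases exactly 0
  m_full <- partial_exam_metrics(co, all_sites)
  expect_equal(m_full$sensitivity, 1)
  expect_equal(m_full$relative_bias_severity, 0)
  expect_equal(m_full$relative_bias_extent, 0)

  # two-chart toy with hand-computed biases
  ch <- rbind(make_flat_chart("A", cal = 2), make_flat_chart("B", cal = 4))
  part <- site_universe()
  part <- part[part$tooth == 11, ]  # 6 sites per chart
  m <- partial_exam_metrics(ch, part, case_threshold_mm = 4, strict = TRUE)
  # cohort mean CAL = 3 everywhere; partial mean = 3 as well -> bias 0
  expect_equal(m$relative_bias_severity, 0)
  # no site exceeds 4 mm strictly: sensitivity undefined
  expect_false(m$sensitivity_defined)
  expect_true(is.na(m$sensitivity))
  expect_equal(m$prevalence, 0)
  # with >= 4: chart B is positive everywhere
  m_ge <- partial_exam_metrics(ch, part, strict = FALSE)
  expect_equal(m_ge$sensitivity, 1)
  expect_equal(m_ge$prevalence, 0.5)

  # partial sites systematically shallower -> negative severity bias
  ch2 <- make_flat_chart("C", cal = 5)
  ch2$cal[ch2$tooth == 11] <- 2L
  m_neg <- partial_exam_metrics(ch2, part)
  expect_lt(m_neg$relative_bias_severity, 0)
  expect_lt(m_neg$relative_bias_extent, 0)
  # exact value: partial mean 2, full mean (114*5 + 6*2)/120
  full_mean <- (114 * 5 + 6 * 2) / 120
  expect_equal(m_neg$relative_bias_severity, (2 - full_mean) / full_mean)

  # sensitivity is monotone under protocol growth
  sub1 <- planted_sites()
  sub2 <- rbind(sub1, all_sites[all_sites$tooth %in% c(16, 26), ])
  s1 <- partial_exam_metrics(co, sub1)$sensitivity
  s2 <- partial_exam_metrics(co, sub2)$sensitivity
  expect_gte(s2, s1)
})

test_that("12-site means track full-mouth summaries on default cohorts", {
  co <- generate_cohort(cohort_config(n_subjects = 254, seed = 33))
  stats <- summary_stats(co)
  pred <- predict_full_mouth_summary(co, planted_sites(), "cal")
  pred <- pred[stats$patient_id]
  expect_gte(cor(pred, stats$mean_cal), 0.85)
  # predicted means discriminate severe full-mouth disease
  outcome <- as.integer(stats$mean_cal > 4)
  r <- roc_analysis(as.numeric(pred), outcome)
  expect_gt(r$auc, 0.9)
  # identity-link GLM with slope 1, intercept 0 predicts the ability itself
  g <- list(fit = glm(y ~ x, data = data.frame(x = 1:20, y = 1:20)),
            family_label = "gaussian-identity")
  class(g) <- "perio_glm"
  ab <- c(-1, 0, 1.5)
  expect_equal(predict_full_mouth_summary(method = "glm", model = g,
                                          ability = ab), ab)
  expect_error(predict_full_mouth_summary(method = "glm", model = NULL,
                                          ability = ab), "requires")
})
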