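# Downstream evaluation of a fitted chain: GLM link selection, ROC with the
# equal-error cutoff rule, CDC-AAP case classification, a PD/BOP community
# periodontal index comparator, and partial-examination bias metrics.

#' GLM of a full-mouth summary on ability, with link selection by AIC
#'
#' Fits the candidate set {Gaussian-identity, Gaussian-log, Gamma-log,
#' Gamma-inverse} of generalized linear models of `y` on `x` and returns the
#' minimum-AIC fit. Candidates whose family requires positive responses are
#' skipped (with the failure recorded) when `y` violates that.
#'
#' @param x Predictor (e.g. EAP ability), length >= 10.
#' @param y Response (e.g. full-mouth mean CAL).
#' @return Object of class `perio_glm`: list with `fit` (the winning `glm`),
#'   `family_label`, `coefficients`, `aic`, `p_values`, and `candidates`
#'   (data frame of per-candidate AICs or failure messages).
#' @export
glm_link_selection <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) stop("need at least 10 observations")
  cands <- list("gaussian-identity" = gaussian(),
                "gaussian-log" = gaussian(link = "log"),
                "Gamma-log" = Gamma(link = "log"),
                "Gamma-inverse" = Gamma(link = "inverse"))
  d <- data.frame(x = x, y = y)
  results <- lapply(names(cands), function(nm) {
    fam <- cands[[nm]]
    if (fam$family == "Gamma" && any(y <= 0))
      return(list(label = nm, error = "Gamma family requires y > 0"))
    fit <- tryCatch(glm(y ~ x, family = fam, data = d),
                    error = function(e) e, warning = function(w) {
                      suppressWarnings(glm(y ~ x, family = fam, data = d))
                    })
    if (inherits(fit, "error"))
      return(list(label = nm, error = conditionMessage(fit)))
    if (!fit$converged) return(list(label = nm, error = "did not converge"))
    list(label = nm, fit = fit, aic = AIC(fit))
  })
  ok <- vapply(results, function(r) is.null(r$error), logical(1))
  if (!any(ok))
    stop("all GLM candidates failed: ",
         paste(vapply(results, function(r) paste0(r$label, " (", r$error, ")"),
                      ""), collapse = "; "))
  aics <- vapply(results, function(r) if (is.null(r$error)) r$aic else NA_real_,
                 numeric(1))
  best <- results[[which.min(aics)]]
  sm <- summary(best$fit)
  structure(list(fit = best$fit,
                 family_label = best$label,
                 coefficients = coef(best$fit),
                 aic = best$aic,
                 p_values = sm$coefficients[, 4],
                 candidates = data.frame(
                   family = vapply(results, `[[`, "", "label"),
                   aic = aics,
                   error = vapply(results, function(r) r$error %||% "", ""),
                   stringsAsFactors = FALSE)),
            class = "perio_glm")
}

#' @export
print.perio_glm <- function(x, ...) {
  cat("GLM (", x$family_label, "), AIC ", round(x$aic, 2), "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' ROC analysis with the equal-error cutoff rule
#'
#' Builds the ROC curve of a continuous score against a binary outcome and
#' chooses the cutoff minimizing |sensitivity - specificity| (ties broken
#' toward higher sensitivity). Higher scores indicate the positive class.
#' The curve and AUC come from \pkg{pROC}; the cutoff rule is applied to the
#' full coordinate set.
#'
#' @param score Numeric predictor, one value per subject.
#' @param outcome Binary outcome (0/1 or logical).
#' @return Object of class `perio_roc`: list with `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `plr` (positive likelihood ratio), and
#'   `curve` (data frame of threshold, sensitivity, specificity).
#' @export
roc_analysis <- function(score, outcome) {
  outcome <- as.integer(outcome)
  stopifnot(length(score) == length(outcome), all(outcome %in% 0:1))
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present")
  if (length(unique(score)) == 1L) {
    # degenerate constant score: chance discrimination by the tie convention
    curve <- data.frame(threshold = c(-Inf, Inf),
                        sensitivity = c(1, 0), specificity = c(0, 1))
    return(structure(list(auc = 0.5, cutoff = -Inf, sensitivity = 1,
                          specificity = 0, plr = 1, curve = curve),
                     class = "perio_roc"))
  }
  r <- pROC::roc(response = outcome, predictor = score,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- data.frame(threshold = r$thresholds,
                      sensitivity = r$sensitivities,
                      specificity = r$specificities)
  gap <- abs(curve$sensitivity - curve$specificity)
  cand <- which(gap == min(gap))
  pick <- cand[which.max(curve$sensitivity[cand])]
  sens <- curve$sensitivity[pick]; spec <- curve$specificity[pick]
  structure(list(auc = as.numeric(r$auc),
                 cutoff = curve$threshold[pick],
                 sensitivity = sens, specificity = spec,
                 plr = if (spec < 1) sens / (1 - spec) else Inf,
                 curve = curve),
            class = "perio_roc")
}

#' @export
print.perio_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f; cutoff %.3f (sens %.3f, spec %.3f, +LR %.2f)\n",
              x$auc, x$cutoff, x$sensitivity, x$specificity, x$plr))
  invisible(x)
}

#' CDC-AAP periodontitis case classification
#'
#' Classifies each patient by the CDC-AAP surveillance case definitions on
#' interproximal (mesial/distal) sites: severe when there are >= 2
#' interproximal sites with CAL >= 6 mm on different teeth and >= 1
#' interproximal site with PD >= 5 mm; moderate when there are >= 2
#' interproximal sites with CAL >= 4 mm on different teeth or >= 2
#' interproximal sites with PD >= 5 mm on different teeth; otherwise none.
#'
#' @param cohort A cohort data frame.
#' @return Data frame with `patient_id` and `diagnosis` (ordered factor
#'   none < moderate < severe).
#' @export
cdc_aap_classify <- function(cohort) {
  cohort <- validate_cohort(cohort)
  ip <- cohort[cohort$position %in% c("mesial", "distal"), ]
  ids <- unique(cohort$patient_id)
  diag <- vapply(ids, function(id) {
    d <- ip[ip$patient_id == id, ]
    teeth_cal6 <- unique(d$tooth[d$cal >= 6])
    teeth_cal4 <- unique(d$tooth[d$cal >= 4])
    teeth_pd5 <- unique(d$tooth[d$pd >= 5])
    any_pd5 <- any(d$pd >= 5)
    if (length(teeth_cal6) >= 2L && any_pd5) "severe"
    else if (length(teeth_cal4) >= 2L || length(teeth_pd5) >= 2L) "moderate"
    else "none"
  }, "")
  data.frame(patient_id = ids,
             diagnosis = factor(diag, levels = c("none", "moderate", "severe"),
                                ordered = TRUE),
             stringsAsFactors = FALSE)
}

# the ten classic CPI index teeth
.CPI_INDEX_TEETH <- c(17, 16, 11, 26, 27, 37, 36, 31, 46, 47)

#' Community periodontal index (PD + BOP variant)
#'
#' Per-person maximum of per-site CPI codes: 4 for PD >= 6 mm, 3 for PD 4-5
#' mm, 1 for bleeding on probing, 0 otherwise. Calculus (code 2) is not
#' recorded in these charts, so this comparator is a "CPI (PD+BOP)" variant
#' in which code 2 is unreachable; its use for ranking subjects is
#' unaffected.
#'
#' @param cohort A cohort data frame.
#' @param index_teeth_only Restrict to the ten classic index teeth
#'   (17, 16, 11, 26, 27, 37, 36, 31, 46, 47)? Default `TRUE`.
#' @return Data frame with `patient_id` and integer `cpi` (0-4).
#' @export
cpi_score <- function(cohort, index_teeth_only = TRUE) {
  cohort <- validate_cohort(cohort)
  d <- if (index_teeth_only) cohort[cohort$tooth %in% .CPI_INDEX_TEETH, ]
       else cohort
  ids <- unique(cohort$patient_id)
  code <- ifelse(d$pd >= 6, 4L, ifelse(d$pd >= 4, 3L, ifelse(d$bop == 1, 1L, 0L)))
  cpi <- vapply(ids, function(id) {
    v <- code[d$patient_id == id]
    if (length(v)) max(v) else 0L
  }, integer(1))
  data.frame(patient_id = ids, cpi = cpi, stringsAsFactors = FALSE)
}

#' Partial-examination performance metrics
#'
#' Compares a partial-mouth protocol with the full-mouth examination:
#' * sensitivity -- probability that the partial exam finds at least one
#'   site above the case threshold given the full mouth has one;
#' * prevalence -- fraction of subjects positive under the partial exam;
#' * relative bias (severity) -- (cohort mean CAL over partial sites -
#'   cohort mean CAL over all sites) / cohort mean over all sites;
#' * relative bias (extent) -- the same ratio for the fraction of sites
#'   with CAL >= 4 mm.
#'
#' Biases are cohort-level ratios of means by default; `per_subject = TRUE`
#' averages subject-level means first.
#'
#' @param cohort A cohort data frame.
#' @param partial_sites Site subset (data frame with `tooth`, `surface`,
#'   `position`, or a character vector of site labels).
#' @param case_threshold_mm Case definition threshold in mm (default 4).
#' @param strict Positive means CAL strictly `> case_threshold_mm` (default);
#'   `FALSE` uses `>=`.
#' @param per_subject Compute biases from per-subject means?
#' @return Object of class `partial_exam_metrics`: list with `sensitivity`
#'   (`NA` with `sensitivity_defined = FALSE` when the full mouth has no
#'   positives), `prevalence`, `relative_bias_severity`,
#'   `relative_bias_extent`, `n_partial_sites`.
#' @export
partial_exam_metrics <- function(cohort, partial_sites, case_threshold_mm = 4,
                                 strict = TRUE, per_subject = FALSE) {
  cohort <- validate_cohort(cohort)
  labels <- if (is.character(partial_sites)) partial_sites
            else site_label(partial_sites$tooth, partial_sites$surface,
                            partial_sites$position)
  all_labels <- site_label(cohort$tooth, cohort$surface, cohort$position)
  if (!all(labels %in% site_universe()$label))
    stop("partial_sites contains labels outside the site universe")
  in_partial <- all_labels %in% labels

  pos <- if (strict) cohort$cal > case_threshold_mm
         else cohort$cal >= case_threshold_mm
  ids <- unique(cohort$patient_id)
  full_pos <- tapply(pos, cohort$patient_id, any)[ids]
  part_pos <- tapply(pos & in_partial, cohort$patient_id, any)[ids]

  sens_defined <- any(full_pos)
  sensitivity <- if (sens_defined) mean(part_pos[full_pos]) else NA_real_

  mean_by <- function(v, subset) {
    if (per_subject) {
      m <- tapply(v[subset], cohort$patient_id[subset], mean)
      mean(m)
    } else mean(v[subset])
  }
  sev_full <- mean_by(cohort$cal, rep(TRUE, nrow(cohort)))
  sev_part <- mean_by(cohort$cal, in_partial)
  ext_full <- mean_by(as.numeric(cohort$cal >= 4), rep(TRUE, nrow(cohort)))
  ext_part <- mean_by(as.numeric(cohort$cal >= 4), in_partial)

  structure(list(sensitivity = sensitivity,
                 sensitivity_defined = sens_defined,
                 prevalence = mean(part_pos),
                 relative_bias_severity = (sev_part - sev_full) / sev_full,
                 relative_bias_extent = if (ext_full > 0)
                   (ext_part - ext_full) / ext_full else NA_real_,
                 n_partial_sites = length(unique(labels)),
                 case_threshold_mm = case_threshold_mm, strict = strict),
            class = "partial_exam_metrics")
}

#' @export
print.partial_exam_metrics <- function(x, ...) {
  cat(sprintf(paste0("Partial exam (%d sites, CAL %s %g mm): sensitivity ",
                     "%.3f, prevalence %.3f,\n  relative bias severity ",
                     "%.4f, extent %.4f\n"),
              x$n_partial_sites, if (x$strict) ">" else ">=",
              x$case_threshold_mm, x$sensitivity, x$prevalence,
              x$relative_bias_severity, x$relative_bias_extent))
  invisible(x)
}

#' Predict full-mouth summaries from a partial exam
#'
#' Predicts each subject's full-mouth summary (e.g. mean CAL) either as the
#' simple mean of the selected partial sites, or from a fitted
#' ability-to-summary GLM (see [glm_link_selection()]).
#'
#' @param cohort A cohort data frame (for `method = "mean_partial"`).
#' @param partial_sites Site subset as in [partial_exam_metrics()].
#' @param parameter Which clinical value to average (`"cal"`, `"pd"`,
#'   `"bop"`, `"pli"`); `"bop"` yields a percentage.
#' @param method `"mean_partial"` (default) or `"glm"`.
#' @param model A `perio_glm` (required for `method = "glm"`).
#' @param ability Ability vector (required for `method = "glm"`).
#' @return Named numeric vector of per-subject predictions.
#' @export
predict_full_mouth_summary <- function(cohort = NULL, partial_sites = NULL,
                                       parameter = "cal",
                                       method = c("mean_partial", "glm"),
                                       model = NULL, ability = NULL) {
  method <- match.arg(method)
  if (method == "glm") {
    if (is.null(model) || !inherits(model, "perio_glm"))
      stop("method = 'glm' requires a fitted perio_glm model")
    if (is.null(ability)) stop("method = 'glm' requires ability values")
    return(as.numeric(predict(model$fit,
                              newdata = data.frame(x = ability),
                              type = "response")))
  }
  cohort <- validate_cohort(cohort)
  labels <- if (is.character(partial_sites)) partial_sites
            else site_label(partial_sites$tooth, partial_sites$surface,
                            partial_sites$position)
  keep <- site_label(cohort$tooth, cohort$surface, cohort$position) %in% labels
  v <- cohort[[parameter]]
  if (parameter == "bop") v <- 100 * v
  out <- tapply(v[keep], cohort$patient_id[keep], mean)
  out[unique(cohort$patient_id)]
}
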