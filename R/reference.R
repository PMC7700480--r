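#' Reference item parameters of the published final 6-variable models
#'
#' The partial-examination protocol this package implements was calibrated,
#' in the multicenter study it derives from, to six bilaterally merged
#' variables: maxillary 2nd premolar (palatal-mesial), 1st premolar
#' (palatal-distal), canine (palatal-mesial), lateral incisor
#' (palatal-central), central incisor (palatal-distal), and mandibular 1st
#' premolar (lingual-mesial). This function returns the published
#' discrimination and extremity (threshold) parameters of those final models
#' for each clinical parameter, together with the published AIC/BIC of each
#' model (n = 254 subjects). These values seed the `"paper-2020"` synthetic
#' preset and can score new charts directly.
#'
#' @param parameter Optionally restrict to one clinical parameter.
#' @return Data frame with columns `parameter` (`cal`, `pd`, `bop`, `pli`,
#'   `mobility`), `tooth_type`, `surface`, `position`, `item` (label),
#'   `b1`, `b2` (`NA` for the dichotomous BOP items), `a`, `aic`, `bic`.
#' @export
reference_site_params <- function(parameter = NULL) {
  types <- c("max5", "max4", "max3", "max2", "max1", "mand4")
  positions <- c("mesial", "distal", "mesial", "central", "distal", "mesial")
  base <- data.frame(
    tooth_type = types,
    surface = "lingual",
    position = positions,
    stringsAsFactors = FALSE)
  base$item <- paste0(base$tooth_type, ":l-", base$position)

  block <- function(param, b1, b2, a, aic, bic)
    cbind(data.frame(parameter = param, stringsAsFactors = FALSE),
          base, b1 = b1, b2 = b2, a = a, aic = aic, bic = bic)

  out <- rbind(
    block("cal",
          b1 = c(0.28, 0.45, 0.65, 1.13, 0.75, 0.53),
          b2 = c(1.28, 1.24, 1.31, 1.59, 1.38, 1.57),
          a  = c(3.07, 3.42, 4.51, 4.83, 3.16, 2.03),
          aic = 1796.06, bic = 1859.73),
    block("pd",
          b1 = c(0.72, 0.88, 0.96, 1.35, 1.01, 1.03),
          b2 = c(1.46, 1.48, 1.39, 1.79, 1.45, 1.63),
          a  = c(3.89, 3.38, 4.89, 4.63, 3.90, 3.39),
          aic = 1198.73, bic = 1262.41),
    block("bop",
          b1 = c(1.30, 1.22, 1.56, 1.45, 1.63, 1.95),
          b2 = NA_real_,
          a  = c(3.70, 7.71, 2.93, 16.96, 2.48, 2.09),
          aic = 686.60, bic = 729.04),
    block("pli",
          b1 = c(0.38, 0.47, 0.35, 0.27, 0.47, 0.82),
          b2 = c(1.85, 1.70, 1.65, 1.81, 1.96, 2.03),
          a  = c(2.78, 3.85, 3.86, 2.66, 2.14, 2.19),
          aic = 1965.74, bic = 2029.41),
    block("mobility",
          b1 = c(0.87, 0.77, 1.22, 0.69, 0.72, 1.19),
          b2 = c(1.90, 1.85, 2.21, 1.79, 1.99, 2.56),
          a  = c(2.41, 2.53, 2.98, 3.81, 3.23, 2.07),
          aic = 1445.90, bic = 1509.57))
  rownames(out) <- NULL
  if (!is.null(parameter)) {
    parameter <- match.arg(parameter, unique(out$parameter))
    out <- out[out$parameter == parameter, ]
    rownames(out) <- NULL
  }
  out
}
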