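# Synthetic full-mouth cohort generator. One latent severity trait theta per
# subject drives every clinical parameter; site-level CAL categories come
# from a graded response model with per-site susceptibility profiles, and
# the mm/chart layer is emitted on top.

#' Per-site generating profiles
#'
#' Builds the site-level susceptibility profiles that drive the cohort
#' generator: a GRM discrimination `a` and ordered CAL thresholds `b1 < b2`
#' per site, plus the BOP logistic coefficients, the mean recession rate
#' (which couples PD to CAL), and ordinal-model offsets for PlI and
#' mobility. Profiles are mirror-symmetric (left = right) unless an
#' asymmetry is requested.
#'
#' The `"paper-2020"` preset plants the published final-model CAL parameters
#' (see [reference_site_params()]) at the six reference winner sites, gives
#' the other sites of those teeth attenuated discriminations, and assigns
#' every remaining tooth type a lower-information profile, so that the
#' stepwise selection procedure has a known ground truth. The `"uniform"`
#' preset gives every site the same moderate profile.
#'
#' @param preset `"paper-2020"` or `"uniform"`.
#' @param asymmetry Amount added to the left-side thresholds (default 0;
#'   use to probe the bilateral merge rule under left/right violation).
#' @return Data frame with one row per site: the [site_universe()] columns
#'   plus `a`, `b1`, `b2`, `bop_slope`, `bop_intercept`, `recession_rate`,
#'   `pli_shift`, `mobility_shift`.
#' @export
default_site_profiles <- function(preset = c("paper-2020", "uniform"),
                                  asymmetry = 0) {
  preset <- match.arg(preset)
  sites <- site_universe()
  n <- nrow(sites)
  prof <- sites
  prof$a <- rep(NA_real_, n); prof$b1 <- NA_real_; prof$b2 <- NA_real_

  if (preset == "uniform") {
    prof$a <- 1.8; prof$b1 <- 0.8; prof$b2 <- 2.2
  } else {
    ref <- reference_site_params("cal")
    winner_key <- paste(ref$tooth_type, "lingual", ref$position)
    site_key <- paste(sites$tooth_type, sites$surface, sites$position)
    is_winner <- site_key %in% winner_key
    winner_types <- ref$tooth_type

    # winner sites: published parameters, mirrored to both quadrants
    idx <- match(site_key[is_winner], winner_key)
    prof$a[is_winner] <- ref$a[idx]
    prof$b1[is_winner] <- ref$b1[idx]
    prof$b2[is_winner] <- ref$b2[idx]

    # other sites on winner teeth: attenuated discrimination, shifted up
    on_winner_tooth <- sites$tooth_type %in% winner_types & !is_winner
    widx <- match(sites$tooth_type[on_winner_tooth], ref$tooth_type)
    prof$a[on_winner_tooth] <- pmax(0.55 * ref$a[widx], 1.0)
    prof$b1[on_winner_tooth] <- ref$b1[widx] + 0.30
    prof$b2[on_winner_tooth] <- ref$b2[widx] + 0.45

    # remaining tooth types: low-information background; molars somewhat
    # more diseased (lower thresholds), mandibular anteriors less
    rest <- !(sites$tooth_type %in% winner_types)
    base_a <- ifelse(sites$pos[rest] >= 6, 1.30, 1.40)
    base_b1 <- ifelse(sites$pos[rest] >= 6, 0.70,
                      ifelse(sites$jaw[rest] == "mand" & sites$pos[rest] <= 3,
                             1.05, 0.90))
    base_b2 <- base_b1 + 1.55
    # deterministic within-tooth variation so sites are distinguishable
    site_idx <- match(paste(sites$surface, sites$position),
                      paste(.SITE_CODES$surface, .SITE_CODES$position))
    jit <- c(-0.08, 0.00, 0.08, -0.04, 0.04, 0.10)
    prof$a[rest] <- base_a * (1 + 0.05 * (site_idx[rest] - 3.5) / 2.5)
    prof$b1[rest] <- base_b1 + jit[site_idx[rest]]
    prof$b2[rest] <- base_b2 + jit[site_idx[rest]]
  }

  if (asymmetry != 0) {
    left <- prof$side == "left"
    prof$b1[left] <- prof$b1[left] + asymmetry
    prof$b2[left] <- prof$b2[left] + asymmetry
  }

  prof$bop_slope <- 1.2
  prof$bop_intercept <- -2.54
  prof$recession_rate <- 0.75
  prof$pli_shift <- 0
  prof$mobility_shift <- 0
  prof
}

#' Cohort generator configuration
#'
#' Study conditions for [generate_cohort()]: cohort size, seed, the
#' calibration preset, tooth missingness, and the category-to-millimetre
#' emission tables. The default `"paper-2020"` preset targets the reference
#' cohort's descriptive statistics (mean CAL 3.1 mm, mean PD 2.5 mm, BOP
#' 15.0%, mean PlI 0.3) in a treated chronic-periodontitis population with
#' at least 20 teeth per patient.
#'
#' @param n_subjects Number of patients (default 254).
#' @param seed Integer RNG seed.
#' @param preset Profile preset name passed to [default_site_profiles()].
#' @param missing_tooth_rate Poisson mean of missing teeth per patient
#'   (truncated so every patient keeps >= 20 of 28 teeth; default 1.5).
#' @param emission Category-to-mm emission tables: a list with
#'   `cat0_probs` (over 1-3 mm), `cat1_probs` (over 4-5 mm), and
#'   `cat2_geom_p` (CAL = 6 + Geometric tail).
#' @param bop_pocket_bonus Added to the BOP logit at sites in CAL category
#'   >= 1 (bleeding is likelier at diseased sites).
#' @param pli_cutpoints,mobility_cutpoints Latent cutpoints of the shared-
#'   trait cumulative-logistic models for plaque (per site) and mobility
#'   (per tooth).
#' @param pli_slope,mobility_slope Latent slopes of those models.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 254L, seed = 1L,
                          preset = "paper-2020",
                          missing_tooth_rate = 1.5,
                          emission = list(cat0_probs = c(0.16, 0.38, 0.46),
                                          cat1_probs = c(0.60, 0.40),
                                          cat2_geom_p = 0.65),
                          bop_pocket_bonus = 0.8,
                          pli_cutpoints = c(1.55, 3.10, 4.40),
                          pli_slope = 1.2,
                          mobility_cutpoints = c(1.9, 3.0, 4.0),
                          mobility_slope = 1.0) {
  stopifnot(n_subjects >= 0, missing_tooth_rate >= 0)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 preset = preset, missing_tooth_rate = missing_tooth_rate,
                 emission = emission, bop_pocket_bonus = bop_pocket_bonus,
                 pli_cutpoints = pli_cutpoints, pli_slope = pli_slope,
                 mobility_cutpoints = mobility_cutpoints,
                 mobility_slope = mobility_slope),
            class = "cohort_config")
}

# one coherent ordinal draw from a cumulative-logistic model
.ordinal_draw <- function(theta, slope, cutpoints, shift = 0) {
  u <- runif(length(theta))
  out <- integer(length(theta))
  for (c_k in cutpoints) {
    out <- out + as.integer(u < plogis(slope * theta - (c_k + shift)))
  }
  out
}

#' Generate a synthetic full-mouth cohort
#'
#' Draws one latent severity trait per subject from N(0, 1) and emits a
#' complete site-level chart: the CAL category at each site comes from the
#' graded response model with that site's profile; integer CAL mm are
#' emitted from the category's emission table; recession is truncated
#' Poisson and PD = CAL - recession (floor 1 mm); BOP is Bernoulli on a
#' logit shared with the trait plus a pocket bonus; PlI (per site) and
#' mobility (per tooth) come from cumulative-logistic models on the same
#' trait. Teeth go missing at random subject to the >= 20-teeth constraint.
#' Fully deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @param profiles Site profiles, as from [default_site_profiles()]
#'   (defaults to the config's preset).
#' @param theta Optional fixed latent trait vector (length `n_subjects`),
#'   bypassing the N(0,1) draw -- a debugging hook.
#' @return A validated `perio_cohort` data frame (long format; see
#'   [validate_cohort()]), with the generating `theta` attached as
#'   `attr(, "theta")` (named by patient).
#' @export
generate_cohort <- function(config = cohort_config(),
                            profiles = default_site_profiles(config$preset),
                            theta = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  if (n == 0L) {
    out <- data.frame(patient_id = character(), tooth = integer(),
                      surface = character(), position = character(),
                      cal = integer(), pd = integer(), bop = integer(),
                      pli = integer(), mobility = integer())
    class(out) <- c("perio_cohort", class(out))
    return(out)
  }
  set.seed(config$seed)
  if (is.null(theta)) theta <- rnorm(n) else stopifnot(length(theta) == n)
  ids <- sprintf("P%04d", seq_len(n))
  names(theta) <- ids
  em <- config$emission
  teeth_all <- .ALL_TEETH

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    th <- theta[i]
    n_missing <- min(rpois(1, config$missing_tooth_rate), 8L)
    teeth <- sort(sample(teeth_all, 28L - n_missing))
    prof <- profiles[profiles$tooth %in% teeth, ]
    ns <- nrow(prof)

    # CAL category from the site's GRM profile
    p_ge1 <- plogis(prof$a * (th - prof$b1))
    p_ge2 <- plogis(prof$a * (th - prof$b2))
    u <- runif(ns)
    cat_cal <- as.integer(u < p_ge1) + as.integer(u < p_ge2)

    cal <- integer(ns)
    i0 <- cat_cal == 0L; i1 <- cat_cal == 1L; i2 <- cat_cal == 2L
    cal[i0] <- sample(1:3, sum(i0), replace = TRUE, prob = em$cat0_probs)
    cal[i1] <- sample(4:5, sum(i1), replace = TRUE, prob = em$cat1_probs)
    cal[i2] <- 6L + stats::rgeom(sum(i2), em$cat2_geom_p)

    rec <- pmin(rpois(ns, prof$recession_rate), pmax(cal - 1L, 0L))
    pd <- pmax(cal - rec, 1L)

    bop_logit <- prof$bop_slope * th + prof$bop_intercept +
      config$bop_pocket_bonus * (cat_cal >= 1L)
    bop <- rbinom(ns, 1L, plogis(bop_logit))

    pli <- .ordinal_draw(rep(th, ns), config$pli_slope,
                         config$pli_cutpoints, prof$pli_shift)

    mob_tooth <- .ordinal_draw(rep(th, length(teeth)), config$mobility_slope,
                               config$mobility_cutpoints, 0)
    names(mob_tooth) <- teeth
    mobility <- mob_tooth[as.character(prof$tooth)]

    rows[[i]] <- data.frame(patient_id = ids[i], tooth = prof$tooth,
                            surface = prof$surface, position = prof$position,
                            cal = cal, pd = as.integer(pd), bop = bop,
                            pli = as.integer(pmin(pli, 3L)),
                            mobility = as.integer(pmin(mobility, 3L)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- validate_cohort(out)
  attr(out, "theta") <- theta
  out
}

#' Simulate raw GRM responses
#'
#' Direct response simulation from given graded-response items, without the
#' mm/chart layer -- the estimator-testing path.
#'
#' @param items A list of per-item parameter lists `list(a =, b =)`, or a
#'   data frame with columns `a`, `b1` (and `b2`, ... as needed; `NA`
#'   thresholds are dropped).
#' @param n Number of subjects.
#' @param seed Integer RNG seed.
#' @param theta Optional fixed latent trait vector of length `n`.
#' @return Integer matrix `n` x `length(items)` of category codes.
#' @export
generate_from_grm <- function(items, n, seed = 1L, theta = NULL) {
  stopifnot(n >= 1)
  if (is.data.frame(items)) {
    bcols <- grep("^b[0-9]+$", names(items), value = TRUE)
    items <- lapply(seq_len(nrow(items)), function(j) {
      b <- as.numeric(items[j, bcols])
      list(a = items$a[j], b = b[!is.na(b)])
    })
  }
  set.seed(seed)
  if (is.null(theta)) theta <- rnorm(n) else stopifnot(length(theta) == n)
  X <- matrix(NA_integer_, n, length(items))
  for (j in seq_along(items)) {
    a <- items[[j]]$a; b <- items[[j]]$b
    u <- runif(n)
    xj <- integer(n)
    for (bk in b) xj <- xj + as.integer(u < plogis(a * (theta - bk)))
    X[, j] <- xj
  }
  colnames(X) <- paste0("item", seq_along(items))
  X
}
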