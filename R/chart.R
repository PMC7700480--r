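#' Categorization thresholds for CAL and PD
#'
#' Millimetre thresholds that turn probe readings into the three ordinal
#' severity categories used by the graded response model: `< lower_mm` is
#' category 0, `lower_mm..upper_mm` (inclusive) category 1, `> upper_mm`
#' category 2. The default (4, 5) gives the <4 / 4-5 / >5 mm scheme;
#' `categorization_config(4, 6)` gives the alternative <4 / 4-6 / >6 mm
#' scheme.
#'
#' @param lower_mm Lower threshold in mm (default 4).
#' @param upper_mm Upper threshold in mm (default 5); must exceed `lower_mm`.
#' @return An object of class `categorization_config`.
#' @export
categorization_config <- function(lower_mm = 4L, upper_mm = 5L) {
  lower_mm <- as.integer(lower_mm); upper_mm <- as.integer(upper_mm)
  if (is.na(lower_mm) || is.na(upper_mm) || lower_mm >= upper_mm)
    stop("lower_mm must be < upper_mm")
  structure(list(lower_mm = lower_mm, upper_mm = upper_mm),
            class = "categorization_config")
}

#' Categorize a millimetre reading
#'
#' Maps an integer mm value (CAL or PD) to ordinal category 0, 1 or 2 under a
#' [categorization_config()]. Probes read in whole millimetres, so no tie
#' rule beyond the inclusive upper bound is needed.
#'
#' @param value_mm Integer mm value(s), >= 0. `NA` passes through.
#' @param config A [categorization_config()].
#' @return Integer category code(s) in 0..2.
#' @export
#' @examples
#' categorize_value(c(3, 5, 6))  # 0 1 2
categorize_value <- function(value_mm, config = categorization_config()) {
  stopifnot(inherits(config, "categorization_config"))
  if (any(value_mm < 0, na.rm = TRUE))
    stop("invalid measurement: negative mm value")
  out <- ifelse(value_mm < config$lower_mm, 0L,
                ifelse(value_mm <= config$upper_mm, 1L, 2L))
  as.integer(out)
}

#' Merge contralateral site categories
#'
#' Combines the ordinal categories of a left/right mirrored site pair into
#' one variable: the worse (maximum) category of the two, i.e. "at least one
#' site in the top category" scores top, "at least one in the middle" scores
#' middle, and only "both below" scores bottom. Missing sides are ignored;
#' the result is missing only when both are.
#'
#' @param left,right Integer category codes (or `NA`), recycled to a common
#'   length.
#' @return Integer vector of merged categories.
#' @export
#' @examples
#' merge_bilateral(2, 0)    # 2
#' merge_bilateral(NA, 1)   # 1
merge_bilateral <- function(left, right) {
  n <- max(length(left), length(right))
  left <- rep_len(as.integer(left), n); right <- rep_len(as.integer(right), n)
  out <- pmax(left, right, na.rm = TRUE)
  out[is.na(left) & is.na(right)] <- NA_integer_
  as.integer(out)
}

#' Validate a cohort of periodontal charts
#'
#' A cohort is a long data frame with one row per examined site and columns
#' `patient_id`, `tooth` (FDI), `surface`, `position`, `cal`, `pd`, `bop`,
#' `pli`, `mobility`. Checks the chart invariants: every present tooth has
#' exactly its six sites, every patient has at least 20 teeth, mm values are
#' non-negative integers (PD >= 1), `bop` is 0/1, `pli` and `mobility` are in
#' 0..3, and mobility is constant within a tooth.
#'
#' @param cohort A long-format cohort data frame.
#' @param min_teeth Minimum teeth per patient (default 20, the usual
#'   inclusion criterion for these cohorts).
#' @return The cohort, invisibly, with class `perio_cohort` prepended.
#' @export
validate_cohort <- function(cohort, min_teeth = 20L) {
  need <- c("patient_id", "tooth", "surface", "position",
            "cal", "pd", "bop", "pli", "mobility")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(cohort)) stop("empty cohort")
  if (!all(cohort$tooth %in% .ALL_TEETH))
    stop("invalid FDI tooth codes: ",
         paste(unique(setdiff(cohort$tooth, .ALL_TEETH)), collapse = ", "))
  if (any(cohort$cal < 0 | cohort$cal != floor(cohort$cal)))
    stop("cal must be a non-negative integer (mm)")
  if (any(cohort$pd < 1 | cohort$pd != floor(cohort$pd)))
    stop("pd must be a positive integer (mm)")
  if (!all(cohort$bop %in% c(0L, 1L))) stop("bop must be 0/1")
  if (!all(cohort$pli %in% 0:3)) stop("pli must be in 0..3")
  if (!all(cohort$mobility %in% 0:3)) stop("mobility must be in 0..3")

  key <- paste(cohort$patient_id, cohort$tooth)
  sites_per_tooth <- table(key)
  if (any(sites_per_tooth != 6L))
    stop("each present tooth must have exactly 6 site rows; offending: ",
         paste(utils::head(names(sites_per_tooth)[sites_per_tooth != 6L], 5), collapse = ", "))
  dup <- duplicated(paste(key, cohort$surface, cohort$position))
  if (any(dup)) stop("duplicated site rows")

  teeth_per_pat <- tapply(cohort$tooth, cohort$patient_id,
                          function(x) length(unique(x)))
  if (any(teeth_per_pat < min_teeth))
    stop("patients with fewer than ", min_teeth, " teeth: ",
         paste(utils::head(names(teeth_per_pat)[teeth_per_pat < min_teeth], 5), collapse = ", "))

  mob_var <- tapply(cohort$mobility, key, function(x) length(unique(x)))
  if (any(mob_var > 1L)) stop("mobility must be identical across a tooth's 6 sites")

  if (!inherits(cohort, "perio_cohort"))
    class(cohort) <- c("perio_cohort", class(cohort))
  invisible(cohort)
}

# collapse a 0-3 ordinal scale to three ordered levels {0, 1, >=2}
.collapse3 <- function(x) as.integer(pmin(x, 2L))

#' Build the ordinal response matrix for a clinical parameter
#'
#' Converts a cohort of charts into the subjects-by-items ordinal matrix that
#' the graded response model consumes. CAL and PD are categorized to three
#' levels via `config`; BOP is left binary; PlI and mobility (0-3 scales) are
#' collapsed to the three ordered levels 0, 1, >=2. Missing teeth yield
#' missing responses. With `bilateral = TRUE`, contralateral site pairs are
#' merged into one item each via [merge_bilateral()] (the site list must be
#' closed under mirroring).
#'
#' @param cohort A validated cohort (see [validate_cohort()]).
#' @param sites Data frame of sites to use as items, as from
#'   [site_universe()] (any subset of its rows).
#' @param parameter One of `"cal"`, `"pd"`, `"bop"`, `"pli"`, `"mobility"`.
#' @param config A [categorization_config()] (used for CAL/PD only).
#' @param bilateral Merge mirrored pairs into single items?
#' @return An object of class `perio_resp`: a list with `responses` (integer
#'   matrix, subjects x items, `NA` = missing), `n_categories` (integer per
#'   item), `items` (data frame of item metadata), `subjects`, and
#'   `parameter`.
#' @export
chart_to_response_matrix <- function(cohort, sites = site_universe(),
                                     parameter = c("cal", "pd", "bop", "pli", "mobility"),
                                     config = categorization_config(),
                                     bilateral = FALSE) {
  parameter <- match.arg(parameter)
  if (!nrow(sites)) stop("sites must be non-empty")
  cohort <- validate_cohort(cohort)

  subjects <- unique(cohort$patient_id)
  raw <- switch(parameter,
    cal = categorize_value(cohort$cal, config),
    pd  = categorize_value(cohort$pd, config),
    bop = as.integer(cohort$bop),
    pli = .collapse3(cohort$pli),
    mobility = .collapse3(cohort$mobility))
  max_cat <- if (parameter == "bop") 1L else 2L

  site_lab <- site_label(cohort$tooth, cohort$surface, cohort$position)
  want <- sites$label %||% site_label(sites$tooth, sites$surface, sites$position)
  full <- matrix(NA_integer_, nrow = length(subjects), ncol = length(want),
                 dimnames = list(subjects, want))
  keep <- site_lab %in% want
  full[cbind(match(cohort$patient_id[keep], subjects),
             match(site_lab[keep], want))] <- raw[keep]

  empty <- colSums(!is.na(full)) == 0L
  if (any(empty))
    stop("site(s) absent from every chart: ",
         paste(utils::head(want[empty], 8), collapse = ", "))

  items <- parse_site_label(want)
  items$label <- want
  items$tooth_type <- .tooth_type(items$tooth)

  if (bilateral) {
    mirrored <- mirror_site_label(want)
    if (!all(mirrored %in% want))
      stop("bilateral = TRUE requires a site list closed under mirroring")
    # one item per mirrored pair, keyed by tooth type + surface + position
    pair_key <- paste0(items$tooth_type, ":",
                       substr(items$surface, 1, 1), "-", items$position)
    keys <- unique(pair_key)
    merged <- matrix(NA_integer_, nrow = length(subjects), ncol = length(keys),
                     dimnames = list(subjects, keys))
    for (k in keys) {
      cols <- which(pair_key == k)
      stopifnot(length(cols) == 2L)
      merged[, k] <- merge_bilateral(full[, cols[1]], full[, cols[2]])
    }
    first <- match(keys, pair_key)
    items <- data.frame(label = keys,
                        tooth_type = items$tooth_type[first],
                        surface = items$surface[first],
                        position = items$position[first],
                        stringsAsFactors = FALSE)
    full <- merged
  }

  structure(list(responses = full,
                 n_categories = rep(max_cat + 1L, ncol(full)),
                 items = items,
                 subjects = subjects,
                 parameter = parameter,
                 bilateral = bilateral),
            class = "perio_resp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.perio_resp <- function(x, ...) {
  cat("Ordinal response matrix:", length(x$subjects), "subjects x",
      ncol(x$responses), "items (", x$parameter,
      if (x$bilateral) ", bilaterally merged" else "", ")\n", sep = " ")
  invisible(x)
}

#' Per-patient full-mouth summary statistics
#'
#' Computes the conventional whole-mouth summaries per patient: mean CAL and
#' PD (mm), BOP% (share of bleeding sites), mean PlI, maximum CAL, and the
#' extent (fraction of sites with CAL >= 4 mm).
#'
#' @param cohort A cohort data frame (one or more patients).
#' @return A data frame with one row per patient and columns `patient_id`,
#'   `n_teeth`, `n_sites`, `mean_cal`, `mean_pd`, `bop_pct`, `mean_pli`,
#'   `max_cal`, `extent_cal_ge4`.
#' @export
summary_stats <- function(cohort) {
  cohort <- validate_cohort(cohort)
  ids <- unique(cohort$patient_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    ch <- cohort[cohort$patient_id == id, ]
    data.frame(patient_id = id,
               n_teeth = length(unique(ch$tooth)),
               n_sites = nrow(ch),
               mean_cal = mean(ch$cal),
               mean_pd = mean(ch$pd),
               bop_pct = 100 * mean(ch$bop),
               mean_pli = mean(ch$pli),
               max_cal = max(ch$cal),
               extent_cal_ge4 = mean(ch$cal >= 4),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
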