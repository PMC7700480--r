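# Stepwise item-information site reduction:
#   Model 1: all unilateral sites ->
#   Model 2: best site per tooth type (bilateral information sum) ->
#   Model 3: top-k tooth types ->
#   Model 4: bilaterally merged variables.

#' Bilateral item-information table
#'
#' From a fit over unilateral sites, computes each item's integrated
#' information and tabulates it by (tooth type, surface, position), summing
#' the left and right sides. A side missing from the fit contributes 0.
#'
#' @param fit A `grm_fit` whose items carry site metadata (fitted via
#'   [chart_to_response_matrix()] with `bilateral = FALSE`).
#' @param range,n_grid Passed to [item_information_integral()].
#' @return A data frame with columns `tooth_type`, `surface`, `position`,
#'   `info_left`, `info_right`, `info_sum`, `a_left`, `a_right`, `a_sum` --
#'   one row per (tooth type, surface, position) present; 84 rows for a
#'   complete dentition.
#' @export
bilateral_info_sum <- function(fit, range = c(-10, 10), n_grid = 2001L) {
  stopifnot(inherits(fit, "grm_fit"))
  it <- fit$items
  if (is.null(it$tooth)) stop("fit items carry no site metadata")
  info <- vapply(fit$params, function(p)
    item_information_integral(p$a, p$b, range, n_grid), numeric(1))
  avec <- vapply(fit$params, `[[`, numeric(1), "a")
  side <- ifelse(it$tooth %/% 10 %in% c(1, 4), "right", "left")
  key <- paste(it$tooth_type, it$surface, it$position, sep = ":")
  keys <- unique(key)
  out <- do.call(rbind, lapply(keys, function(k) {
    rows <- which(key == k)
    if (length(rows) > 2L) stop("labeling error: more than two sides for ", k)
    lft <- rows[side[rows] == "left"]; rgt <- rows[side[rows] == "right"]
    il <- if (length(lft)) info[lft] else 0
    ir <- if (length(rgt)) info[rgt] else 0
    al <- if (length(lft)) avec[lft] else 0
    ar <- if (length(rgt)) avec[rgt] else 0
    data.frame(tooth_type = it$tooth_type[rows[1]],
               surface = it$surface[rows[1]],
               position = it$position[rows[1]],
               info_left = il, info_right = ir, info_sum = il + ir,
               a_left = al, a_right = ar, a_sum = al + ar,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# deterministic tie-break ordering: lingual before buccal, then
# mesial < central < distal
.site_order_rank <- function(surface, position) {
  2L * match(surface, c("lingual", "buccal")) +
    match(position, c("mesial", "central", "distal")) / 10
}

#' Best site per tooth type
#'
#' For each tooth type (jaw x distance from midline), picks the
#' surface/position with the highest bilateral information sum. Ties are
#' broken by higher summed discrimination, then lingual before buccal, then
#' mesial before central before distal.
#'
#' @param table Output of [bilateral_info_sum()].
#' @return List with `winners` (one row per tooth type: the winning
#'   surface/position and its information) and `sites` (the corresponding
#'   concrete unilateral sites, two per tooth type, as a [site_universe()]
#'   subset).
#' @export
select_best_site_per_tooth_type <- function(table) {
  stopifnot(all(c("tooth_type", "info_sum") %in% names(table)))
  winners <- do.call(rbind, lapply(split(table, table$tooth_type), function(d) {
    o <- order(-d$info_sum, -d$a_sum, .site_order_rank(d$surface, d$position))
    d[o[1], ]
  }))
  rownames(winners) <- NULL
  uni <- site_universe()
  sel <- paste(uni$tooth_type, uni$surface, uni$position) %in%
    paste(winners$tooth_type, winners$surface, winners$position)
  list(winners = winners, sites = uni[sel, ])
}

#' Top tooth types by bilateral information
#'
#' Ranks the tooth types of a reduced (e.g. 28-site) fit by their bilateral
#' summed integrated item information and keeps the top `k`, returning their
#' left + right concrete sites.
#'
#' @param fit A `grm_fit` over unilateral sites (one site per tooth).
#' @param k Number of tooth types to keep (default 6).
#' @param range,n_grid Passed to [item_information_integral()].
#' @return List with `ranking` (tooth types with their information, in
#'   descending order), `kept` (the top-k tooth types), and `sites` (their
#'   concrete sites, `2 * k` rows).
#' @export
select_top_tooth_types <- function(fit, k = 6L, range = c(-10, 10),
                                   n_grid = 2001L) {
  tab <- bilateral_info_sum(fit, range, n_grid)
  agg <- do.call(rbind, lapply(split(tab, tab$tooth_type), function(d)
    data.frame(tooth_type = d$tooth_type[1],
               info_sum = sum(d$info_sum), a_sum = sum(d$a_sum),
               stringsAsFactors = FALSE)))
  if (k > nrow(agg))
    stop("k = ", k, " exceeds the ", nrow(agg), " tooth types present")
  agg <- agg[order(-agg$info_sum, -agg$a_sum, agg$tooth_type), ]
  rownames(agg) <- NULL
  kept <- agg$tooth_type[seq_len(k)]
  it <- fit$items
  sel_key <- paste(it$tooth_type, it$surface, it$position)
  uni <- site_universe()
  uni_key <- paste(uni$tooth_type, uni$surface, uni$position)
  sites <- uni[uni_key %in% sel_key[it$tooth_type %in% kept], ]
  list(ranking = agg, kept = kept, sites = sites)
}

#' Run the full stepwise site-reduction chain
#'
#' Executes the four-model reduction for one clinical parameter: Model 1
#' fits all unilateral sites; Model 2 refits on the best site per tooth type
#' (28 sites for a complete dentition); Model 3 refits on the top-`k` tooth
#' types (12 sites at `k = 6`); Model 4 refits on the bilaterally merged
#' variables of those sites (6 items). Models 2-4 are refit from scratch on
#' their reduced site sets. Items whose top severity category is unobserved
#' in the cohort are collapsed before fitting (recorded in the audit).
#'
#' @param cohort A cohort data frame (>= 50 charts recommended; fewer warns).
#' @param parameter Clinical parameter to select on (default `"cal"`).
#' @param config Categorization thresholds for CAL/PD.
#' @param k Tooth types kept at Model 3.
#' @param include_molars If `FALSE`, molars are excluded from the site
#'   universe before Model 1 (the premolar/anterior universe).
#' @param quad,tol,max_iter,m_step_maxit EM settings for all four fits; the
#'   defaults are coarser than [fit_grm()]'s because selection needs the
#'   information ordering, which stabilizes long before the parameters
#'   converge to full precision.
#' @return Object of class `selection_chain`: list with `model1`..`model4`
#'   (`grm_fit`s), `selected_sites` (the final 12 unilateral sites),
#'   `site_info` (Model 1 bilateral table), `ranking` (Model 2 tooth-type
#'   ranking), `audit` (data frame of per-stage item decisions), `parameter`
#'   and `k`.
#' @export
build_model_chain <- function(cohort, parameter = "cal",
                              config = categorization_config(), k = 6L,
                              include_molars = TRUE,
                              quad = quadrature_spec(), tol = 1e-3,
                              max_iter = 60L, m_step_maxit = 2L) {
  cohort <- validate_cohort(cohort)
  n_charts <- length(unique(cohort$patient_id))
  if (n_charts < 50L)
    warning("only ", n_charts, " charts; selection is unstable below 50")

  uni <- site_universe(include_molars = include_molars)
  audit <- list()
  note_collapsed <- function(stage, resp, resp2) {
    changed <- which(resp2$n_categories != resp$n_categories)
    if (length(changed))
      audit[[length(audit) + 1L]] <<- data.frame(
        stage = stage, item = colnames(resp$responses)[changed],
        action = "collapsed_empty_category", stringsAsFactors = FALSE)
  }
  fit_stage <- function(stage, sites, bilateral = FALSE) {
    resp <- chart_to_response_matrix(cohort, sites, parameter, config,
                                     bilateral = bilateral)
    resp2 <- collapse_empty_categories(resp)
    note_collapsed(stage, resp, resp2)
    tryCatch(fit_grm(resp2, quad = quad, tol = tol, max_iter = max_iter,
                     m_step_maxit = m_step_maxit),
             error = function(e)
               stop("chain failed at ", stage, ": ", conditionMessage(e)))
  }

  model1 <- fit_stage("model1", uni)
  info_tab <- bilateral_info_sum(model1)
  step2 <- select_best_site_per_tooth_type(info_tab)
  sites28 <- step2$sites
  if (!include_molars) sites28 <- sites28[sites28$pos <= 5, ]

  model2 <- fit_stage("model2", sites28)
  step3 <- select_top_tooth_types(model2, k = k)
  sites12 <- step3$sites

  model3 <- fit_stage("model3", sites12)
  model4 <- fit_stage("model4", sites12, bilateral = TRUE)

  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(stage = character(), item = character(), action = character())

  structure(list(model1 = model1, model2 = model2, model3 = model3,
                 model4 = model4,
                 selected_sites = sites12,
                 sites28 = sites28,
                 site_info = info_tab,
                 winners = step2$winners,
                 ranking = step3$ranking,
                 kept_tooth_types = step3$kept,
                 audit = audit_df,
                 parameter = parameter, k = k),
            class = "selection_chain")
}

#' @export
print.selection_chain <- function(x, ...) {
  cat("Stepwise site-selection chain (", x$parameter, "):\n", sep = "")
  cat("  Model 1:", length(x$model1$params), "sites  ->",
      "Model 2:", length(x$model2$params), "sites  ->",
      "Model 3:", length(x$model3$params), "sites  ->",
      "Model 4:", length(x$model4$params), "merged variables\n")
  cat("  kept tooth types:", paste(x$kept_tooth_types, collapse = ", "), "\n")
  invisible(x)
}
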