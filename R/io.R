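# Chart CSV readers/writers, fit-parameter serialization, run manifests.

# CSV schema: patient_id, tooth_fdi, site (MB/B/DB/ML/L/DL),
# cal_mm, pd_mm, bop, pli, mobility

#' Read and write charts as CSV
#'
#' Long-format chart CSV with one row per examined site and header
#' `patient_id, tooth_fdi, site, cal_mm, pd_mm, bop, pli, mobility`, where
#' `site` is one of MB, B, DB, ML, L, DL. Missing teeth are simply absent
#' rows. `read_chart_csv()` validates every chart invariant and reports
#' offending row numbers.
#'
#' @param path File path.
#' @return `read_chart_csv()`: a validated `perio_cohort` data frame.
#' @export
read_chart_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "tooth_fdi", "site", "cal_mm", "pd_mm",
            "bop", "pli", "mobility")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("chart CSV missing column(s): ", paste(miss, collapse = ", "))
  idx <- match(raw$site, .SITE_CODES$code)
  if (anyNA(idx))
    stop("unknown site code(s) at row(s): ",
         paste(utils::head(which(is.na(idx)), 8), collapse = ", "))
  for (col in c("tooth_fdi", "cal_mm", "pd_mm", "bop", "pli", "mobility")) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))) |
                   as.numeric(raw[[col]]) != floor(as.numeric(raw[[col]])))
    if (length(bad))
      stop("non-integer ", col, " at row(s): ",
           paste(utils::head(bad, 8), collapse = ", "))
  }
  cohort <- data.frame(patient_id = as.character(raw$patient_id),
                       tooth = as.integer(raw$tooth_fdi),
                       surface = .SITE_CODES$surface[idx],
                       position = .SITE_CODES$position[idx],
                       cal = as.integer(raw$cal_mm),
                       pd = as.integer(raw$pd_mm),
                       bop = as.integer(raw$bop),
                       pli = as.integer(raw$pli),
                       mobility = as.integer(raw$mobility),
                       stringsAsFactors = FALSE)
  validate_cohort(cohort)
}

#' @rdname read_chart_csv
#' @param cohort A cohort data frame.
#' @export
write_chart_csv <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  code <- .SITE_CODES$code[match(paste(cohort$surface, cohort$position),
                                 paste(.SITE_CODES$surface, .SITE_CODES$position))]
  out <- data.frame(patient_id = cohort$patient_id,
                    tooth_fdi = cohort$tooth,
                    site = code,
                    cal_mm = cohort$cal, pd_mm = cohort$pd,
                    bop = cohort$bop, pli = cohort$pli,
                    mobility = cohort$mobility)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize fitted item parameters
#'
#' `write_grm_params_csv()` writes a flat per-item parameter table
#' (`item, Extrmt1, Extrmt2, ..., Dscrmn, ItemInformation, AIC, BIC`)
#' mirroring the layout in which graded-response software reports final
#' models. `grm_fit_report()` returns the same content plus fit metadata as
#' a list ready for JSON serialization.
#'
#' @param fit A `grm_fit`.
#' @param path Output CSV path.
#' @param range Information integration range.
#' @return The parameter data frame (invisibly for the writer).
#' @export
write_grm_params_csv <- function(fit, path, range = c(-10, 10)) {
  tab <- grm_param_table(fit, range)
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_grm_params_csv
#' @export
grm_param_table <- function(fit, range = c(-10, 10)) {
  stopifnot(inherits(fit, "grm_fit"))
  m_max <- max(fit$n_categories) - 1L
  tab <- data.frame(item = fit$labels, stringsAsFactors = FALSE)
  for (k in seq_len(m_max))
    tab[[paste0("Extrmt", k)]] <- vapply(fit$params, function(p)
      if (length(p$b) >= k) p$b[k] else NA_real_, numeric(1))
  tab$Dscrmn <- vapply(fit$params, `[[`, numeric(1), "a")
  tab$ItemInformation <- vapply(fit$params, function(p)
    item_information_integral(p$a, p$b, range), numeric(1))
  tab$AIC <- fit$aic
  tab$BIC <- fit$bic
  tab
}

#' @rdname write_grm_params_csv
#' @export
grm_fit_report <- function(fit, range = c(-10, 10)) {
  list(n_subjects = fit$n, n_items = length(fit$params),
       loglik = fit$loglik, n_parameters = fit$p,
       aic = fit$aic, bic = fit$bic,
       converged = fit$converged, n_iterations = fit$n_iterations,
       items = grm_param_table(fit, range))
}

#' Write a run manifest
#'
#' Records command, configuration, seed, input/output paths, package
#' version and timestamp as JSON so a run can be reproduced bit-for-bit.
#'
#' @param dir Output directory (created if needed).
#' @param command Command or function name.
#' @param seed Integer seed used.
#' @param config List of configuration values.
#' @param inputs,outputs Character vectors of paths.
#' @return Path of the written manifest, invisibly.
#' @export
write_run_manifest <- function(dir, command, seed, config = list(),
                               inputs = character(), outputs = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(command = command, seed = seed, config = config,
                   inputs = inputs, outputs = outputs,
                   package_version = as.character(packageVersion("periogrm")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
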