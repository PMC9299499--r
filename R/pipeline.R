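#' Analysis configuration
#'
#' Collects every tunable of the benchmark-dose / margin-of-exposure
#' pipeline.  The defaults are the recommended settings for continuous
#' in vivo micronucleus data: CES 50%, two-sided 90% profile CI (so the
#' BMDL is a one-sided 95% lower bound), likelihood-ratio acceptance at
#' p < 0.05, both the exponential and Hill families, rat-to-human
#' body-surface-area scaling and a 3- to 10-fold target MOE range.
#'
#' @param ces critical effect size (fraction over background).
#' @param ci_level two-sided CI level for BMDL/BMDU.
#' @param alpha likelihood-ratio significance level for covariate
#'   structure selection.
#' @param families model families to fit and combine.
#' @param d_bounds bounds for the log-steepness parameter.
#' @param thresholds named vector `c(lower = 3, upper = 10)` of MOE zone
#'   boundaries.
#' @param species animal species of the study, for HED scaling.
#' @param km_human human Km factor (mg/kg to mg/m^2).
#' @param dose_units,response_units unit labels echoed in reports.
#' @return A list of class `mn_config`.
#' @export
mn_config <- function(ces = 0.50, ci_level = 0.90, alpha = 0.05,
                      families = c("exponential", "hill"),
                      d_bounds = c(0.25, 4),
                      thresholds = c(lower = 3, upper = 10),
                      species = "rat", km_human = 37,
                      dose_units = "mg/kg/day",
                      response_units = "MN-PCE%") {
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(ces > 0, ci_level > 0, ci_level < 1, alpha > 0, alpha < 1)
  structure(list(ces = ces, ci_level = ci_level, alpha = alpha,
                 families = families, d_bounds = d_bounds,
                 thresholds = thresholds, species = species,
                 km_human = km_human, dose_units = dose_units,
                 response_units = response_units),
            class = "mn_config")
}

#' Run the full benchmark-dose to margin-of-exposure pipeline
#'
#' For each requested model family: select the covariate structure by
#' forward likelihood-ratio testing, then compute profile-likelihood
#' BMD/BMDL/BMDU per covariate level.  The per-family estimates are
#' combined per level (lowest BMDL, highest BMDU).  The point of
#' departure is the lowest combined BMDL across levels; it is converted
#' to human-equivalent doses by body-surface-area scaling and, when an
#' exposure range is supplied, characterized as margins of exposure with
#' zone verdicts.
#'
#' @param dataset an [mn_dataset], or a path to a CSV/TSV readable by
#'   [read_mn_dataset()].
#' @param config an [mn_config].
#' @param exposure_range optional numeric length-2 vector (mg/m^2) of
#'   anticipated human exposures.
#' @return A list of class `mn_report`: `config`, `dataset_info`,
#'   `selection` (per family: structure and trace), `estimates` (list of
#'   [mn_bmd]), `bmd_table`, `combined` (per-level PoD bounds),
#'   `ci_ratios`, `pod` (level, value), `hed`, `moe` (when an exposure
#'   range was given).
#' @export
run_pipeline <- function(dataset, config = mn_config(),
                         exposure_range = NULL) {
  if (is.character(dataset)) dataset <- read_mn_dataset(dataset)
  stopifnot(inherits(dataset, "mn_dataset"),
            inherits(config, "mn_config"))
  bounds <- mn_bounds(d = config$d_bounds)
  selection <- list(); estimates <- list()
  for (fam in config$families) {
    sel <- select_covariate_structure(dataset, fam, config$alpha, bounds)
    selection[[fam]] <- list(
      level_specific = sel$structure$level_specific,
      loglik = sel$fit$loglik, trace = sel$trace)
    for (lev in dataset$levels) {
      est <- profile_bmd_ci(dataset, fam, sel$structure, lev,
                            ces = config$ces,
                            ci_level = config$ci_level,
                            bounds = bounds, fit = sel$fit)
      estimates[[paste(fam, lev, sep = ".")]] <- est
    }
  }
  combined <- combine_families(unname(estimates))
  ci_ratios <- ci_ratio_report(unname(estimates), combined)
  bmd_table <- do.call(rbind, lapply(unname(estimates), function(e)
    data.frame(family = e$family, covariate_level = e$level,
               bmd = e$bmd, bmdl = e$bmdl, bmdu = e$bmdu,
               ci_ratio = e$ci_ratio, stringsAsFactors = FALSE)))
  pod_i <- which.min(combined$pod_bmdl)
  pod <- list(covariate_level = combined$covariate_level[pod_i],
              value = combined$pod_bmdl[pod_i],
              basis = "lowest combined BMDL across covariate levels")
  hed <- animal_to_hed(pod$value, species = config$species,
                       km_human = config$km_human)
  moe <- NULL
  if (!is.null(exposure_range)) {
    stopifnot(length(exposure_range) == 2L)
    moe <- moe_range_profile(hed$hed_mgm2,
                             exposure_range[1], exposure_range[2],
                             lower = config$thresholds[["lower"]],
                             upper = config$thresholds[["upper"]])
  }
  structure(list(
    config = config,
    dataset_info = list(form = dataset$form, n_rows = nrow(dataset$data),
                        endpoint = dataset$endpoint,
                        units = dataset$units,
                        levels = dataset$levels,
                        doses = sort(unique(dataset$data$dose))),
    selection = selection, estimates = estimates,
    bmd_table = bmd_table, combined = combined, ci_ratios = ci_ratios,
    pod = pod, hed = hed, moe = moe),
    class = "mn_report")
}

#' @export
print.mn_report <- function(x, ...) {
  pct <- round(100 * x$config$ces)
  cat("<mn_report> covariate BMD analysis, CES ", pct, "%, ",
      round(100 * x$config$ci_level), "% CI\n", sep = "")
  cat("\nPer-family estimates:\n")
  print(x$bmd_table, row.names = FALSE, digits = 4)
  cat("\nCombined (lowest BMDL / highest BMDU per level):\n")
  print(as.data.frame(x$combined), row.names = FALSE, digits = 4)
  cat(sprintf("\nPoD: BMDL%d = %.4g mg/kg (%s)\n", pct, x$pod$value,
              x$pod$covariate_level))
  print(x$hed)
  if (!is.null(x$moe)) print(x$moe)
  invisible(x)
}

# strip non-serializable pieces and produce a stable plain list
report_as_list <- function(report) {
  est <- lapply(unname(report$estimates), function(e)
    list(family = e$family, covariate_level = e$level, ces = e$ces,
         ci_level = e$ci_level, bmd = e$bmd, bmdl = e$bmdl,
         bmdu = e$bmdu, ci_ratio = e$ci_ratio,
         flags = e$diagnostics$flags))
  h <- report$hed
  out <- list(
    config = unclass(report$config),
    dataset = report$dataset_info,
    covariate_selection = lapply(report$selection, function(s)
      list(level_specific = s$level_specific, loglik = s$loglik,
           trace = s$trace)),
    estimates = est,
    combined = as.data.frame(report$combined),
    ci_ratios = report$ci_ratios,
    pod = report$pod,
    hed = list(pod_animal = h$pod_animal, species = h$species,
               bsa_divisor = h$bsa_divisor, km_human = h$km_human,
               hed_mgkg = h$hed_mgkg, hed_mgm2 = h$hed_mgm2,
               hed_mgkg_rounded = h$hed_mgkg_rounded,
               hed_mgm2_rounded = h$hed_mgm2_rounded))
  if (!is.null(report$moe))
    out$moe <- list(pod_hed = report$moe$at_min$pod_hed,
                    lower_threshold = report$moe$at_min$lower_threshold,
                    upper_threshold = report$moe$at_min$upper_threshold,
                    assessments = report$moe$table,
                    summary_zone = report$moe$summary_zone)
  out
}

#' Write a pipeline report as JSON
#'
#' The JSON is deterministic for identical inputs and configuration (no
#' timestamps or environment fields), so re-runs are byte-identical.
#'
#' @param report an `mn_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "string")
  invisible(path)
}

#' Write a pipeline report as Markdown
#'
#' Human-readable rendering of the same numbers the JSON report carries.
#'
#' @inheritParams write_report_json
#' @export
write_report_md <- function(report, path) {
  pct <- round(100 * report$config$ces)
  fmtrow <- function(...) paste(c("|", ...), collapse = " ")
  lines <- c(
    sprintf("# Covariate BMD / margin-of-exposure report (CES %d%%)", pct),
    "",
    sprintf("- endpoint: %s; dose units: %s", report$dataset_info$endpoint,
            report$dataset_info$units),
    sprintf("- families: %s; CI level: %g%%; LR alpha: %g",
            paste(report$config$families, collapse = ", "),
            100 * report$config$ci_level, report$config$alpha),
    "",
    "## Per-family BMD estimates",
    "",
    "| family | level | BMD | BMDL | BMDU | CI ratio |",
    "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(report$bmd_table))) {
    r <- report$bmd_table[i, ]
    lines <- c(lines, sprintf("| %s | %s | %.4g | %.4g | %.4g | %.3g |",
                              r$family, r$covariate_level, r$bmd,
                              r$bmdl, r$bmdu, r$ci_ratio))
  }
  lines <- c(lines, "",
             "## Combined (lowest BMDL, highest BMDU across families)",
             "",
             sprintf("| level | BMDL%d | BMDU%d |", pct, pct),
             "|---|---|---|")
  for (i in seq_len(nrow(report$combined))) {
    r <- report$combined[i, ]
    lines <- c(lines, sprintf("| %s | %.4g | %.4g |", r$covariate_level,
                              r$pod_bmdl, r$pod_bmdu))
  }
  h <- report$hed
  lines <- c(lines, "",
             "## Point of departure and human-equivalent dose", "",
             sprintf("- PoD: BMDL%d = %.6g mg/kg (%s; %s)", pct,
                     report$pod$value, report$pod$covariate_level,
                     report$pod$basis),
             sprintf("- HED: %.6g / %g = %.6g mg/kg; x Km %g = %.6g mg/m2",
                     h$pod_animal, h$bsa_divisor, h$hed_mgkg,
                     h$km_human, h$hed_mgm2),
             sprintf("- at reporting precision: %.2f mg/kg; %g mg/m2",
                     h$hed_mgkg_rounded, h$hed_mgm2_rounded))
  if (!is.null(report$moe)) {
    lines <- c(lines, "", "## Margin of exposure", "",
               "| exposure (mg/m2) | MOE | zone |", "|---|---|---|")
    for (i in seq_len(nrow(report$moe$table))) {
      r <- report$moe$table[i, ]
      lines <- c(lines, sprintf("| %.6g | %.4g | %s |", r$exposure,
                                r$moe, r$zone))
    }
    lines <- c(lines, "",
               sprintf("Worst-case zone: **%s**",
                       toupper(report$moe$summary_zone)))
  }
  writeLines(lines, path)
  invisible(path)
}
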