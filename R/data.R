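#' Dose-response dataset container
#'
#' Wraps a data frame of continuous micronucleus dose-response observations
#' in one of two dialects:
#'
#' * individual form — columns `dataset_id`, `covariate_level`, `dose`,
#'   `response` (one row per animal; `subject_id` optional);
#' * summary form — columns `dataset_id`, `covariate_level`, `dose`, `n`,
#'   `mean`, `sd` (one row per dose group, arithmetic summaries).
#'
#' Responses are strictly positive (the lognormal error model has no
#' support at zero); doses are non-negative and model fitting requires at
#' least three distinct dose levels including a control at dose 0.
#'
#' @param df data frame in one of the two dialects above.
#' @param form `"individual"` or `"summary"`; auto-detected from the
#'   columns when `NULL`.
#' @param endpoint endpoint label, default `"MN-PCE%"`.
#' @param units dose units label, default `"mg/kg/day"`.
#' @return An object of class `mn_dataset`.
#' @export
mn_dataset <- function(df, form = NULL, endpoint = "MN-PCE%",
                       units = "mg/kg/day") {
  df <- as.data.frame(df)
  ind_cols <- c("dataset_id", "covariate_level", "dose", "response")
  sum_cols <- c("dataset_id", "covariate_level", "dose", "n", "mean", "sd")
  if (is.null(form)) {
    form <- if (all(c("n", "mean", "sd") %in% names(df))) "summary"
            else "individual"
  }
  form <- match.arg(form, c("individual", "summary"))
  need <- if (form == "individual") ind_cols else sum_cols
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) for ", form, " form: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$covariate_level <- as.character(df$covariate_level)
  df$dataset_id <- as.character(df$dataset_id)
  check_num <- function(col) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
      stop("non-numeric ", col, " on row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    v
  }
  dose <- check_num("dose")
  if (any(dose < 0))
    stop("negative dose on row(s) ",
         paste(utils::head(which(dose < 0), 5), collapse = ", "),
         call. = FALSE)
  if (form == "individual") {
    resp <- check_num("response")
    bad <- which(resp <= 0)
    if (length(bad))
      stop("non-positive response on row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           ": the lognormal error model requires responses > 0",
           call. = FALSE)
  } else {
    n <- check_num("n"); m <- check_num("mean"); s <- check_num("sd")
    if (any(n < 1)) stop("group n must be >= 1", call. = FALSE)
    if (any(m <= 0))
      stop("non-positive group mean on row(s) ",
           paste(utils::head(which(m <= 0), 5), collapse = ", "),
           ": the lognormal error model requires positive responses",
           call. = FALSE)
    if (any(s < 0)) stop("group sd must be non-negative", call. = FALSE)
    if (any(s == 0 & n > 1))
      stop("sd = 0 with n > 1 is not fittable under the lognormal model",
           call. = FALSE)
  }
  structure(list(data = df, form = form, endpoint = endpoint,
                 units = units,
                 levels = sort(unique(df$covariate_level))),
            class = "mn_dataset")
}

#' @export
print.mn_dataset <- function(x, ...) {
  cat("<mn_dataset>", x$form, "form;", nrow(x$data), "rows;",
      length(unique(x$data$dose)), "dose levels;",
      length(x$levels), "covariate level(s):",
      paste(x$levels, collapse = ", "), "\n")
  cat("  endpoint:", x$endpoint, " dose units:", x$units, "\n")
  invisible(x)
}

#' Read a dose-response dataset from delimited text
#'
#' Auto-detects the delimiter (comma or tab) and the dialect (individual
#' vs summary form) from the header, then validates through
#' [mn_dataset()]. Parse errors are addressed by row number.
#'
#' @inheritParams mn_dataset
#' @param path path to a CSV/TSV file.
#' @return An `mn_dataset`.
#' @export
read_mn_dataset <- function(path, endpoint = "MN-PCE%",
                            units = "mg/kg/day") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  mn_dataset(df, endpoint = endpoint, units = units)
}

#' Write a dataset in the CSV dialect the readers accept
#'
#' @param dataset an `mn_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mn_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "mn_dataset"))
  utils::write.csv(dataset$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Per-(level, dose) sufficient statistics on the log scale.
# Individual form: n, mean of log responses, within-group sum of squared
# log deviations. Summary form: arithmetic mean/SD mapped to log-scale
# moments via the lognormal moment identities
#   log-variance = log(1 + CV^2),  log-mean = log(mean) - log-variance/2,
# and the within-group sum of squares taken as n * log-variance.
group_stats <- function(dataset) {
  df <- dataset$data
  if (dataset$form == "individual") {
    key <- interaction(df$covariate_level, df$dose, drop = TRUE)
    sp <- split(log(df$response), key)
    lev <- vapply(split(df$covariate_level, key), `[`, "", 1)
    dos <- vapply(split(df$dose, key), `[`, 0, 1)
    data.frame(
      covariate_level = unname(lev),
      dose = unname(dos),
      n = vapply(sp, length, 0L),
      logmean = vapply(sp, mean, 0),
      logss = vapply(sp, function(v) sum((v - mean(v))^2), 0),
      row.names = NULL)
  } else {
    lv <- log1p((df$sd / df$mean)^2)
    data.frame(
      covariate_level = df$covariate_level,
      dose = df$dose,
      n = as.integer(df$n),
      logmean = log(df$mean) - lv / 2,
      logss = df$n * lv,
      row.names = NULL)
  }
}

# fitting precondition: >= 3 distinct doses including control
check_fittable <- function(dataset) {
  doses <- unique(dataset$data$dose)
  if (length(doses) < 3L)
    stop("model fitting needs at least 3 distinct dose levels; got ",
         length(doses), call. = FALSE)
  if (!any(doses == 0))
    stop("model fitting needs a control group at dose 0", call. = FALSE)
  invisible(TRUE)
}
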