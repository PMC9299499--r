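#' Dose-response model parameters
#'
#' Container for one fitted or assumed dose-response curve family across a
#' set of covariate levels.  Background `a`, potency `b` and log-scale
#' residual variance `var` are per-level maps; the maximum fold-change `c`
#' and log-steepness `d` are scalar shape parameters shared by every level
#' of the covariate (the defining constraint of the covariate approach).
#'
#' The two supported families, in PROAST's four-parameter "full model"
#' parameterization for increasing continuous responses, are
#' \deqn{m(x) = a \, [c - (c - 1)\exp(-b x^d)]}{m(x) = a*(c - (c-1)*exp(-b*x^d))}
#' for `family = "exponential"` and
#' \deqn{m(x) = a \, [1 + (c - 1) x^d / (b^d + x^d)]}{m(x) = a*(1 + (c-1)*x^d/(b^d + x^d))}
#' for `family = "hill"`.  Both satisfy `m(0) = a`, are non-decreasing in
#' dose for `c > 1`, and approach the plateau `a * c` at high dose.
#'
#' @param family `"exponential"` or `"hill"`.
#' @param a named numeric vector of per-level background responses
#'   (response units, > 0); a single unnamed value is recycled to `levels`.
#' @param b named numeric vector of per-level potency parameters (> 0);
#'   units are dose^(-d) for the exponential family and dose for Hill.
#' @param c scalar maximum fold-change over background (> 1 for an
#'   increasing response; values at or below 1 denote a flat curve).
#' @param d scalar log-steepness (dimensionless).
#' @param var named numeric vector of per-level variances of log-responses
#'   (> 0).
#' @param levels character vector of declared covariate levels; defaults
#'   to the names of `a`.
#' @return An object of class `mn_params`.
#' @seealso [predict_response()], [fit_single_structure()]
#' @export
#' @examples
#' p <- mn_params("exponential", a = c(male = 0.1), b = c(male = log(2)),
#'                c = 3, d = 1, var = c(male = 0.1))
#' predict_response(p, "male", 1)
mn_params <- function(family = c("exponential", "hill"),
                      a, b, c, d, var, levels = NULL) {
  family <- match.arg(family)
  if (is.null(levels)) levels <- names(a)
  if (is.null(levels)) levels <- "all"
  expand <- function(x, nm) {
    if (length(x) == 1L && is.null(names(x))) x <- rep(x, length(levels))
    if (is.null(names(x))) names(x) <- levels
    if (!setequal(names(x), levels))
      stop("parameter '", nm, "' must carry one value per declared level (",
           paste(levels, collapse = ", "), ")", call. = FALSE)
    x[levels]
  }
  a <- expand(a, "a"); b <- expand(b, "b"); var <- expand(var, "var")
  stopifnot(length(c) == 1L, length(d) == 1L)
  if (any(a <= 0)) stop("background 'a' must be positive", call. = FALSE)
  if (any(b <= 0)) stop("potency 'b' must be positive", call. = FALSE)
  if (any(var <= 0)) stop("log-scale variance 'var' must be positive",
                          call. = FALSE)
  structure(list(family = family, a = a, b = b, c = c, d = d, var = var,
                 levels = levels),
            class = "mn_params")
}

#' @export
print.mn_params <- function(x, ...) {
  cat("<mn_params>", x$family, "family;", length(x$levels),
      "covariate level(s)\n")
  cat("  shared: c =", format(x$c, digits = 4), " d =",
      format(x$d, digits = 4), "\n")
  for (l in x$levels)
    cat(sprintf("  %-10s a = %-10.4g b = %-12.5g var = %.4g\n",
                l, x$a[[l]], x$b[[l]], x$var[[l]]))
  invisible(x)
}

#' Predicted mean response at a dose
#'
#' Evaluates the fitted curve `m(dose)` for one covariate level.
#'
#' @param params an [mn_params] object.
#' @param level covariate level to evaluate; must be one of
#'   `params$levels`.
#' @param dose numeric vector of non-negative doses.
#' @return Numeric vector of predicted mean responses (same units as the
#'   background parameter `a`).
#' @export
predict_response <- function(params, level, dose) {
  stopifnot(inherits(params, "mn_params"))
  if (!level %in% params$levels)
    stop("unknown covariate level '", level, "'; declared levels: ",
         paste(params$levels, collapse = ", "), call. = FALSE)
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  a <- params$a[[level]]; b <- params$b[[level]]
  cc <- params$c; d <- params$d
  mean_response(params$family, a, b, cc, d, dose)
}

# vectorized curve kernel; x >= 0
mean_response <- function(family, a, b, cc, d, x) {
  xd <- ifelse(x > 0, x^d, 0)
  if (family == "exponential") {
    a * (cc - (cc - 1) * exp(-b * xd))
  } else {
    a * (1 + (cc - 1) * xd / (b^d + xd))
  }
}
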