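#' Body-surface-area species conversion table
#'
#' Divisors converting an animal mg/kg dose to a human-equivalent mg/kg
#' dose (FDA clinical starting-dose guidance), and the human Km factor
#' (37) converting mg/kg to mg/m^2.  The rat divisor is 6.2, equivalently
#' a multiplication by 0.16.  `human` is the identity entry.
#'
#' @return Named numeric vector of divisors.
#' @export
bsa_divisors <- function() {
  c(rat = 6.2, mouse = 12.3, human = 1)
}

#' Convert an animal point of departure to human-equivalent doses
#'
#' Applies body-surface-area scaling: the animal mg/kg dose is divided by
#' the species divisor (6.2 for rat) to give the human-equivalent mg/kg
#' dose, which is multiplied by the human Km (37) to give mg/m^2.
#' Both full-precision values and values at the conventional reporting
#' precision (mg/kg to 2 decimals; that rounded value times Km to 3
#' significant figures) are returned, since published chains round the
#' intermediate: 2.89 / 6.2 = 0.47 mg/kg, 0.47 x 37 = 17.4 mg/m^2.
#'
#' @param pod_animal animal point of departure, mg/kg (> 0).
#' @param species species name; must appear in `divisors`.
#' @param km_human human Km factor, default 37.
#' @param divisors named divisor table, default [bsa_divisors()].
#' @return An object of class `mn_hed` with `pod_animal`, `species`,
#'   `bsa_divisor`, `km_human`, `hed_mgkg`, `hed_mgm2` (full precision)
#'   and `hed_mgkg_rounded`, `hed_mgm2_rounded` (reporting precision).
#' @export
#' @examples
#' animal_to_hed(2.89, "rat")
animal_to_hed <- function(pod_animal, species = "rat", km_human = 37,
                          divisors = bsa_divisors()) {
  stopifnot(is.numeric(pod_animal), length(pod_animal) == 1L)
  if (pod_animal <= 0) stop("pod_animal must be positive", call. = FALSE)
  if (!species %in% names(divisors))
    stop("unknown species '", species, "'; available: ",
         paste(names(divisors), collapse = ", "), call. = FALSE)
  div <- unname(divisors[[species]])
  hed_mgkg <- pod_animal / div
  hed_mgkg_r <- round(hed_mgkg, 2)
  structure(list(pod_animal = pod_animal, species = species,
                 bsa_divisor = div, km_human = km_human,
                 hed_mgkg = hed_mgkg,
                 hed_mgm2 = hed_mgkg * km_human,
                 hed_mgkg_rounded = hed_mgkg_r,
                 hed_mgm2_rounded = signif(hed_mgkg_r * km_human, 3)),
            class = "mn_hed")
}

#' @export
print.mn_hed <- function(x, ...) {
  cat(sprintf("<mn_hed> %g mg/kg (%s) / %g = %.4g mg/kg HED; x Km %g = %.4g mg/m2\n",
              x$pod_animal, x$species, x$bsa_divisor, x$hed_mgkg,
              x$km_human, x$hed_mgm2))
  cat(sprintf("  at reporting precision: %.2f mg/kg -> %g mg/m2\n",
              x$hed_mgkg_rounded, x$hed_mgm2_rounded))
  invisible(x)
}

#' Margin of exposure with zone classification
#'
#' MOE = PoD (human-equivalent) / anticipated human exposure, both in
#' the same units.  Zones: green when `moe >= upper`, yellow when
#' `lower <= moe < upper`, red when `moe < lower` — boundary values fall
#' in the more favorable zone.
#'
#' @param pod_hed human-equivalent point of departure (mg/m^2 by
#'   default).
#' @param exposure anticipated human exposure, same units as `pod_hed`.
#' @param lower,upper zone thresholds, defaults 3 and 10 (the targeted
#'   3- to 10-fold acceptable MOE range).
#' @param pod_units,exposure_units unit labels; a mismatch is an error.
#' @return An object of class `mn_moe`: `pod_hed`, `exposure`, `moe`,
#'   `zone`, `lower_threshold`, `upper_threshold`, `units`.
#' @export
#' @examples
#' compute_moe(17.4, 35)   # red: margin below 3
compute_moe <- function(pod_hed, exposure, lower = 3, upper = 10,
                        pod_units = "mg/m2", exposure_units = "mg/m2") {
  if (!identical(pod_units, exposure_units))
    stop("unit mismatch: PoD in ", pod_units, " but exposure in ",
         exposure_units, call. = FALSE)
  stopifnot(lower > 0, upper >= lower)
  if (!is.numeric(exposure) || exposure <= 0)
    stop("exposure must be a positive number", call. = FALSE)
  if (!is.numeric(pod_hed) || pod_hed <= 0)
    stop("pod_hed must be a positive number", call. = FALSE)
  moe <- pod_hed / exposure
  zone <- if (moe >= upper) "green" else if (moe >= lower) "yellow"
          else "red"
  structure(list(pod_hed = pod_hed, exposure = exposure, moe = moe,
                 zone = zone, lower_threshold = lower,
                 upper_threshold = upper, units = pod_units),
            class = "mn_moe")
}

#' @export
print.mn_moe <- function(x, ...) {
  cat(sprintf("<mn_moe> PoD %g / exposure %g %s -> MOE %.3g  [%s]\n",
              x$pod_hed, x$exposure, x$units, x$moe, toupper(x$zone)))
  invisible(x)
}

#' Margin-of-exposure profile over an exposure range
#'
#' Assesses the MOE at both endpoints of an exposure range and reports a
#' worst-case summary (the highest exposure gives the smallest margin).
#'
#' @inheritParams compute_moe
#' @param exposure_min,exposure_max endpoints of the exposure range
#'   (`0 < exposure_min <= exposure_max`).
#' @return A list of class `mn_moe_profile`: `at_min`, `at_max`
#'   ([compute_moe()] results), `summary_zone` (the worst-case zone) and
#'   `table` (a data frame of both assessments).
#' @export
#' @examples
#' moe_range_profile(17.4, 35, 100)
moe_range_profile <- function(pod_hed, exposure_min, exposure_max,
                              lower = 3, upper = 10,
                              pod_units = "mg/m2",
                              exposure_units = "mg/m2") {
  if (!(exposure_min > 0 && exposure_min <= exposure_max))
    stop("need 0 < exposure_min <= exposure_max", call. = FALSE)
  at_min <- compute_moe(pod_hed, exposure_min, lower, upper,
                        pod_units, exposure_units)
  at_max <- compute_moe(pod_hed, exposure_max, lower, upper,
                        pod_units, exposure_units)
  tab <- data.frame(exposure = c(exposure_min, exposure_max),
                    moe = c(at_min$moe, at_max$moe),
                    zone = c(at_min$zone, at_max$zone),
                    stringsAsFactors = FALSE)
  structure(list(at_min = at_min, at_max = at_max,
                 summary_zone = at_max$zone, table = tab),
            class = "mn_moe_profile")
}

#' @export
print.mn_moe_profile <- function(x, ...) {
  cat("<mn_moe_profile> worst-case zone:", toupper(x$summary_zone), "\n")
  print(x$table)
  invisible(x)
}
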