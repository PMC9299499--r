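#' Benchmark dose at a critical effect size
#'
#' The BMD is the dose at which the mean response reaches
#' `a * (1 + ces)`, i.e. a fractional change of `ces` over background.
#' Closed forms:
#' \deqn{\mathrm{BMD}_{exp} = \left[-\ln\frac{c-1-\mathrm{CES}}{c-1}\Big/b\right]^{1/d}}
#' \deqn{\mathrm{BMD}_{hill} = b\,\left(\frac{t}{1-t}\right)^{1/d},\quad t = \mathrm{CES}/(c-1)}
#' When `ces >= c - 1` the curve never reaches the benchmark response and
#' `Inf` is returned.
#'
#' @param params an [mn_params].
#' @param level covariate level whose curve is evaluated.
#' @param ces critical effect size as a fraction over background
#'   (0.50 is the recommended value for in vivo micronucleus data; 0.10
#'   is the general continuous-data default).
#' @return The benchmark dose (dose units), or `Inf` when the effect size
#'   is unreachable.
#' @export
#' @examples
#' p <- mn_params("exponential", a = c(all = 1), b = c(all = log(2)),
#'                c = 2, d = 1, var = c(all = 0.1))
#' compute_bmd(p, "all", 0.5)  # exactly 1
compute_bmd <- function(params, level, ces) {
  stopifnot(inherits(params, "mn_params"), ces > 0)
  if (!level %in% params$levels)
    stop("unknown covariate level '", level, "'", call. = FALSE)
  b <- params$b[[level]]; cc <- params$c; d <- params$d
  if (ces >= cc - 1) return(Inf)
  if (params$family == "exponential") {
    (-log((cc - 1 - ces) / (cc - 1)) / b)^(1 / d)
  } else {
    t <- ces / (cc - 1)
    b * (t / (1 - t))^(1 / d)
  }
}

# potency parameter implied by a given BMD (inverse of compute_bmd);
# requires c - 1 > ces
b_from_bmd <- function(family, bmd, cc, d, ces) {
  if (family == "exponential") {
    -log((cc - 1 - ces) / (cc - 1)) / bmd^d
  } else {
    t <- ces / (cc - 1)
    bmd / (t / (1 - t))^(1 / d)
  }
}

#' Profile-likelihood confidence interval for the BMD
#'
#' Reparameterizes the focal level's curve so its BMD is an explicit
#' parameter (the potency `b` becomes a function of BMD, `c`, `d` and the
#' CES), profiles out every nuisance parameter, and brackets the doses at
#' which the profile log-likelihood drops `qchisq(ci_level, 1) / 2` below
#' its maximum (1.3528 for the default two-sided 90% interval, whose
#' lower end is therefore a one-sided 95% bound — the conventional BMDL).
#' Root finding is by bisection on log-dose to a tolerance of 1e-4, over
#' a bracket spanning BMD/1000 to 1000 * BMD.
#'
#' @inheritParams fit_single_structure
#' @param level covariate level whose BMD is profiled.
#' @param ces critical effect size (fraction over background).
#' @param ci_level two-sided confidence level, default 0.90.
#' @param fit optional precomputed [mn_fit] for this dataset / family /
#'   structure (avoids refitting).
#' @return An object of class `mn_bmd` with fields `family`, `level`,
#'   `ces`, `ci_level`, `bmd`, `bmdl`, `bmdu` (possibly `Inf`),
#'   `ci_ratio` and `diagnostics`.
#' @export
profile_bmd_ci <- function(dataset, family = c("exponential", "hill"),
                           structure = mn_structure(), level,
                           ces = 0.5, ci_level = 0.9,
                           bounds = mn_bounds(), fit = NULL) {
  family <- match.arg(family)
  if (is.null(fit))
    fit <- fit_single_structure(dataset, family, structure, bounds)
  if (!level %in% dataset$levels)
    stop("unknown covariate level '", level, "'", call. = FALSE)
  flags <- character()
  if (!fit$diagnostics$optim_ok) flags <- c(flags, "mle_not_converged")
  if (length(fit$diagnostics$at_bounds))
    flags <- c(flags, "mle_at_bounds")
  bmd_hat <- compute_bmd(fit$params, level, ces)
  if (!is.finite(bmd_hat)) {
    return(new_mn_bmd(family, level, ces, ci_level,
                      bmd = Inf, bmdl = NA_real_, bmdu = Inf,
                      flags = c(flags, "flat_model_bmd_undefined")))
  }

  gs <- group_stats(dataset)
  levels <- dataset$levels
  lev_idx <- match(gs$covariate_level, levels)
  n_lev <- length(levels)
  pm <- make_parmap(structure, levels, family, gs, bounds)
  b_specific <- pm$n_b == length(levels) && length(levels) > 1L
  # profile theta drops the focal potency entry and re-expresses c as
  # log(c - 1 - ces) so the benchmark response stays reachable
  foc <- if (b_specific) which(levels == level) else 1L
  drop_i <- pm$idx_b[foc]
  keep <- setdiff(seq_along(pm$lower), drop_i)
  lower <- pm$lower[keep]; upper <- pm$upper[keep]
  idx_c_k <- match(pm$idx_c, keep)
  idx_d_k <- match(pm$idx_d, keep)
  # c is re-expressed as ces + exp(.): keep c - 1 inside the user bounds
  # while guaranteeing the benchmark response stays reachable (c - 1 > ces)
  lower[idx_c_k] <- log(max(bounds$cm1[1] - ces, 1e-8))
  upper[idx_c_k] <- log(max(bounds$cm1[2] - ces, 2e-8))

  prof_negll <- function(thk, logbmd) {
    theta <- numeric(length(pm$lower))
    theta[keep] <- thk
    cc <- 1 + ces + exp(thk[idx_c_k]); d <- thk[idx_d_k]
    theta[pm$idx_c] <- log(cc - 1)
    bf <- b_from_bmd(family, exp(logbmd), cc, d, ces)
    if (!is.finite(bf) || bf <= 0) return(1e10)
    theta[drop_i] <- log(bf)
    r <- profile_ll_theta(theta, pm, family, gs, lev_idx, n_lev)
    if (!is.finite(r$ll)) 1e10 else -r$ll
  }

  th_full <- params_to_theta(fit$params, pm, levels)
  th0 <- th_full[keep]
  th0[idx_c_k] <- log(max(fit$params$c - 1 - ces, 1e-8))
  th0 <- pmin(pmax(th0, lower), upper)
  state <- new.env(parent = emptyenv())
  state$warm <- th0
  prof_ll <- function(logbmd) {
    o <- tryCatch(
      stats::optim(state$warm, prof_negll, logbmd = logbmd,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 300, factr = 1e6)),
      error = function(e) NULL)
    # fall back to the MLE-derived start if the warm chain failed
    if (is.null(o))
      o <- tryCatch(
        stats::optim(th0, prof_negll, logbmd = logbmd,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 300, factr = 1e6)),
        error = function(e) NULL)
    if (is.null(o)) return(-Inf)
    state$warm <- o$par
    -o$value
  }

  lb_hat <- log(bmd_hat)
  ll_at_hat <- prof_ll(lb_hat)
  ll_max <- max(fit$loglik, ll_at_hat)
  drop <- stats::qchisq(ci_level, df = 1) / 2
  target <- ll_max - drop
  f <- function(logbmd) prof_ll(logbmd) - target

  scan <- function(side) {
    # outward scan in quarter-decade steps, then bisection
    steps <- log(10) * seq(0.25, 3, by = 0.25)
    state$warm <- th0
    prev_x <- lb_hat; prev_f <- ll_at_hat - target
    for (s in steps) {
      x <- lb_hat + side * s
      fx <- f(x)
      if (is.finite(fx) && fx < 0) {
        lo <- min(prev_x, x); hi <- max(prev_x, x)
        r <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-4)$root,
                      error = function(e) NA_real_)
        return(list(x = r, crossed = TRUE))
      }
      prev_x <- x; prev_f <- fx
    }
    list(x = NA_real_, crossed = FALSE)
  }

  lo <- scan(-1)
  bmdl <- if (lo$crossed && is.finite(lo$x)) exp(lo$x) else {
    flags <- c(flags, "lower_bracket_exhausted")
    bmd_hat / 1000
  }
  hi <- scan(+1)
  bmdu <- if (hi$crossed && is.finite(hi$x)) exp(hi$x) else {
    flags <- c(flags, "upper_profile_unbounded")
    Inf
  }
  new_mn_bmd(family, level, ces, ci_level, bmd = bmd_hat,
             bmdl = bmdl, bmdu = bmdu, flags = flags, loglik = ll_max)
}

new_mn_bmd <- function(family, level, ces, ci_level, bmd, bmdl, bmdu,
                       flags = character(), loglik = NA_real_) {
  structure(list(family = family, level = level, ces = ces,
                 ci_level = ci_level, bmd = bmd, bmdl = bmdl,
                 bmdu = bmdu, ci_ratio = bmdu / bmdl, loglik = loglik,
                 diagnostics = list(flags = flags)),
            class = "mn_bmd")
}

#' @export
print.mn_bmd <- function(x, ...) {
  pct <- round(100 * x$ces)
  cat(sprintf("<mn_bmd> %s / %s: BMD%d = %.4g  [BMDL %.4g, BMDU %.4g]  (%.0f%% CI, ratio %.3g)\n",
              x$family, x$level, pct, x$bmd, x$bmdl, x$bmdu,
              100 * x$ci_level, x$ci_ratio))
  if (length(x$diagnostics$flags))
    cat("  flags:", paste(x$diagnostics$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Minimum log-likelihood gain required to accept extra parameters
#'
#' Half the chi-square critical value: an addition of `df` level-specific
#' parameters is accepted when twice the log-likelihood gain exceeds
#' `qchisq(1 - alpha, df)`.
#'
#' @param alpha significance level (default 0.05).
#' @param df number of additional free parameters.
#' @return Required gain in log-likelihood (e.g. 1.9207 for
#'   `alpha = 0.05`, `df = 1`).
#' @export
lr_critical_loglik <- function(alpha = 0.05, df = 1) {
  stats::qchisq(1 - alpha, df = df) / 2
}

#' Likelihood-ratio selection of the covariate structure
#'
#' Forward stepwise search starting from the fully shared model: at each
#' step the candidate level-specific parameter (considered in the fixed
#' order `a`, `b`, `var`) giving the largest log-likelihood gain is
#' accepted if twice the gain exceeds the chi-square critical value at
#' `alpha` with degrees of freedom equal to the number of extra
#' parameters.  The shape parameters `c` and `d` always remain shared.
#'
#' @inheritParams fit_single_structure
#' @param alpha significance level of the likelihood-ratio acceptance
#'   test, default 0.05.
#' @return A list with `structure` (the selected [mn_structure]), `fit`
#'   (its [mn_fit]) and `trace` (a data frame of every candidate tested).
#' @export
select_covariate_structure <- function(dataset,
                                       family = c("exponential", "hill"),
                                       alpha = 0.05,
                                       bounds = mn_bounds()) {
  family <- match.arg(family)
  stopifnot(alpha > 0, alpha < 1)
  L <- length(dataset$levels)
  cur_str <- mn_structure()
  cur_fit <- fit_single_structure(dataset, family, cur_str, bounds)
  trace <- data.frame(step = integer(), candidate = character(),
                      loglik = numeric(), gain = numeric(),
                      critical = numeric(), accepted = logical(),
                      stringsAsFactors = FALSE)
  if (L < 2L)
    return(list(structure = cur_str, fit = cur_fit, trace = trace))
  remaining <- c("a", "b", "var")
  step <- 0L
  crit <- lr_critical_loglik(alpha, df = L - 1L)
  repeat {
    step <- step + 1L
    cand_fits <- list()
    for (p in remaining) {
      st <- mn_structure(c(cur_str$level_specific, p))
      ft <- tryCatch(
        fit_single_structure(dataset, family, st, bounds,
                             start = cur_fit$params),
        error = function(e) NULL)
      if (is.null(ft) || !ft$diagnostics$optim_ok) {
        warning("candidate fit for level-specific '", p,
                "' did not converge; skipped", call. = FALSE)
        trace <- rbind(trace, data.frame(
          step = step, candidate = p, loglik = NA_real_,
          gain = NA_real_, critical = crit, accepted = FALSE))
        next
      }
      cand_fits[[p]] <- ft
      trace <- rbind(trace, data.frame(
        step = step, candidate = p, loglik = ft$loglik,
        gain = ft$loglik - cur_fit$loglik, critical = crit,
        accepted = FALSE))
    }
    if (!length(cand_fits)) break
    gains <- vapply(cand_fits, function(f) f$loglik - cur_fit$loglik, 0)
    # ties broken by the fixed candidate order a, b, var
    best <- names(cand_fits)[which.max(gains)]
    if (gains[[best]] > crit) {
      trace$accepted[trace$step == step & trace$candidate == best] <- TRUE
      cur_str <- mn_structure(c(cur_str$level_specific, best))
      cur_fit <- cand_fits[[best]]
      remaining <- setdiff(remaining, best)
      if (!length(remaining)) break
    } else break
  }
  list(structure = cur_str, fit = cur_fit, trace = trace)
}

#' Combine per-family BMD estimates into a point of departure
#'
#' For each covariate level, takes the lowest BMDL and the highest BMDU
#' across the supplied families (an infinite BMDU dominates the
#' maximum).  All estimates must share the same CES and CI level.
#'
#' @param estimates list of [mn_bmd] objects (at least one per level).
#' @return A data frame of class `mn_pod` with one row per covariate
#'   level: `covariate_level`, `pod_bmdl`, `pod_bmdu`,
#'   `contributing_families`, `ces`, `ci_level`.
#' @export
combine_families <- function(estimates) {
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, TRUE, "mn_bmd")))
  ces <- unique(vapply(estimates, `[[`, 0, "ces"))
  cl <- unique(vapply(estimates, `[[`, 0, "ci_level"))
  if (length(ces) != 1L)
    stop("estimates carry mixed CES values: ",
         paste(ces, collapse = ", "), call. = FALSE)
  if (length(cl) != 1L)
    stop("estimates carry mixed CI levels", call. = FALSE)
  levs <- unique(vapply(estimates, `[[`, "", "level"))
  out <- do.call(rbind, lapply(levs, function(l) {
    es <- Filter(function(e) e$level == l, estimates)
    data.frame(covariate_level = l,
               pod_bmdl = min(vapply(es, `[[`, 0, "bmdl")),
               pod_bmdu = max(vapply(es, `[[`, 0, "bmdu")),
               contributing_families =
                 paste(sort(unique(vapply(es, `[[`, "", "family"))),
                       collapse = "+"),
               ces = ces, ci_level = cl,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("mn_pod", "data.frame")
  out
}

#' BMD confidence-interval ratio report
#'
#' The BMDU/BMDL ratio measures the precision of a BMD estimate: wide
#' ratios indicate a study design that does not pin down the benchmark
#' dose.  Reports the ratio per family and level, plus the combined
#' point-of-departure ratio when a [combine_families()] result is given.
#'
#' @param estimates list of [mn_bmd] objects.
#' @param combined optional `mn_pod` from [combine_families()].
#' @return Data frame with columns `family`, `covariate_level`, `bmdl`,
#'   `bmdu`, `ci_ratio` (Inf when the upper bound is unbounded).
#' @export
ci_ratio_report <- function(estimates, combined = NULL) {
  out <- do.call(rbind, lapply(estimates, function(e)
    data.frame(family = e$family, covariate_level = e$level,
               bmdl = e$bmdl, bmdu = e$bmdu,
               ci_ratio = e$bmdu / e$bmdl, stringsAsFactors = FALSE)))
  if (!is.null(combined)) {
    out <- rbind(out, data.frame(
      family = "combined", covariate_level = combined$covariate_level,
      bmdl = combined$pod_bmdl, bmdu = combined$pod_bmdu,
      ci_ratio = combined$pod_bmdu / combined$pod_bmdl,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
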