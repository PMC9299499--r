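#' Covariate structure
#'
#' Declares which of the per-level parameters (background `a`, potency
#' `b`, log-scale variance `var`) are estimated separately for every
#' covariate level.  The shape parameters `c` and `d` are always shared
#' across levels; they can never be made level-specific.
#'
#' @param level_specific character subset of `c("a", "b", "var")`.
#' @return An object of class `mn_structure`.
#' @export
mn_structure <- function(level_specific = character()) {
  bad <- setdiff(level_specific, c("a", "b", "var"))
  if (length(bad))
    stop("only a, b and var may be level-specific (c and d are shared ",
         "shape parameters); got: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(level_specific = sort(unique(level_specific))),
            class = "mn_structure")
}

#' @export
print.mn_structure <- function(x, ...) {
  ls <- if (length(x$level_specific))
    paste(x$level_specific, collapse = ", ") else "(none)"
  cat("<mn_structure> level-specific:", ls, "; shared: c, d",
      if (!"a" %in% x$level_specific) "+ a",
      if (!"b" %in% x$level_specific) "+ b",
      if (!"var" %in% x$level_specific) "+ var", "\n")
  invisible(x)
}

#' Parameter bounds for model fitting
#'
#' @param d range for the log-steepness parameter; the default
#'   `c(0.25, 4)` avoids both infinite-slope and flat-shape degeneracy.
#' @param cm1 range for `c - 1` (fold-change over background minus one).
#' @return A list of class `mn_bounds`.
#' @export
mn_bounds <- function(d = c(0.25, 4), cm1 = c(1e-6, 1e4)) {
  stopifnot(length(d) == 2, d[1] > 0, d[1] < d[2],
            length(cm1) == 2, cm1[1] > 0, cm1[1] < cm1[2])
  structure(list(d = d, cm1 = cm1), class = "mn_bounds")
}

#' Lognormal log-likelihood of a dataset under fixed parameters
#'
#' Log-responses are modelled as normal with mean `log m(dose)` for the
#' record's covariate level and that level's log-scale variance; the
#' value is the sum of the normal log-densities of the log-responses.
#' Summary-form data contribute through their log-scale sufficient
#' statistics (see [mn_dataset()]), which for individual data reproduces
#' the per-observation sum exactly.
#'
#' @param dataset an [mn_dataset].
#' @param params an [mn_params] whose levels cover the dataset's.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, params) {
  stopifnot(inherits(dataset, "mn_dataset"), inherits(params, "mn_params"))
  miss <- setdiff(dataset$levels, params$levels)
  if (length(miss))
    stop("params missing covariate level(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  gs <- group_stats(dataset)
  mu <- log(mean_response(params$family,
                          params$a[gs$covariate_level],
                          params$b[gs$covariate_level],
                          params$c, params$d, gs$dose))
  v <- params$var[gs$covariate_level]
  sum(-gs$n / 2 * log(2 * pi * v) -
        (gs$logss + gs$n * (gs$logmean - mu)^2) / (2 * v))
}

# ---- internal fitting machinery ---------------------------------------

# Map between the optimizer vector theta and curve parameters.
# theta = [log a (1 or L), log b (1 or L), log(c-1), d]; the residual
# variance is profiled out analytically (its MLE given the curve is the
# mean squared log-residual, per level or pooled).
make_parmap <- function(structure, levels, family, gs, bounds) {
  L <- length(levels)
  n_a <- if ("a" %in% structure$level_specific) L else 1L
  n_b <- if ("b" %in% structure$level_specific) L else 1L
  idx_a <- seq_len(n_a)
  idx_b <- n_a + seq_len(n_b)
  idx_c <- n_a + n_b + 1L
  idx_d <- n_a + n_b + 2L
  map_lev <- function(n) if (n == L) match(levels, levels) else rep(1L, L)
  ia <- map_lev(n_a)[match(gs$covariate_level, levels)]
  ib <- map_lev(n_b)[match(gs$covariate_level, levels)]
  rng <- range(gs$logmean)
  lb_b <- if (family == "hill")
    c(log(min(gs$dose[gs$dose > 0])) - 12, log(max(gs$dose)) + 12)
  else c(-45, 12)
  lower <- c(rep(rng[1] - 4, n_a), rep(lb_b[1], n_b),
             log(bounds$cm1[1]), bounds$d[1])
  upper <- c(rep(rng[2] + 4, n_a), rep(lb_b[2], n_b),
             log(bounds$cm1[2]), bounds$d[2])
  list(levels = levels, n_a = n_a, n_b = n_b,
       idx_a = idx_a, idx_b = idx_b, idx_c = idx_c, idx_d = idx_d,
       ia = ia, ib = ib, lower = lower, upper = upper,
       var_specific = "var" %in% structure$level_specific)
}

# Profile log-likelihood of theta with var maximized analytically.
# Returns list(ll, var) where var is the per-level (or pooled, recycled)
# variance MLE.
profile_ll_theta <- function(theta, pm, family, gs, lev_idx, n_lev) {
  a <- exp(theta[pm$idx_a]); b <- exp(theta[pm$idx_b])
  cc <- 1 + exp(theta[pm$idx_c]); d <- theta[pm$idx_d]
  m <- mean_response(family, a[pm$ia], b[pm$ib], cc, d, gs$dose)
  if (any(!is.finite(m)) || any(m <= 0)) return(list(ll = -Inf, var = NA))
  dev <- gs$logss + gs$n * (gs$logmean - log(m))^2
  if (pm$var_specific) {
    S <- vapply(seq_len(n_lev), function(i) sum(dev[lev_idx == i]), 0)
    N <- vapply(seq_len(n_lev), function(i) sum(gs$n[lev_idx == i]), 0)
    v <- pmax(S / N, 1e-12)
    ll <- sum(-N / 2 * (log(2 * pi * v) + 1))
    vv <- v
  } else {
    N <- sum(gs$n)
    v <- max(sum(dev) / N, 1e-12)
    ll <- -N / 2 * (log(2 * pi * v) + 1)
    vv <- rep(v, n_lev)
  }
  list(ll = ll, var = vv)
}

# deterministic multi-start lattice (no RNG in the fit path)
start_lattice <- function(pm, family, gs, levels) {
  ctrl <- vapply(levels, function(l) {
    i <- gs$covariate_level == l
    if (any(i & gs$dose == 0)) gs$logmean[i & gs$dose == 0][1]
    else min(gs$logmean[i])
  }, 0)
  top <- vapply(levels, function(l) max(gs$logmean[gs$covariate_level == l]), 0)
  fold <- max(exp(top - ctrl), 1.5)
  a0 <- if (pm$n_a == length(levels)) ctrl else mean(ctrl)
  pos <- gs$dose[gs$dose > 0]
  x50s <- c(exp(mean(log(pos))), max(pos))
  starts <- list()
  for (d0 in c(0.5, 1, 2, 3.5))
    for (x50 in x50s)
      for (cm1 in c(1.5 * fold, 5 * fold)) {
        b0 <- if (family == "hill") log(x50) else log(log(2) / x50^d0)
        th <- c(a0, rep(b0, pm$n_b), log(cm1), d0)
        starts[[length(starts) + 1L]] <- pmin(pmax(th, pm$lower), pm$upper)
      }
  starts
}

#' Maximum-likelihood fit of one family under a fixed covariate structure
#'
#' Maximizes the lognormal log-likelihood over background, potency and
#' the shared shape parameters within bounds, with the residual variance
#' profiled out analytically.  Optimization uses bounded quasi-Newton
#' (`L-BFGS-B`) from a deterministic multi-start lattice (16 starts), so
#' the fit path involves no random numbers.
#'
#' @param dataset an [mn_dataset] with at least three distinct dose
#'   levels including a control at dose 0.
#' @param family `"exponential"` or `"hill"`.
#' @param structure an [mn_structure]; default all-shared.
#' @param bounds an [mn_bounds].
#' @param start optional [mn_params] used as an additional warm start.
#' @return An object of class `mn_fit`: `params` (an [mn_params] with the
#'   variance MLE filled in), `loglik`, `n_free_params`, `converged`
#'   (`FALSE` if the optimum sits on a parameter bound or the optimizer
#'   did not report success) and `diagnostics` (best start index, optim
#'   convergence code, parameters at bounds, whether the curve is
#'   effectively flat).
#' @export
fit_single_structure <- function(dataset, family = c("exponential", "hill"),
                                 structure = mn_structure(),
                                 bounds = mn_bounds(), start = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(dataset, "mn_dataset"),
            inherits(structure, "mn_structure"))
  check_fittable(dataset)
  gs <- group_stats(dataset)
  levels <- dataset$levels
  pm <- make_parmap(structure, levels, family, gs, bounds)
  lev_idx <- match(gs$covariate_level, levels)
  n_lev <- length(levels)
  negll <- function(theta) {
    r <- profile_ll_theta(theta, pm, family, gs, lev_idx, n_lev)
    if (!is.finite(r$ll)) 1e10 else -r$ll
  }
  starts <- start_lattice(pm, family, gs, levels)
  if (!is.null(start)) {
    stopifnot(inherits(start, "mn_params"))
    th <- params_to_theta(start, pm, levels)
    starts <- c(list(pmin(pmax(th, pm$lower), pm$upper)), starts)
  }
  # stage 1: cheap screen of every lattice start
  screened <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    o <- tryCatch(
      stats::optim(starts[[i]], negll, method = "L-BFGS-B",
                   lower = pm$lower, upper = pm$upper,
                   control = list(maxit = 120, factr = 1e8)),
      error = function(e) NULL)
    if (!is.null(o)) { o$start <- i; screened[[i]] <- o }
  }
  screened <- Filter(Negate(is.null), screened)
  if (!length(screened))
    stop("all optimizer starts failed for family '", family, "'",
         call. = FALSE)
  # stage 2: refine the two best screened points to full tolerance
  ord <- order(vapply(screened, `[[`, 0, "value"))
  best <- NULL
  for (cand in screened[ord[seq_len(min(2L, length(ord)))]]) {
    o2 <- tryCatch(
      stats::optim(cand$par, negll, method = "L-BFGS-B",
                   lower = pm$lower, upper = pm$upper,
                   control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL)
    o <- if (!is.null(o2) && o2$value <= cand$value) {
      o2$start <- cand$start; o2
    } else cand
    if (is.null(best) || o$value < best$value) best <- o
  }
  theta <- best$par
  pr <- profile_ll_theta(theta, pm, family, gs, lev_idx, n_lev)
  params <- theta_to_params(theta, pr$var, pm, family, levels)
  tol <- 1e-7
  nm <- theta_names(pm, levels)
  at <- nm[(theta - pm$lower < tol) | (pm$upper - theta < tol)]
  n_var <- if (pm$var_specific) n_lev else 1L
  flat <- params$c - 1 < 10 * bounds$cm1[1]
  out <- list(
    params = params, loglik = pr$ll,
    n_free_params = length(theta) + n_var,
    converged = best$convergence == 0 && length(at) == 0L,
    structure = structure, family = family, bounds = bounds,
    dataset_levels = levels,
    diagnostics = list(optim_ok = best$convergence == 0,
                       optim_message = best$message,
                       best_start = best$start,
                       n_starts = length(starts),
                       at_bounds = at, flat = flat))
  class(out) <- "mn_fit"
  out
}

theta_names <- function(pm, levels) {
  la <- if (pm$n_a > 1) paste0("a[", levels, "]") else "a"
  lb <- if (pm$n_b > 1) paste0("b[", levels, "]") else "b"
  c(la, lb, "c", "d")
}

theta_to_params <- function(theta, var, pm, family, levels) {
  theta <- unname(theta)
  a <- exp(theta[pm$idx_a]); b <- exp(theta[pm$idx_b])
  if (pm$n_a == 1L) a <- rep(a, length(levels))
  if (pm$n_b == 1L) b <- rep(b, length(levels))
  names(a) <- names(b) <- levels
  names(var) <- levels
  mn_params(family, a = a, b = b, c = 1 + exp(theta[pm$idx_c]),
            d = theta[pm$idx_d], var = var, levels = levels)
}

params_to_theta <- function(params, pm, levels) {
  a <- params$a[levels]; b <- params$b[levels]
  th_a <- if (pm$n_a == length(levels)) log(a) else log(mean(a))
  th_b <- if (pm$n_b == length(levels)) log(b) else log(exp(mean(log(b))))
  c(th_a, th_b, log(max(params$c - 1, 1e-12)), params$d)
}

#' @export
print.mn_fit <- function(x, ...) {
  cat("<mn_fit>", x$family, "family; loglik =",
      format(x$loglik, digits = 8), ";", x$n_free_params,
      "free parameters; converged:", x$converged, "\n")
  if (length(x$diagnostics$at_bounds))
    cat("  at bounds:", paste(x$diagnostics$at_bounds, collapse = ", "),
        "\n")
  print(x$params)
  invisible(x)
}
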