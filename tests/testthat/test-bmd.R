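test_that("closed-form BMD matches hand evaluations and flags unreachable CES", {
  p <- mn_params("exponential", a = c(all = 1), b = c(all = log(2)),
                 c = 2, d = 1, var = c(all = 0.1))
  expect_equal(compute_bmd(p, "all", 0.5), 1, tolerance = 1e-12)

  # effect size at or above c - 1 is never reached
  p2 <- mn_params("exponential", a = c(all = 1), b = c(all = 1),
                  c = 1.4, d = 1, var = c(all = 0.1))
  expect_identical(compute_bmd(p2, "all", 0.5), Inf)

  # vanishing effect size gives a vanishing BMD
  for (fam in c("exponential", "hill")) {
    b0 <- if (fam == "hill") 5 else 0.2
    pp <- mn_params(fam, a = c(all = 1), b = c(all = b0), c = 3, d = 1,
                    var = c(all = 0.1))
    expect_lt(compute_bmd(pp, "all", 1e-8), 1e-6)
  }
})

test_that("the benchmark response is attained at the BMD and BMD is monotone in CES", {
  set.seed(123)
  for (fam in c("exponential", "hill")) {
    for (i in 1:50) {
      p <- random_params(fam, ces = 0.5)
      bmd <- compute_bmd(p, "all", 0.5)
      expect_true(is.finite(bmd) && bmd > 0)
      expect_equal(predict_response(p, "all", bmd),
                   p$a[["all"]] * 1.5, tolerance = 1e-10)
      # strictly increasing on the reachable CES range
      ces_grid <- seq(0.05, min(0.9 * (p$c - 1), 2), length.out = 6)
      bmds <- vapply(ces_grid, function(ce) compute_bmd(p, "all", ce), 0)
      expect_true(all(diff(bmds) > 0))
    }
  }
})

test_that("profile interval contains the MLE and is ordered", {
  ds <- garriott_like(seed = 4)
  for (fam in c("exponential", "hill")) {
    est <- profile_bmd_ci(ds, fam, mn_structure(c("a", "b")), "male")
    expect_lte(est$bmdl, est$bmd)
    expect_lte(est$bmd, est$bmdu)
    expect_gte(est$ci_ratio, 1)
  }
})

test_that("BMD and its bounds are equivariant under dose rescaling", {
  p <- toy_exp_params()
  ds <- generate_dataset(p, c(0, 3, 12, 48), n_per_group = 5, seed = 8)
  k <- 10
  df_scaled <- ds$data
  df_scaled$dose <- df_scaled$dose * k
  ds_scaled <- mn_dataset(df_scaled)
  for (fam in c("exponential", "hill")) {
    e1 <- profile_bmd_ci(ds, fam, mn_structure(), "all")
    e2 <- profile_bmd_ci(ds_scaled, fam, mn_structure(), "all")
    expect_equal(e2$bmd, k * e1$bmd, tolerance = 0.01)
    expect_equal(e2$bmdl, k * e1$bmdl, tolerance = 0.01)
    expect_equal(e2$bmdu, k * e1$bmdu, tolerance = 0.01)
  }
})

test_that("BMD is invariant under response rescaling (only background moves)", {
  p <- toy_exp_params()
  ds <- generate_dataset(p, c(0, 3, 12, 48), n_per_group = 5, seed = 8)
  k <- 7
  df_scaled <- ds$data
  df_scaled$response <- df_scaled$response * k
  ds_scaled <- mn_dataset(df_scaled)
  e1 <- profile_bmd_ci(ds, "exponential", mn_structure(), "all")
  e2 <- profile_bmd_ci(ds_scaled, "exponential", mn_structure(), "all")
  expect_equal(e2$bmd, e1$bmd, tolerance = 0.01)
  expect_equal(e2$bmdl, e1$bmdl, tolerance = 0.01)
  expect_equal(e2$bmdu, e1$bmdu, tolerance = 0.01)
  f1 <- fit_single_structure(ds, "exponential")
  f2 <- fit_single_structure(ds_scaled, "exponential")
  expect_equal(f2$params$a[["all"]], k * f1$params$a[["all"]],
               tolerance = 0.01)
})

test_that("bisection bounds agree with an exhaustive grid profile", {
  # toy case with c and d pinned, so only a and the BMD-parameterized
  # potency remain free; the oracle grids the profile independently
  ces <- 0.5; cc <- 3; d <- 1
  truth <- mn_params("exponential", a = c(all = 1), b = c(all = 0.08),
                     c = cc, d = d, var = c(all = 0.05))
  ds <- generate_dataset(truth, c(0, 4, 12, 40), n_per_group = 5,
                         seed = 17)
  eps <- 1e-9
  pinned <- mn_bounds(d = c(d - eps, d + eps),
                      cm1 = c((cc - 1) - eps, (cc - 1) + eps))
  est <- profile_bmd_ci(ds, "exponential", mn_structure(), "all",
                        ces = ces, ci_level = 0.9, bounds = pinned)

  y <- ds$data$response; x <- ds$data$dose
  prof <- function(logbmd) {
    b <- -log((cc - 1 - ces) / (cc - 1)) / exp(logbmd)^d
    f <- function(loga) {
      mu <- log(exp(loga) * (cc - (cc - 1) * exp(-b * x^d)))
      v <- mean((log(y) - mu)^2)
      sum(stats::dnorm(log(y), mu, sqrt(v), log = TRUE))
    }
    stats::optimize(f, c(-3, 3), maximum = TRUE)$objective
  }
  step <- 0.005
  grid <- seq(log(est$bmd) - 1.5, log(est$bmd) + 1.5, by = step)
  pll <- vapply(grid, prof, 0)
  target <- max(pll) - stats::qchisq(0.9, 1) / 2
  inside <- grid[pll >= target]
  expect_equal(log(est$bmdl), min(inside), tolerance = 2 * step)
  expect_equal(log(est$bmdu), max(inside), tolerance = 2 * step)
})

test_that("family combination takes the extreme bounds per level", {
  mk <- function(fam, lev, bmdl, bmdu)
    mnbmd:::new_mn_bmd(fam, lev, 0.5, 0.9, bmd = sqrt(bmdl * bmdu),
                       bmdl = bmdl, bmdu = bmdu)
  est <- list(mk("exponential", "male", 2.9, 7.0),
              mk("hill", "male", 3.1, 7.42))
  pod <- combine_families(est)
  expect_equal(pod$pod_bmdl, 2.9)
  expect_equal(pod$pod_bmdu, 7.42)
  expect_identical(pod$contributing_families, "exponential+hill")

  # single family passes through
  solo <- combine_families(est[1])
  expect_equal(solo$pod_bmdl, 2.9)
  expect_equal(solo$pod_bmdu, 7.0)

  # infinite upper bound dominates
  inf_est <- list(mk("exponential", "male", 2.9, 7.0),
                  mk("hill", "male", 3.1, Inf))
  expect_identical(combine_families(inf_est)$pod_bmdu, Inf)

  # mixed CES is a configuration error
  bad <- list(mk("exponential", "male", 2.9, 7.0),
              mnbmd:::new_mn_bmd("hill", "male", 0.1, 0.9, 4, 3.1, 7.42))
  expect_error(combine_families(bad), "mixed CES")
})

test_that("CI-ratio report divides bounds and propagates infinity", {
  mk <- function(fam, lev, bmdl, bmdu)
    mnbmd:::new_mn_bmd(fam, lev, 0.5, 0.9, bmd = sqrt(bmdl * min(bmdu, 1e6)),
                       bmdl = bmdl, bmdu = bmdu)
  tab <- ci_ratio_report(list(mk("exponential", "male", 2, 8)))
  expect_equal(tab$ci_ratio, 4)
  tab2 <- ci_ratio_report(list(mk("hill", "male", 2, Inf)))
  expect_identical(tab2$ci_ratio, Inf)
  est <- list(mk("exponential", "m", 2, 8), mk("hill", "m", 3, 9))
  comb <- combine_families(est)
  tab3 <- ci_ratio_report(est, comb)
  expect_true("combined" %in% tab3$family)
  expect_equal(tab3$ci_ratio[tab3$family == "combined"], 9 / 2)
})
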